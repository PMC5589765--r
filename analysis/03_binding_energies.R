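#!/usr/bin/env Rscript
# Oxygen binding-energy bookkeeping: wild-type dE_O2 per subunit/state,
# the distal (HE7G) and proximal (HF8G+Im) mutant decomposition, and the
# ordinal oxygen-release ranking. QM/MM energies enter as packaged data;
# everything else is arithmetic defined by the binding-energy identity.
# Outputs under results/binding/.

library(hemefep)

cfg <- run_config("binding", out_dir = file.path("results", "binding"))
res <- run_scenario(cfg)

cat("Wild-type release ranking (most to least labile):\n")
print(res$ranking, digits = 4)

cat("\nMutant shifts ddE = dE(variant) - dE(wt), kcal/mol:\n")
for (s in res$shifts)
  cat(sprintf("  %-5s %s %-8s %-8s %+5.1f\n", s$labels$subunit,
              s$labels$state, s$labels$variant, s$effect_class, s$ddE))

cat("\nReading: both T-state subunits release oxygen faster than either\n")
cat("R-state subunit. The alpha-T proximal shift is negative (removing\n")
cat("proximal strain strengthens binding), all other proximal shifts are\n")
cat("positive; the distal H-bond matters mainly in beta. Tables under\n")
cat(cfg$out_dir, "\n")
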