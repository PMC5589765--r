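# hemefep

Free energy profiles and oxygen binding-energy decomposition for heme
proteins, with a self-contained synthetic model system.

## What this is for

Differential oxygen affinity in hemoglobin is governed by two
processes: ligand **uptake**, controlled by migration from solvent into
the distal pocket through the distal-histidine (HisE7) gate, and
**release**, controlled by how strongly bound O2 is held at the heme
iron (proximal HisF8 strain plus the distal H-bond). This package
implements the analysis stack used to dissect those contributions:

* **Migration free energy profiles** from multiple steered pulls along
  the Fe–O distance, via the Jarzynski equality
  `exp(-dG/kBT) = < exp(-W_i/kBT) >`, with uncertainties reported as
  `sqrt(MSE)`, `MSE = sigma^2(N) + B^2(N)` (bootstrap variance plus
  squared estimator bias); two-segment pulls are stitched at the
  docking-site minimum and a Morse Fe–O term (r0 = 1.8 A, a = 5.6 1/A,
  D = 10 kcal/mol) represents bond formation at short range.
* **Gate-opening profiles** from umbrella sampling on the HisE7
  side-chain dihedral (10 windows, 60–160 deg) unbiased by a periodic
  WHAM solver, summarized as open/closed preference and opening
  barrier.
* **Binding-energy bookkeeping**:
  `dE_O2 = E(Heme-O2) - (E(O2) + E(Heme))` for externally supplied
  QM/MM energies, mutant decomposition
  `ddE = dE(variant) - dE(wt)` (HE7G = distal, HF8G+Im = proximal),
  and the ordinal release ranking (larger dE_O2 = faster release).
* **Heme-pocket geometry** from PDB structures: Fe–O, O–O, Fe–NHis
  distances, the proximal-imidazole rotation angle (folded to
  [0, 45] deg), distal H-bond distances, and state-to-state deltas.

All inputs can be generated by the built-in overdamped Langevin toy
engine on model potentials with known analytic ground truth, so every
stage is testable end to end without an MD engine. Real work profiles,
umbrella samples, QM/MM energy tables and PDB files can be supplied as
TSV/PDB instead.

## Worked example

The numbered scripts under `analysis/` run the four studies and write
tables under `results/`. The first one estimates the closed- and
open-gate migration profiles at the standard protocol (40 pulls per
segment, 150 kcal/mol/A^2 spring, 0.25 A/ns):

```sh
Rscript analysis/01_migration_fep.R
```

prints

```
[closed gate] barrier 5.04 kcal/mol, well -1.08 kcal/mol, max sqrt(MSE) 0.35 kcal/mol
[open gate] barrier 0.30 kcal/mol, well -2.24 kcal/mol, max sqrt(MSE) 0.35 kcal/mol
```

i.e. with the gate closed, an oxygen molecule faces a ~5 kcal/mol
migration barrier; with the gate open the entry is essentially
barrierless and a ~-2 kcal/mol docking well draws the ligand inside —
the uptake-side mechanism by which gate opening promotes binding. The
same machinery in library form:

```r
library(hemefep)
pot <- make_migration_potential("closed")
ws  <- run_steered_set(pot, migration_protocol("solvent_to_docking"),
                       n_traj = 40, base_seed = 1)
fep <- jarzynski_with_mse(ws)          # dG(lambda) +- sqrt(MSE)
```

`analysis/02_gate_fep.R` reconstructs all 12 gate profiles
(subunit x quaternary state x tautomer) and recovers their encoded
thermodynamic orderings; `analysis/03_binding_energies.R` prints the
release ranking (betaT > alphaT > alphaR > betaR in lability) and the
proximal/distal mutant shifts; `analysis/04_pocket_geometry.R` builds
fixture structures at the tense/relaxed alpha-subunit geometries and
flags the 0.08 A Fe–His contraction as a proximal-effect candidate.

## Layout

```
R/                  package code (potentials, Langevin engine, Jarzynski,
                    WHAM, binding, geometry, pipeline, TSV I/O)
src/                Rcpp Langevin/potential core
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R  end-to-end recomputation into JSON
inst/extdata/       packaged QM/MM binding-energy table
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette (models, estimators, conventions)
```
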