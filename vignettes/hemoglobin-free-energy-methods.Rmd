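---
title: "Free energy and binding-energy methods for heme-protein oxygen affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy and binding-energy methods for heme-protein oxygen affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemefep)
```

## The scientific problem

Oxygen affinity in hemoglobin is set by two kinetic legs: uptake
(`k_on`), controlled by ligand migration from solvent into the distal
pocket and gated by the distal histidine (HisE7) side chain, and release
(`k_off`), controlled by how strongly the bound O~2~ is held at the heme
iron — a balance of the proximal-histidine (HisF8) geometry and the
distal H-bond. Three computational quantities dissect this picture:

1. the **migration free energy profile** along the Fe–O distance,
   estimated from repeated steered pulls via the Jarzynski equality;
2. the **gate-opening free energy profile** along the HisE7 side-chain
   dihedral (C–Cα–Cβ–Cγ), reconstructed from umbrella-sampling windows
   by WHAM; and
3. the **oxygen binding energy**
   \(\Delta E_{O_2} = E_{\mathrm{Heme-O_2}} - (E_{O_2} + E_{\mathrm{Heme}})\),
   an externally computed QM/MM quantity whose mutant differences
   \(\Delta\Delta E\) separate proximal from distal contributions, and
   whose ordering is monotone in release lability (larger, i.e. less
   negative, \(\Delta E_{O_2}\) means faster release).

This package implements the three analysis stages plus a heme-pocket
geometry module, and drives all of them with a built-in toy-dynamics
generator so that every stage can be validated against exact ground
truth without any molecular dynamics engine.

## The synthetic model system

### What it emulates

`make_migration_potential()` provides one-dimensional landscapes on an
Fe–O-distance-like axis, `r` from 1.5 to 9 Å with a solvent plateau at
zero. The *closed-gate* preset has a single Gaussian barrier (default
5 kcal/mol, the middle of the 4–6 kcal/mol closed-gate regime) in front
of a shallow distal well; the *open-gate* preset is essentially
barrierless with a −2 kcal/mol docking well. `make_gate_potential()`
provides periodic double wells on the gate dihedral (closed ≈ 60°,
open ≈ 160°) for all 12 subunit × quaternary-state × tautomer presets;
`gate_preset_table()` lists the encoded open–closed free energy
differences and opening barriers. The presets are *trend-faithful*, not
curve-faithful: they encode the qualitative orderings (HIE most closed
with the largest barrier, HIP most open with the smallest, β more
open-prone than α, β-R essentially barrierless) with gaps of at least
0.8 kcal/mol so that a finite-sampling pipeline can resolve them
reliably.

### Dynamics

`langevin_trajectory()` integrates overdamped (inertia-free) Langevin
dynamics with the Euler–Maruyama scheme. Overdamped dynamics is the
simplest engine with exactly known equilibrium and work statistics —
the analysis stages need correct statistics, not realistic kinetics.
The friction coefficient absorbs the mass; its defaults were chosen
once, as follows, and are part of the study conditions:

* migration coordinate: γ = 800 kcal mol⁻¹ ps Å⁻², timestep 0.2 ps.
  At the standard pulling speed this makes a migration segment
  *mildly dissipative* (mean dissipated work ≈ γ·v·L ≈ 1–2 kT),
  which is precisely the regime that exercises the finite-sample bias
  of the Jarzynski estimator and its error model;
* gate coordinate: γ = 0.05 kcal mol⁻¹ ps deg⁻², giving window
  relaxation times of a few ps so the default 8 ns of sampling per
  window decorrelates thoroughly.

Timesteps keep the stability ratio `k·dt/γ` below ≈ 0.1 for every
force constant in use, which also keeps the Euler–Maruyama stationary
variance bias below ~1 %. Trajectories are bit-reproducible: every run
takes an explicit seed (`base_seed + i` for member `i` of an ensemble)
and the seed is recorded in all output headers.

### What the toy system does *not* model

No solvent, no 3-D migration network, no coupling between the gate and
the migration coordinate, no force field. Consequently a green test
suite demonstrates that the *estimators* are correct and calibrated on
data with the right statistical structure — it says nothing about any
real protein's landscape, which requires the full MD/QM-MM machinery
upstream of this package.

## Migration profiles: steered work and the Jarzynski estimator

The steering protocol (`steering_protocol()`) follows the standard
multiple-steered-dynamics setup: a harmonic restraint of
150 kcal mol⁻¹ Å⁻² whose center moves at 0.25 Å/ns, 40 pulls per
profile, each from an independently equilibrated start. Because the
coordinate is long, it is split into two segments — solvent → docking
site (8.0 → 2.8 Å) and docking site → iron (3.6 → 1.8 Å) — which keeps
pulls productive; the segments overlap around the docking minimum.

`integrate_work()` accumulates
\(W(\lambda) = \int -k\,(x - \lambda)\, d\lambda\)
by the trapezoidal rule over saved frames (the work convention and the
integration rule are package choices; frames are saved densely enough —
10⁻³ Å of restraint motion — that the quadrature error is negligible).
Works are then interpolated onto a shared uniform 0.1 Å grid, since
frames are saved at fixed time stride rather than fixed λ.

`jarzynski_estimate()` applies, pointwise on the grid,
\[
\Delta G(\lambda) = -k_BT \,\ln \Big\langle e^{-W_i(\lambda)/k_BT}
\Big\rangle_i ,
\]
computed in log-sum-exp form (tested to agree with the naive average to
10⁻¹⁰ on well-scaled works, and to satisfy the second-law inequality
\(\langle W\rangle \ge \Delta G\) on every generated set).

### Error model

The finite-N exponential average is biased as well as noisy, so the
reported uncertainty is the square root of a mean square error with
both components, MSE = σ²(N) + B²(N). `estimate_mse()` obtains both by
bootstrap over the N work profiles: σ² is the bootstrap variance of the
pointwise estimate and B the mean bootstrap estimate minus the
full-sample estimate, deterministic given `boot_seed` (default 200
resamples). The bootstrap was chosen because it is distribution-free
and exactly reproducible; its known weakness is that resampling cannot
generate works below the observed minimum, so in dissipative regimes it
*underestimates* the true spread of the exponential average. Measured
over 200 independent synthetic replicate sets at the default protocol,
the analytic profile falls inside ±2·√MSE at ≈ 88–90 % of grid points —
close to, but slightly under, the nominal-coverage expectation. Users
who need conservative bars should widen them accordingly; the package
reports the model's bars as defined.

For fewer than 4 pulls the bootstrap is meaningless and the code falls
back to var(W)/N with a warning. `stitch_segments()` joins the two
segment profiles by the least-squares constant over their overlap
(equivalently, the mean pointwise difference), merges at the overlap
midpoint, and carries uncertainties through unchanged; stitching a
profile onto itself is the identity. Finally `add_morse()` adds the
Fe–O bond-formation term
\(D\,(1-e^{-a(r-r_0)})^2 - D\)
with r₀ = 1.8 Å, a = 5.6 Å⁻¹, D = 10 kcal/mol, zero-clamped beyond
`r_max = r0 + 3/a`, which qualitatively represents bond formation at
short range on top of the classical profile.

## Gate profiles: umbrella sampling and periodic WHAM

`run_umbrella_set()` samples 10 windows whose centers span 60°–160°
evenly. The umbrella force constant (60 kcal mol⁻¹ rad⁻², a package
default — window count and range are standard, stiffness is not) gives
window widths σ ≈ 5.7° at 300 K, about half the window spacing, so
neighboring histograms overlap well; overlap is checked explicitly and
`wham()` refuses sets with a disconnected window.

`wham_core()` iterates the standard weighted-histogram equations on
2° bins with minimal-image angular displacements in the bias energies,
to a tolerance of 10⁻⁶ kcal/mol on the window free energies (cap 10⁵
iterations). Correctness is established two ways: fed *exact* expected
counts from direct numerical integration of the biased Boltzmann
densities, the solver reproduces the potential to 10⁻³ kcal/mol; fed
finite inverse-CDF draws from those densities, it reaches
≤ 0.15 kcal/mol RMSD. Shot-noise bars of `kBT/sqrt(n_j)` per bin are
attached to the profile.

`align_profiles()` shifts each profile so its closed-region minimum is
exactly zero — profiles remain mutually independent, and no cross-profile
free energy comparison is implied. `summarize_gate()` reports the two
basin minima, the opening barrier (highest point between them minus the
closed minimum) and the preferred state, declaring a tie when the
open–closed difference is inside the combined pointwise uncertainty.

## Binding energies

The binding-energy module is deliberately thin: QM/MM energies are
opaque external inputs (TSV), the identity
\(\Delta E_{O_2} = E_{\mathrm{Heme-O_2}} - (E_{O_2}+E_{\mathrm{Heme}})\)
is recomputed on load, mutant shifts are
\(\Delta\Delta E = \Delta E_{\mathrm{variant}} - \Delta E_{\mathrm{wt}}\)
for matched subunit/state labels, and `koff_order()` emits a strictly
ordinal most-to-least-labile ranking (descending \(\Delta E_{O_2}\),
ties preserved). No quantitative rate model is implemented — only the
monotone ordering is defensible from the inputs this package consumes.
The packaged dataset (`hb_binding_dataset()`) carries the published
wild-type values for the four subunit/state combinations and mutant
values reconstructed arithmetically from the published shifts (so the
mutant rows are derived fixtures, as the file header states).

## Pocket geometry

`write_fixture_pdb()` builds minimal synthetic heme-pocket structures
(HETATM heme with Fe and the four pyrrole nitrogens, proximal and
distal histidine imidazoles with the relevant hydrogens, O1/O2 ligand,
and the leucine carbonyl accepting the proximal Nδ–H bond) that realize
requested distances to 0.01 Å and rotation angles to 0.5°; infeasible
target combinations (e.g. H···O distances incompatible with the O–O
bond length) are rejected. `read_structure()` wraps `bio3d::read.pdb`
and keeps the highest-occupancy altloc.

The proximal-imidazole rotation angle needed a concrete convention,
since "angle relative to the eclipsed conformation" underdetermines the
construction: here it is the angle between the projection of the
imidazole NE2→ND1 axis onto the porphyrin mean plane (least-squares
plane of the four pyrrole N) and the nearest Fe→N~pyrrole~ direction,
folded into [0°, 45°] by the porphyrin's four-fold pseudo-symmetry.
With this definition eclipsed = 0° and the descriptor is invariant
under rigid motion (10⁻⁶ Å) and under 90° rotations of the imidazole.
Published rotation angles from other conventions are therefore
interpretable but not expected to be bit-reproducible from crystal
files. The iron out-of-plane displacement is reported as a bonus
descriptor. `compare_states()` tabulates descriptor differences and
flags |Δd(Fe–N~His~)| ≥ 0.05 Å as a proximal-effect candidate (the
tense-to-relaxed α-subunit change is 2.20 → 2.12 Å).

## Problem sizes, defaults and reproducibility

The shipped analyses and tests use: 40 pulls per migration segment
(0.2 ps steps; ~26 000 steps per default-speed segment pull), 10
umbrella windows × 4 000 samples per gate profile, 200 bootstrap
resamples, 2° WHAM bins, and 50 replicate sets for the error-bar
calibration study — sizes chosen so the full analysis reruns from
scratch in a couple of minutes on one core while leaving every
statistical margin (ordering gaps vs. WHAM noise, coverage vs.
replicate count) comfortably resolved. All randomness flows from
explicit integer seeds; rerunning any scenario with the same
configuration reproduces its TSV outputs byte for byte.

## Known limitations

* The bootstrap error model slightly undercovers in dissipative
  regimes (see above); bidirectional estimators (Crooks/BAR) that
  would reduce the bias are out of scope.
* The toy gate and migration coordinates are uncoupled, so the
  pipeline cannot represent gating-modulated migration barriers within
  a single run; closed and open profiles come from separate scenarios.
* Gate presets encode orderings, not absolute published free energies;
  cross-profile free energy differences are never meaningful.
* The geometry module measures structures as given; it does not
  optimize, protonate, or average over trajectories.
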