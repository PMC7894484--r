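---
title: "Thermostabilization of extramembrane regions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermostabilization of extramembrane regions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshift)
```

## The problem

Membrane proteins are hard to produce and crystallize; thermostabilized
mutants help. For a seven-transmembrane retinal protein such as the
thermophilic rhodopsin TR, mutations can be designed in the extramembrane
loops and termini, where soluble-protein stabilization rules apply: a
predictor scores every candidate substitution by its folding free-energy
change (ΔΔG, kcal/mol, negative = stabilizing), a short list is chosen
under structural exclusion rules, and the survivors are tested in the lab
(pigment decoloration at 90 °C, DSC melting temperatures) and in silico
(MD snapshot ensembles at native and strongly denaturing temperatures).
This package implements the computational side of that workflow end to
end, with seeded generators standing in for the MD engine and the
instruments.

## Candidate design

`select_exposed_sites()` encodes the exclusion rules on an annotation
table: a residue survives when it is extramembrane, its relative solvent
exposure is at least a threshold (default 0.3), and none of the following
hold — restricted main-chain dihedral position (supplied as a per-residue
flag, since no numeric dihedral window generalises well), Pro or
Asp/Glu capping a helix N-terminus, Arg/Lys/His at a helix C-terminus,
ion-pair membership, or predicted burial in a native-state simulation.
Solvent exposure is deliberately an *input* (any SASA tool can produce
it); the package encodes the decision rules, not the geometry.

`rank_position_scan()` sorts by ΔΔG ascending with a deterministic
(site, substitution) tie-break. `finalize_candidates()` picks the final
set greedily by the refined ΔΔG under three constraints: one substitution
per site, exclusion of candidates flagged for substantial structural
change, and an optional bound on the N-/C-terminal side imbalance of the
final set (a transient imbalance during the greedy pass is allowed
whenever the remaining picks can still repair it). On ΔΔG ties,
candidates whose putative effect class is not yet represented are
preferred — this makes the qualitative "variety of effects and polarity
balance" criterion explicit and reproducible.

## Ensemble statistics

All superpositions are least-squares rigid fits of matched Cα atoms
(Kabsch algorithm via SVD with determinant correction, so a reflection is
never returned; collinear selections are flagged as degenerate). The
native-state score samples frames over a late time window (default
90–100 ns, every 200 ps, both endpoints included — 51 frames; nearest
frame matched within half an interval), superposes each frame on the
crystal reference, averages the RMSDs within each independent run, and
reports mean ± s.e.m. across runs. A small score means the fold is
retained; comparisons between constructs use the statistical protocol
below on the per-run averages.

For denatured ensembles the reference is internal: the *medoid* — the
member minimising its mean pairwise RMSD to the others, ties broken at
the lowest index — represents the ensemble, and its 19 RMSDs (for the
standard 20-member ensemble) quantify intramolecular structural
variation, a proxy for denatured-state entropy. The medoid is found by
exhaustive enumeration of the pairwise matrix; tests verify it against
an independently coded enumeration.

Per-residue Cα deviations are computed after a single global fit (no
per-residue refit), averaged over frames within runs; construct-versus-
construct comparison runs a per-residue two-tailed Student's t-test
across runs at α = 0.05, flagging residues with significantly *larger*
deviation. No multiple-testing correction is applied by default, matching
the raw per-residue reporting convention; a Bonferroni option exists.
Note two consequences verified by simulation in the test suite: the null
flag rate per residue is about α/2 (the direction requirement halves it),
and a strong planted perturbation slightly inflates deviations elsewhere
through the shared global fit.

Ion-pair occupancy counts frames whose charged-atom distance is *not
greater than* the cutoff (5 Å default, boundary inclusive); the
unrounded percentage is kept internally and rounded only for reporting.
The radius of gyration is mass-weighted about the selection's centre of
mass and reported in nm (coordinates are Å everywhere else).

## Stability metrics

Residual pigment is the absorbance ratio at 530 nm after/before heat
incubation, in percent. Decoloration kinetics use a pure single
exponential `P(t) = P0 e^{-kt}` — no floor or plateau term, matching the
single-exponential convention for this assay — fitted by
Levenberg–Marquardt least squares initialised from a log-linear
regression; `τ½ = ln 2 / k`, and a constant series returns k = 0 with
infinite half-life. A consistency check worth knowing: four minutes of
decay at the wild-type panel rate (0.21 min⁻¹) predicts 43.2% residual
pigment, within one printed s.e.m. of the measured 44.5 ± 3.2%.

DSC processing follows the instrument-software convention: the buffer
reference is interpolated onto the sample grid and subtracted, the signal
is divided by the molar protein concentration, and a baseline
interpolated between pre- and post-transition windows (defaults: first
and last 10 °C of the scan) is subtracted. The baseline is a straight
least-squares line through the window data by default — the minimal
faithful reading of an "interpolated baseline" — with a cubic option.
Tm is the temperature of the global maximum *on the sampled grid*: the
peak top is taken literally, with no sub-grid interpolation, so the scan
grid limits the reported precision (use ≤ 0.01 °C steps for
two-decimal Tm values). No scan-rate or irreversibility correction is
applied: the reported values are apparent Tm values, as is standard when
denaturation is kinetically controlled. A construct is classified
thermo-stabilized when its Tm exceeds the wild type's by ≥ 1 °C
(boundary inclusive).

## The statistical protocol

Group comparisons branch: each group is screened for normality with the
Kolmogorov–Smirnov test, variances are compared with a two-tailed F-test
(statistic = larger/smaller variance, p = 2·min(P(F≤f), P(F≥f))), and
then Student's t (pooled) or Welch's t (Satterthwaite df) is applied
two-tailed at α = 0.05. Because the normal parameters are estimated from
the sample, the naive KS p-value is anti-conservative; the default is
therefore the Lilliefors-corrected test (`nortest`), with the asymptotic
variant available as an option. For n < 5, where the Dallal–Wilkinson
approximation is unavailable, the Lilliefors null distribution is
computed once by vectorised Monte Carlo under a fixed internal stream
(RNG state restored) and cached, so tiny groups (n = 3 replicates are
the norm for this assay panel) still get a deterministic screen. A
normality failure is recorded as a flag and a warning, never a hard stop
— on synthetic data it fails at exactly the nominal rate. When both
groups are constant the comparison degenerates gracefully (p = 1 for
equal means); when one is, the variance tests are skipped and Welch's
test is used with a warning.

`compare_from_summary()` applies the same F-then-t branch starting from
printed mean ± s.e.m. tables (sd = sem·√n), with the normality flags set
to untested. Tests verify it against `t.test()` on raw vectors
reconstructed to have exactly the summary moments.

One caveat the test suite documents rather than hides: the 19 RMSD
values of a medoid group share the representative and the ensemble-level
deformation magnitude, so treating them as independent — as the
procedure prescribes — makes the t-test anticonservative for
ensemble-level comparisons (design simulations showed null rejection
clearly above the nominal 5%, robustly across generator variants). The
protocol itself is
correctly calibrated on independent observations (verified at n = 3 and
n = 19 over 2000 null replicates), and scale *ordering* by the medoid
statistic is essentially always correct; p-values from medoid groups
should simply not be read as exact.

## Synthetic data: what it emulates, and what it does not

`gen_toy_structure()` builds an idealized Cα helical bundle — by default
251 residues numbered 3–253 in 7 antiparallel helices, mimicking the
modelled extent of a 7TM rhodopsin chain. Helix geometry uses the ideal
1.5 Å rise and 100°/residue twist with the radius solved so consecutive
Cα atoms are exactly 3.8 Å apart; helices pack on a 10 Å circle (typical
TM packing) and are connected by circular-arc loops that preserve the
3.8 Å spacing exactly. The resulting compactness (Rg ≈ 1.8 nm) is in the
range of a real 7TM fold (≈ 2.0 nm).

`gen_native_runs()` emulates equilibrium snapshot series: a run-level
rigid offset (removed again by superposition — it exists precisely so
tests can verify superposition invariance), slow per-atom AR(1) drift,
and isotropic per-coordinate Gaussian noise of scale σ. For isotropic
noise the expected superposition RMSD is ≈ √3·σ, which is how the
per-construct `native_sigma` presets are derived from the printed
ensemble RMSD table (e.g. wild type 1.06 Å → σ ≈ 0.61 Å). Optional extra
noise at chosen residues plants a localized structural change for the
per-residue recovery tests.

`gen_coil_ensemble()` produces strongly perturbed conformers by a
cumulative random angular perturbation along the chain: each backbone
step direction is rotated by a product of small random rotations
(per-step angle s.d. = coil_scale/3.8 rad), so bond lengths are exact,
long-range structure decays smoothly, and the expected pairwise RMSD
grows monotonically with the scale. The wild-type preset (0.6
Å-equivalent) gives full-size medoid RMSDs around 18 Å, the same
magnitude as the measured coil panel (~22 Å); the one construct with a
reported coil-fluctuation difference (S8D) is scaled up by the printed
ratio, all others share the wild-type value. What the generator does
*not* reproduce: physical energetics, membrane context, or the tight
group s.e.m.s of real heated-MD ensembles — so passing tests demonstrate
the statistics and plumbing, not MD fidelity.

`gen_decoloration()` is the closed-form decay plus Gaussian noise in
percentage points, clipped at zero, with the t = 0 point fixed at 100
(it is the normalization point). `gen_dsc()` is a shared smooth buffer
profile, a linear instrumental baseline, and a Gaussian endotherm at the
preset peak temperature; with zero noise the full processing chain
recovers the preset exactly to grid precision. `gen_distance_trace()`
places exactly the requested number of frames at or below the cutoff
(uniform on [2.5 Å, cutoff]) and the rest above it, shuffled.

All generators accept a seed, restore the caller's RNG state, and are
bitwise-reproducible.

## Numerical choices and degenerate inputs

- Coordinates are Å throughout; only reported gyration radii are nm.
- Frame/time matching tolerance is half the sampling interval; both
  window endpoints are included (which is what makes 90–100 ns at 200 ps
  give 51 frames and 0–100 ns give 501).
- Superposition requires ≥ 3 matched points; collinear sets are flagged
  (rotation not unique) but their RMSD is still valid.
- Medoid ties break at the lowest index; identical members give RMSD 0.
- Alternate locations in PDB input: altloc "A" or blank kept, others
  dropped, for a deterministic conformer. Residue numbering is taken
  verbatim from the file — crystal numbering is never rewritten.
- The decay fit bounds k ≥ 0 and reports k = 0 (τ½ = ∞) for constant
  series; all-zero series are an error.
- DSC baseline windows that contain the signal maximum trigger a
  warning; monotone or flat processed curves are a no-peak error.
- Problem sizes in the test suite are chosen for desk-scale runs:
  60-residue bundles and 3 × 21-frame windows for ensemble statistics,
  with the full 251-residue geometry exercised where the quantity
  depends on it (compactness, panel-preset recovery), and 2000-replicate
  nulls for protocol calibration.

## Known limitations

- ΔΔG values are always consumed from tables; no free-energy function is
  implemented, and no SASA or secondary-structure assignment.
- No mmCIF or binary trajectory formats; multi-MODEL PDB or per-snapshot
  PDB files only.
- Apparent Tm only — no ΔH integration, no scan-rate correction.
- The medoid-group t-test caveat above applies to any ensemble-level
  p-value computed from shared-representative RMSD groups.
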