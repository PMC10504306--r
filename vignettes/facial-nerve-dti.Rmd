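---
title: "Methods: nerve-phantom DTI tractography and MPM-based group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nerve-phantom DTI tractography and MPM-based group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models and the design
decisions behind them. The pipeline has six stages — simulate, fit, track,
fuse, extract, test — and every stage is exported so it can be exercised
and validated in isolation.

## Signal model and tensor fit

Each voxel's diffusion-weighted signal follows the monoexponential tensor
model S = S₀ · exp(−b · gᵀ**D**g), with b in s/mm², g a unit gradient
direction and **D** a symmetric positive 3×3 tensor in mm²/s. The fit is
ordinary (unweighted) log-linear least squares for the seven unknowns
(ln S₀ and the six tensor components): deterministic, cheap, exactly
invertible on noiseless data, and the default of the common toolkits. We
deliberately do not use weighted least squares or robust refits; the
phantom's validation logic depends on the estimator being a known, simple
function of the data.

Numerical choices:

* signals are clamped to a floor of 10⁻⁶ × the voxel's mean b = 0 signal
  before the log (Rician noise can produce arbitrarily small magnitudes);
  clamped samples are counted and reported as QC;
* a voxel whose every sample sits at the floor is flagged "dead" and its
  tensor set to zero;
* gradient schemes whose design matrix is rank-deficient (coplanar
  directions) are rejected with an error rather than silently
  pseudo-inverted.

Eigendecomposition (per-voxel `arma::eig_sym`, C++) sorts eigenvalues
descending. Negative eigenvalues — a finite-noise artefact of the
unconstrained fit — are clamped to zero for scalar purposes and counted;
we do not refit under a positivity constraint, keeping the QC transparent.
Principal eigenvector signs are arbitrary; every consumer treats
directions as axial.

Scalar indexes use the standard definitions: MD = (λ₁+λ₂+λ₃)/3, AD = λ₁,
RD = (λ₂+λ₃)/2, FA = √(3/2)·√Σ(λᵢ−MD)²/√Σλᵢ², with FA defined as 0 for the
all-zero tensor. FA is clipped to [0, 1] against rounding.

## The phantom

The generator emulates the statistical structure the group analysis
assumes, not the physics of any particular scanner:

* **Grid.** Default 64³ voxels at 0.4 mm isotropic — the common-space
  resolution at which the analysis operates. A native-grid mode
  (1.2 × 1.2 × 3.0 mm, then trilinear resampling to 0.4 mm) exercises the
  resampling stage; template registration itself is out of scope, so the
  common grid is axiomatic.
* **Geometry.** Each nerve is a circular arc (radius of curvature 20 mm,
  default length 14 mm capped by the grid, minimum 10 mm) at a lateral
  offset of 0.24 × the grid width from the midline, swept into a tube of
  radius 0.8 mm — a mastoid-segment-like caliber. Left and right are exact
  mirror images across the midsagittal plane, so healthy cohorts are
  symmetric by construction. A voxel belongs to the tube iff its center
  lies within the tube radius (no partial-volume mixing), which keeps the
  ground truth exact for recovery tests.
* **Tissue.** Tube tensors are cylindrically symmetric with eigenvalues
  (AD, RD, RD) along the local tangent; defaults AD = 1.20 × 10⁻³,
  RD = 0.78 × 10⁻³ mm²/s are the healthy-side facial-nerve group means.
  Background is isotropic at 1.0 × 10⁻³ mm²/s (generic soft tissue — the
  bony canal's near-signal-void is not modelled).
* **Acquisition.** 1 b = 0 volume plus 20 directions at b = 1000 s/mm².
  Only the direction count is prescribed by the emulated protocol, so the
  directions themselves are generated by deterministic electrostatic
  repulsion (antipodally symmetric Coulomb descent from a Fibonacci
  hemisphere; no RNG, hence platform-stable).
* **Noise.** Rician: S ← √((S+n₁)² + n₂²) with n₁, n₂ ~ N(0, σ). The
  emulated study reports no SNR; σ defaults to S₀/30, a mid-range clinical
  value. Tests verify the Rician mean bias rather than assuming it away.
* **Between-subject variation.** Per subject, the log of each diffusivity
  receives a Gaussian jitter with relative SD 0.08, split into a
  subject-shared component and a per-side component with between-side
  correlation 0.6. Both numbers are calibrated to the published group
  tables: 0.08 reproduces the order of the reported per-side SDs, and the
  correlation is the value implied by the reported paired t statistics
  (back-computing Var(d) = σ₁² + σ₂² − 2ρσ₁σ₂ from the printed means, SDs
  and t gives ρ ≈ 0.5–0.75 across indexes). Sides would otherwise be
  independent and paired tests would see a √2-inflated difference SD that
  no within-subject design exhibits.
* **Lesion.** Patients multiply the affected side's RD by 1.128 (the
  affected/healthy ratio of the published group means) with AD unchanged —
  the pure demyelination signature. Affected sides follow the reported
  13 right : 6 left split by default.

What the phantom does **not** emulate: EPI/susceptibility distortion, eddy
currents, partial-volume averaging at the nerve boundary, crossing or
kissing fibers, the bony-canal signal void, registration error, and
scanner drift. Passing tests therefore show that the analysis recovers the
modelled signature under idealised spatial correspondence — they do not
certify performance on clinical data, where registration and
partial-volume effects dominate.

## Tractography

FACT-style deterministic integration: the direction at a point is the
principal eigenvector of the voxel containing it (nearest-voxel lookup, no
interpolation — the Diffusion Toolkit's FACT convention and the easiest to
oracle-check), sign-aligned with the previous step. Both half-tracks from
the seed (±e₁) are concatenated. Termination: containing voxel FA below
threshold, turning angle between successive steps above threshold, grid
exit, or the step cap.

Parameters (protocol values as defaults): FA threshold 0.15, angle
threshold 60°, minimum fiber length 2 mm, step 0.2 mm (half the common-grid
voxel; the protocol states no step size), 2000-step cap. The 2 mm rule is
read as a *total fiber length* filter, strictly "less than" (a 2.0 mm fiber
is retained) — a 2 mm *integration step* would exceed the nerve caliber.
The first step from the seed is exempt from the angle check. Seeds are
5 mm-diameter spheres, two per side placed at 35% and 65% of each arc,
expanded to one seed per voxel center inside the sphere (jittered copies
under `density > 1`); seeds act as seed regions only, not as inclusion
filters, since the emulated protocol describes none.

## Label fusion and extraction

A subject votes for a side at a voxel iff any retained streamline of that
side has a point in the voxel (half-open ownership; with a 0.2 mm step on a
0.4 mm grid, point membership rasterizes faithfully). There is no
streamline-count weighting — tract membership is binary per subject. The
maximum probability map assigns a side label iff its vote count exceeds
n/2 (*strict* majority, the conservative reading; plurality would admit
voxels labelled by arbitrarily small fractions). When both sides exceed
n/2 — possible because one subject can carry both labels at a voxel — the
larger count wins and exact ties fall to background. Three group maps are
built: healthy-only, patient-only, pooled.

Per subject and side, the scalar indexes are arithmetic means of the
subject's own maps over the group MPM label — so every subject is averaged
over the same voxel set, and between-subject contrast reflects tissue, not
region, differences. Empty labels yield NA with a warning and are dropped
from the statistics with the cell's n reported.

## Statistics

Within-subject comparisons (left vs right in controls; healthy side vs
affected in patients, oriented healthy-minus-affected) use the paired t
test, df = n − 1. Between-group comparisons use the pooled-variance
Student t, df = n₁ + n₂ − 2 — not Welch, because the published tables'
degrees of freedom (53 = 19 + 36 − 2 and 72 = 19 + 55 − 2) are only
consistent with pooling. All tests are two-tailed at α = 0.05 with no
multiplicity correction, matching the emulated design. The third table
compares the patients' healthy-side nerves (N1 = 19) against the healthy
cohort's pooled bilateral nerves (N3 = 36), and the affected nerves
(N2 = 19) against N4 = N3 + N1 = 55.

Normality is checked with a one-sample Kolmogorov–Smirnov test against a
normal with the sample's own mean and SD. With estimated parameters the
classical K-S p-value is anti-conservative (the Lilliefors situation); it
is reported with that caveat because the emulated analysis used the plain
K-S test. Constant samples are an error, not a p-value.

MD is displayed in 10⁻³ mm²/s and AD/RD in mm²/s, mirroring the published
tables' (inconsistent) convention; all CSV output carries SI mm²/s.

## Validation strategy and problem sizes

Every operation with a checkable contract is tested against an independent
oracle: the tensor fit against per-voxel `lm()`, the eigendecomposition
against `eigen()`, seed expansion and streamline rasterization against
brute-force enumeration, majority fusion against per-voxel counting on
random label stacks, `p_from_t` against numerical integration of the t
density, and the t-tests against `stats::t.test`. The published tables'
(t, df) → p cells are reproduced to three decimals analytically.

End-to-end properties run on scaled-down cohorts chosen for tight feedback
loops: a 48³ noiseless phantom for recovery and tracking invariants, and
44³ grids with 19-subject patient cohorts for replicated image-level
signature recovery (50 replicates; lower FA, higher MD/RD at p < 0.05 with
AD non-significant). The null false-positive rate is checked at the
measurement level (200 replicates of 18-subject symmetric cohorts) using
the analytic index generator `simulate_index_cohort()`, which draws the
same tissue model but skips imaging — the oracle for the statistics layer.

## Known limitations

* The tracking step is nearest-voxel FACT only; no tensor or direction
  interpolation, no probabilistic variant.
* The unconstrained fit can produce negative eigenvalues at low SNR;
  clamping is logged but biases FA slightly upward in noise-dominated
  background voxels.
* Eigenvalue repulsion biases AD up and RD down at low SNR; the paired
  design largely cancels this between sides, but absolute index levels in
  noisy regions should not be over-interpreted.
* The K-S p-value is anti-conservative with estimated parameters, as noted.
* The common grid is axiomatic: no registration, so registration error —
  a dominant error source on real nerve data — is untested.
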