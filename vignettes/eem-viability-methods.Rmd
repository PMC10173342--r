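---
title: "Estimating cell viability from EEM fluorescence with PARAFAC: models and methods"
author: "eemviva"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell viability from EEM fluorescence with PARAFAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colorimetric viability assays such as MTT are destructive, slow, and can
interfere with the compound under study. Intrinsic fluorescence of a cell
culture — tryptophan and tyrosine in proteins, pyridoxine, flavins, NADH —
changes systematically as cells die, so an excitation–emission matrix
(EEM) recorded directly from a culture well carries enough information to
estimate viability without any reagent. `eemviva` implements the full
chain from raw masked EEMs to a viability estimate:

1. build the acquisition wavelength grid and its measured-region mask
   (`build_acquisition_grid`),
2. complete the unmeasured scatter triangle (`preprocess_cube`),
3. decompose the sample × emission × excitation cube into non-negative
   trilinear components (`fit_parafac`),
4. choose the number of components by a residual scan plus split-half
   validation (`residual_scan`, `split_half`, `select_n_components`),
5. regress MTT viability on the component scores per cell line
   (`fit_mlr`, `loocv_predict`, `accordance_fit`),
6. compare dose groups by one-way ANOVA and Tukey HSD
   (`anova_oneway`, `tukey_hsd`, `accordance_tables`).

`run_pipeline()` orchestrates all stages on a simulated study;
`generate_cube()` and its companions produce synthetic data with the same
structure as the laboratory design, so every stage is testable without
instrument output.

## The trilinear model

Fluorescence of a dilute mixture follows Beer's law closely enough that
the intensity of sample $i$ at emission $j$, excitation $k$ is

$$x_{ijk} \approx \sum_{f=1}^{F} a_{if}\, b_{jf}\, c_{kf},$$

where $a_{if}$ is the relative concentration (score) of fluorophore $f$
in sample $i$ and $b_{\cdot f}$, $c_{\cdot f}$ are its emission and
excitation profiles (loadings). This PARAFAC decomposition is unique up
to permutation and scaling, which is what makes the recovered profiles
interpretable as spectra of real fluorophores. `fit_parafac` solves the
least-squares problem under non-negativity on all three factor matrices
by alternating least squares (ALS), each mode update being an exact
active-set non-negative least-squares solve (`nnls_solve`, with the
batched inner solver in compiled code). Exact NNLS updates guarantee the
residual sum of squares never increases, which the `sse_trace`
diagnostic records and the tests assert.

Canonical form: loading columns have unit Euclidean norm, all magnitude
is carried by the scores, and components are ordered by decreasing score
energy (exact ties broken lexicographically on the emission loading), so
a fit is fully deterministic given `(cube, F, seed, n_starts)`.

### Numerical choices

* **Convergence**: iteration stops when the relative SSE change drops
  below `tol = 1e-8`, or after `max_iter = 2000` iterations (a
  non-converged model is returned with `converged = FALSE` and a
  warning).
* **Multi-start**: one SVD-informed start (absolute values of the
  leading singular vectors of each unfolding) plus seeded random
  non-negative starts, `n_starts = 10` by default. Each start runs at
  most `start_iter = 150` exploratory iterations; only the lowest-SSE
  candidate is then iterated to convergence. This is the usual
  multi-start economy for ALS — ranking candidates after the SSE curve
  has flattened, which on these cubes happens well before 150
  iterations — and it cuts a full model scan several-fold. Setting
  `start_iter = max_iter` runs every start to convergence. Overfactored
  models (more components than the data support) can still converge to
  local minima when very few starts are used; the default of 10 is
  deliberate, and degenerate solutions show up clearly as a collapsed
  (all-zero) component and a near-zero split-half congruence.
* **Rank deficiency**: inside ALS a numerically singular passive-set
  subsystem gets a tiny on-the-fly ridge; `corcondia` falls back to a
  pseudo-inverse core solve with a warning.

## Preprocessing the masked region

The acquisition protocol never measures emission at or below the
excitation wavelength: each column starts at `ex + 20` nm (or at 300 nm
for `ex < 290` nm), leaving a triangular unmeasured region (506 of the
1,846 grid cells on the default 71 × 26 grid — a constant frozen in the
tests by direct enumeration of the protocol rule). ALS needs a complete
cube, so `preprocess_cube` fills the triangle: zeros at and below the
first-order Rayleigh line (`em <= ex`), and a linear ramp along the
emission axis from 0 on the Rayleigh line to the first measured
intensity. The ramp is the simplest scheme consistent with
"interpolation above the line, zeros below": it introduces no new
extrema, never touches a measured cell, and keeps every filled value
inside `[0, anchor]`. Whether one interpolates along emission,
excitation, or both is a genuinely open choice; the emission-mode ramp
is this package's documented one, and `rayleigh_halfwidth` widens the
zeroed scatter band for sensitivity checks. No second-order Rayleigh or
Raman handling is implemented — those bands lie outside the measured
region of this protocol entirely.

Because the filled cells are a convention rather than data, they are the
one place where the trilinear model and the completed cube can
systematically disagree; the next section explains how the synthetic
generator accounts for that.

## What the synthetic generator emulates

`generate_design()` reproduces the study layout: 2 cell lines × 6
oxaliplatin dose groups (A375: 0, 5, 50, 250, 500, 1000 µM; HaCaT: 0, 5,
25, 100, 250, 500 µM) × 12 replicates = 144 samples. `viability_map()`
fixes the dose → viability ground truth (A375: 100, 90, 80, 60, 10, 10%;
HaCaT: 100, 90, 70, 65, 50, 10%). Scores are linear in viability with
seeded Gaussian replicate noise (CV 3%), increasing with viability for
components 1, 4, 5 and decreasing for 2, 3; slopes violating these
directions are refused unless explicitly overridden. Optional flags add
a linear per-replicate drift and an inner-filter-like attenuation of
component 3 at the lowest viabilities (both off by default). The MTT
reference (`mtt_reference`) simulates 5 absorbance-ratio replicates per
group (CV 5%) and self-normalizes each cell line so the control mean is
exactly 100%, mirroring the assay's ratio definition.

The five fluorophore prototypes sit at the literature peak positions
(tryptophan-like 290/330, tyrosine-like 280/~315, pyridoxine-like
300/380, flavin-like with bimodal excitation 390 + 440 and emission
520 + 590, NADH-like 360/450 nm ex/em). Band shapes are **bifurcated
Gaussians**: emission bands use σ = 10 nm below and 28 nm above the
maximum, excitation bands the mirror image. This asymmetry is the
physically correct one — fluorophores emit essentially no anti-Stokes
intensity, so emission spectra rise steeply on the blue side and tail
off to the red, while excitation (absorption) spectra cut off steeply on
the red side. It also matters technically: with symmetric bands a
substantial share of the trilinear signal of the short-wavelength
components would fall at or below the Rayleigh line, where the
preprocessing convention inserts zeros, capping the achievable
five-component fit quality near 99.5% explained variance no matter how
small the noise. With the asymmetric (realistic) shapes the excised
region carries negligible trilinear energy, the convention is
self-consistent, and the fit explains ≥ 99.93% of the variance at the
default measurement noise (RMS 0.1% of the signal RMS over the measured
region). The tyrosine-like emission center is set to 315 nm — its exact
position is unresolvable on this grid because the 300–320 nm band is
excised in most columns, which is also why only its approximate position
is asserted anywhere.

What the generator does **not** emulate: inner-filter nonlinearity (the
optional attenuation flag is a caricature), instrument drift beyond a
linear replicate term, scatter ridges (the protocol never records the
scatter region), well-to-well optical-path variation, and any
photophysics (quantum yields, absorbance spectra). Passing tests on
synthetic cubes therefore demonstrate the correctness of the numerics
and the recoverability of the design under the stated noise model — not
that real cell-culture EEMs are exactly trilinear.

## Choosing the number of components

`residual_scan` fits one model per candidate count (default 1–8) and
tabulates SSE, explained variance and the core consistency diagnostic.
`split_half` divides the samples (by cell line by default, matching the
laboratory analysis; any metadata field or explicit halves work), fits
each half independently, and matches components by Tucker congruence
with an exact assignment (greedy matching can pair the wrong components
when profiles overlap). A count passes when every matched pair reaches
congruence ≥ 0.95 in both the emission and excitation modes — 0.95 is
the conventional "equal loadings" bar, configurable. `select_n_components`
then picks the **largest** count that both passes split-half and still
improves explained variance by more than `gain_tol = 0.02` percentage
points over the previous count. On the default synthetic study the gain
collapses from ~1.5 points (4 → 5) to ~0.016 points (5 → 6) and the
split-half congruence of the extra component drops to ~0, so the rule
selects five components; only the quantitative criteria decide — no
visual plausibility judgment is encoded.

## Viability calibration and dose-group statistics

Per cell line, viability is regressed on the five scores by OLS with
intercept (`fit_mlr`); the training target of each sample is the MTT
mean of its dose group, since MTT replicates are separate wells.
Cross-validation is leave-one-out, computed exactly through the
hat-matrix identity and verified in the tests against explicit per-fold
refits. Predictions are deliberately not clipped to [0, 100]
(out-of-range values are flagged), preserving linearity for the
accordance analysis: `accordance_fit` regresses predicted dose-group
means on MTT means and reports slope and intercept with 95% t-based
confidence intervals; the calibration is "ideal-consistent" when 1 lies
in the slope CI and 0 in the intercept CI. An optional `1/sd²` weighting
is available; the default is unweighted, matching how such accordance
lines are usually fitted to group means.

Dose groups are compared with classical one-way ANOVA and equal-variance
Tukey HSD (through `stats::aov`/`stats::TukeyHSD`), flagged `ns` /
`*` (p < 0.05) / `**` (p < 0.01). `accordance_tables` assembles one
significance matrix per source — MTT, each component's scores, the MLR
predictions — and lists every pair on which a score-based source and MTT
disagree; the interesting outcome is MLR discriminating pairs MTT
cannot, while losing none that MTT resolves. Group sizes are taken as
given (MTT n = 5, fluorescence n = 12); nothing is resampled to equalize
them.

## Problem sizes and reproducibility

The default study (144 × 71 × 26) is desk-scale: a ten-start
five-component fit takes well under a minute, the full 1–8 scan plus
split-half validation about three minutes on one core. Unit tests use
smaller cubes (fewer replicates, smaller exact tensors) so the whole
suite stays in single-digit minutes; the full-size selection and fit run
once in the end-to-end acceptance tests. Every stochastic stage is
driven by explicit integer seeds, and `run_pipeline` derives per-stage
seeds from one master seed, so a rerun with the same config is
identical.

## Known limitations

* The filled triangle is a convention; components whose emission
  maxima fall inside or against the excised 300–320 nm band (the
  tyrosine-like one here) have partially unidentifiable peak positions.
* Weighted or missing-data ALS is intentionally absent: preprocessing
  guarantees complete cubes, which is the workflow this package
  implements.
* Scores are assumed linear in viability for the calibration; strongly
  nonlinear regimes (heavy inner-filter conditions, very dense
  cultures) are out of scope.
* ANOVA/Tukey assume equal variances across dose groups; no
  Games–Howell or nonparametric alternatives are provided.
* The intensity scale is arbitrary units throughout; no blank
  subtraction or Raman normalization is applied.
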