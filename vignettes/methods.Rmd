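---
title: "Models and methods behind aestheticfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aestheticfmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aestheticfmri)
```

`aestheticfmri` analyses naturalistic aesthetic-rating fMRI experiments in
which participants watch short movie clips while turning a dial to report
moment-to-moment enjoyment and then give one overall aesthetic judgment per
clip. This vignette explains the statistical models, the choices we made
where the methodology is genuinely open, and what the synthetic-data
generator does and does not emulate.

## The experimental design being modelled

The reference design has 24 participants, 31 analysed movie trials spread
over 4 runs of up to 8 trials (a final short run slot absorbs one dropped
trial), and a fifth set of 7 repeated presentations used to assess
repeatability. Each trial is 10 s fixation, 30 s movie, 4 s response, with
2 s initial and 10 s final blank per run; BOLD is sampled at TR = 2 s, so a
run is 182 scans. Nineteen ROIs span visual (pericalcarine, FFA, LO, hMT+,
OPA, PPA, RSC), default-mode (aMPFC, dMPFC, vMPFC, PCC, IPL) and reward
(NAc, caudate, putamen, pallidum, lOFC, mOFC, maOFC) networks. Dial traces
are recorded at 60 Hz and analysed at 10 Hz; overall ratings live on
[-1, 1] after affine scaling from the device range.

## Inter-rater agreement: MM1 and MM1c

Agreement for overall ratings is the mean-minus-one correlation: for each
rater, the Pearson correlation between their rating vector and the average
vector of all remaining raters. For continuous traces (MM1c) the same
leave-one-out correlation is computed per (participant, movie) and
averaged across movies per participant. Group summaries transform r to
Fisher z = atanh(r), average, build a 95% CI, and transform back.

Two places here are genuinely underdetermined and are exposed as flags:

* **Averaging space for MM1c.** Per-participant averaging across movies is
  done in z space by default (`average_space = "z"`), matching the group
  summary's use of the z scale; `"r"` averages raw correlations.
* **CI construction.** The default CI treats the participants as the
  sample and uses a t-based interval on the z values (`ci_method = "t"`);
  `"se"` uses the per-correlation large-sample SE `1/sqrt(n - 3)` instead.

One property worth stating precisely: a rater's own MM1 score is invariant
to a positive affine transform of *that rater's* ratings (Pearson r is
affine-invariant in each argument). Blanket invariance of the whole set of
MM1 scores does not hold, because rescaling one rater changes the
leave-one-out mean seen by every other rater. The tests check the former.

Undefined correlations (a flat rating vector or flat trace) are recorded
as missing and excluded from group summaries with a warning — never
silently set to 0, which would bias group means toward zero.

## Shared versus individual taste

Using the movies every participant rated twice, total rating variance is
partitioned into a non-repeatable part (presentation-to-presentation
noise) and a repeatable part, and the repeatable part is split into a
shared component (the movie main effect — taste common to everyone) and an
individual component (participant-specific preference). The estimator is
two-way random-effects method-of-moments: with P participants, M repeated
movies and K = 2 presentations,

* error variance = mean of (r1 - r2)^2 / 2 over cells,
* the interaction mean square estimates error + 2 x individual,
* the movie mean square estimates error + 2 x individual + 2P x shared.

Per-participant centering (default on) removes scale-use offsets before
estimation; with centering off, such offsets count as individual taste.
Components are reported signed: noise can push a fraction outside [0, 1],
which is flagged but never clipped, so that group averages of the
fractions stay unbiased.

Because the reported fractions are ratios of noisy variance components,
they acquire a small Jensen-type bias when the movie main effect has few
degrees of freedom (7 repeated movies gives 6). A leave-one-movie-out
jackknife correction (default on) removes the leading term of this bias;
simulations in the test suite show the corrected estimator recovering
generative shared fractions of 0.1/0.5/0.9 with |bias| < 0.05 at 31
repeated movies and remaining unbiased within Monte-Carlo error at the
7-movie scale, where the spread is naturally much wider (SD ≈ 0.15 at a
true fraction of 0.5).

## Quartile appeal levels

Overall ratings are discretized per participant into four appeal levels by
rank: sort the participant's ratings (ties broken by original trial
order), split the ranks into four contiguous blocks with sizes as balanced
as n allows, assigning the larger blocks extremes-first (for n = 31 the
sizes by level are 8, 8, 7, 8 — the short block sits at level 3). A rank
rule guarantees every level is populated, which the appeal-level GLM
requires; equal-width value bins would not.

## ROI activation GLM

ROI-averaged BOLD is analysed per run with a discrete-cosine high-pass at
0.01 Hz, linear detrend and z-scoring, then runs are concatenated. The
design contains one boxcar regressor per appeal level (30 s movie-on
periods), a 4 s response regressor, a 24-parameter motion block (6
parameters, their temporal derivatives, and squares of both), per-run
cosine drift columns, and per-run intercepts. Boxcars are convolved with a
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit
dispersions, undershoot ratio 1/6) on a 10x oversampled grid and decimated
to scan times.

Two numerical conventions matter:

* **HRF scaling.** `canonical_hrf()` is peak-normalized for inspection,
  but convolution uses a unit-integral rescaling, so a sustained block of
  amplitude a plateaus at a and betas keep amplitude units regardless of
  block length or grid resolution.
* **Drift columns in the design.** High-pass filtering the data but not
  the design attenuates task betas, because the level regressors have
  substantial low-frequency content. Including the same cosine basis as
  design columns makes the task betas the matched (filtered-regressor)
  estimates. Without this the 4-vs-1 contrast loses roughly a third of its
  amplitude in our simulations.

Contrasts are movies-vs-baseline (mean of the four level betas by default;
a `sum` flag is available since the aggregation is not uniquely
determined), 4 vs 1, and 4 vs 321 (level 4 minus the mean of the rest).
Group inference is a per-ROI one-sample t-test across the per-participant
contrast effects with Bonferroni correction at 0.05 / n_ROIs. For a
balanced design with participant random intercepts this two-stage
procedure is numerically equivalent to the mixed-model formulation with
random intercepts, which is why no REML fit is needed; the equivalence
holds because the intercepts absorb only between-participant offsets that
the within-participant contrasts eliminate. A beta-series variant fits one
regressor per trial (least-squares-all); on a noiseless balanced design
the per-level means of trial betas equal the level-GLM betas exactly,
which the tests assert.

Baseline is the unmodelled inter-trial fixation (implicit baseline), the
standard convention when only movie and response periods are modelled.

## Trial-wise functional connectivity

Denoising regresses, in a single pass: six aCompCor components with
temporal derivatives, the 24-parameter motion block, one spike regressor
per censored frame (FD > 0.5 mm or DVARS beyond ±3 within-run SD), per-run
linear trends and intercepts, and (by default) HRF-convolved task
regressors with their derivatives. Residuals are then band-pass filtered
0.008–0.2 Hz per run with a zero-phase 2nd-order Butterworth filter
(forward-backward). Censored frames are handled by spike regression before
filtering, not interpolation. Runs with more than half their frames
censored are excluded. Note one honest caveat: after the band-pass stage,
residuals are no longer exactly orthogonal to the raw confounds — the
filter mixes timepoints and a sampling-level correlation of order
1/sqrt(n) can reappear. Exact orthogonality holds at the regression output
(`band = NULL`).

For each movie trial, the timepoints entering connectivity are chosen by
convolving the single-trial boxcar with the HRF and keeping the
k = duration/TR scans with the largest convolved values within
[onset, onset + duration + 16 s] (ties to the earlier scan). For 30 s
trials at TR = 2 s this retains exactly 15 contiguous, lag-shifted scans.
We prefer top-k over literal positive-value thresholding because an
HRF-convolved 30 s boxcar stays positive for more than 15 TRs; top-k
reproduces the intended count and amounts to a hemodynamic-lag shift. The
literal reading is available via `method = "positive-threshold"`.

Per trial, Pearson correlations between all ROI pairs over the retained
uncensored scans are Fisher-z transformed (|r| clipped at 1 - 1e-7 with a
degeneracy flag), giving a trials x edges stack — 31 x 171 for 19 ROIs.
Trials with fewer than 10 usable scans are dropped; the 10-scan floor is
our policy since the interaction of censoring with trial windows is not
standardized. Per edge, the z values are regressed on an intercept, a
linear appeal regressor (standardized overall ratings by default; 4-level
bins by flag) and a quadratic regressor orthogonalized against the linear
one. The per-participant coefficient t-values enter group one-sample
t-tests per edge, with Benjamini-Hochberg FDR at q < 0.05 within each
regressor family. Fitting linear and quadratic terms jointly (rather than
in separate models) is our choice where the convention is ambiguous; with
the quadratic orthogonalized, the linear t is identical either way.

## Time-resolved connectivity: MTD

Multiplication of temporal derivatives: per ROI the first difference
dt(t) = x(t) - x(t-1) is normalized and the raw coupling of a pair is the
product of normalized derivatives, smoothed with a centered 7-point moving
average (window half-width 3, partial windows at the series boundaries).
We normalize by the root-mean-square of the derivative over the
concatenated series rather than the centered SD: for denoised BOLD the
derivative mean is ~0 so the two agree, and the RMS convention makes the
self-coupling series average exactly 1, a useful exactness contract. The
time-mean of raw MTD approximates the Pearson correlation of the
differenced series over long stationary stretches.

Rating-change regressors are built from the 10 Hz traces: the derivative
is smoothed with a 1 s moving average and thresholded at ±0.01 rating
units/s into increasing/decreasing indicators, placed on the session
timeline, HRF-convolved at 10 Hz, and block-mean downsampled to the scan
rate (0.5 Hz). Each participant's MTD series for the three-node subset
(PPA, aMPFC, PCC — 3 edges) is regressed on an intercept plus the two
change regressors, and the per-participant t-values are compared with a
paired t-test (positive vs negative) per edge.

## Gabor-jet motion energy

Each frame is filtered with a bank of complex Gabor kernels (default 5
scales, wavelengths log-spaced 4–32 px; 8 orientations; envelope sigma =
0.56 wavelength) and the complex moduli at a 12 x 12 grid form the frame's
jet. Kernels are made exactly zero-mean by subtracting a scaled Gaussian
envelope, so constant frames give zero jets and the jet is invariant to
global luminance offsets; magnitude (quadrature) responses damp pure phase
shifts. Motion energy is the L2 norm of the jet difference between
consecutive frames (L1 by flag), downsampled to 10 Hz by block means for
correlation with continuous ratings, with per-movie means for overall
ratings. The jet literature fixes none of grid density, scales,
orientations or the difference norm; all are configurable and the defaults
above are the package's documented choice. Tests use a reduced bank
(wavelengths 4/8/16, 6 orientations, 6 x 6 grid) on 48–64 px frames purely
for speed; the properties checked (zero for static stacks, offset
invariance, monotonicity in translation speed up to half the smallest
wavelength) are bank-independent.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth:

* **Overall ratings**: rating(p, m, k) = shared_sd·mu_m +
  individual_sd·tau_pm + error_sd·eps_pmk with iid standard-normal
  latents, so the generative shared fraction is shared_sd² /
  (shared_sd² + individual_sd²). Defaults (0.4 / 1.0 / 0.3) give a mostly
  individual taste profile (shared fraction ≈ 0.14) and leave-one-out
  agreement around 0.3–0.4 — the magnitude regime typical of naturalistic
  video ratings; no published noise magnitudes exist for this design, so
  these are documented package choices, made once. Bounded squashing
  (tanh(x/2.5)) is off by default because it distorts variance fractions.
* **Continuous traces**: shared + private + noise components, each
  low-pass filtered white noise (cutoff 1/smoothness_s), mixed by the
  generator's component sds and normalized into [-1, 1].
* **ROI BOLD**: task signal built through the same convolution code as
  the analysis designs (so noiseless recovery is exact to numerical
  precision); appeal-modulated amplitudes per ROI; optionally
  appeal-modulated noise correlation on named ROI pairs, injected only
  within the retained trial windows (matching what trial-wise FC can
  detect — between-trial noise is independent); AR(1) temporal
  autocorrelation, slow cosine drift, and an fMRIPrep-style confound table
  with occasional motion spikes for the censoring path.
* **Frame stacks**: band-pass noise textures translated by per-frame
  speeds with subpixel Fourier shifts and toroidal wrap.

Randomness uses one root seed with per-participant streams derived by
fixed offsets, so outputs are reproducible and participant-parallel.

What the generator does **not** emulate: voxel-level images, hemodynamic
nonlinearities and saturation, physiological noise spectra, spatial
autocorrelation between ROIs beyond the injected edges, scanner drift
nonstationarity, and rating-device dynamics (haptic stops, reaction lag).
Passing tests therefore establish the statistical machinery — estimator
identities, calibration, power under the stated conditions — not fidelity
to any particular empirical dataset.

## Problem sizes used by the test suite

Simulation-based checks run at the reference scale (24 participants, 19
ROIs, 31 trials over 4 runs) with 100 replicate group analyses for
calibration and power and 200 replicates for taste-decomposition
recovery; oracle comparisons use small randomized fixtures. These sizes
were chosen so the whole suite completes in about ten minutes on one CPU
while keeping Monte-Carlo error well below the margins being tested
(binomial SE ≈ 0.02–0.04 at 100 replicates).

## Known limitations

* The two-stage contrast test is equivalent to the random-intercept mixed
  model only for balanced designs; with missing trials or ROIs the mixed
  model would weight participants differently.
* FDR calibration is assessed under independent-noise nulls; strong
  between-edge dependence (shared ROIs) is handled by BH only in its
  PRDS-robust sense.
* The band-pass/censoring interaction is approximate: spike regression
  before filtering removes censored-frame leverage but filtered residuals
  at neighbouring frames still borrow from the spike window.
* Motion-energy monotonicity in speed holds for translations up to half
  the smallest wavelength; beyond that aliasing in the fine-scale channels
  can make the trace non-monotone.
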