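---
title: "Band-limited Higuchi fractal dimension analysis of event-related EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited Higuchi fractal dimension analysis of event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG is a pooled, strongly non-periodic signal, and linear spectral summaries
miss part of what changes when the brain's state changes. A widely used
nonlinear summary is the **Higuchi fractal dimension (HFD)**: a measure of
the "roughness" of a sampled curve that ranges from 1 (a smooth,
differentiable curve) to 2 (a curve so irregular it begins to fill the
plane). Clinical work on diffuse axonal brain injury uses HFD to compare
resting-state complexity across patient groups and to quantify the change
in complexity evoked by emotionally colored sound stimuli.

This package implements that analysis pipeline end to end - stimulus-locked
epoch assembly, band-pass filtering, the HFD estimator, rest-subtracted
responses on a lateralized 10-20 montage, and the multivariate group
statistics - together with a synthetic cohort generator whose fractal
structure is known and controllable, so every stage is testable without
access to clinical recordings.

## The estimator

For a series $x(1), \dots, x(N)$ and a coarse-graining interval $k$, Higuchi
forms $k$ decimated sub-series (offsets $m = 1..k$) and computes the
normalized curve length

$$L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{\lfloor (N-m)/k\rfloor}
  \lvert x(m+ik)-x(m+(i-1)k)\rvert\right]
  \frac{N-1}{\lfloor (N-m)/k\rfloor\, k},$$

with $L(k)$ the mean over $m$. For a fractal curve $L(k) \propto k^{-D}$;
the dimension is estimated as the OLS slope of $\ln L(k)$ on $\ln(1/k)$
over $k = 1..k_{\max}$, all scales weighted equally (Higuchi's original
prescription). The pipeline default is $k_{\max} = 8$ and 60 s epochs at
250 Hz ($N = 15000$).

Two analytic anchors calibrate the implementation:

* a strictly linear series has $L(k) = (N-1)/k$ *exactly*, so the fitted
  slope is exactly 1 (the suite asserts agreement to $10^{-9}$);
* fractional Brownian motion with Hurst exponent $H$ has dimension
  $D = 2 - H$; with $N = 15000$ the estimator recovers this within a few
  thousandths across $H \in \{0.2, 0.5, 0.8\}$ (the acceptance tolerance is
  0.15, mirroring what can be promised for a single generic estimator
  configuration).

Estimates outside $[1, 2]$ can occur under estimation noise on short
signals. They are reported as computed with a classed warning, never
clipped: silent clipping would bias group means.

The sign convention (regressing on $\ln(1/k)$ rather than $\ln k$) is fixed
so that $D$ is positive; the source analysis does not state which was used,
and the choice only flips the slope's sign.

## Preprocessing choices

**Bands.** Four canonical bands: broadband 2-20 Hz, slow-wave 2-7 Hz,
alpha 8-13 Hz, beta 14-19 Hz. (The source text also contains the remark
that the "filtering frequency range width was 5 Hz", which conflicts with
the 18 Hz broadband width; the four named bands are implemented as written
and the remark is surfaced here rather than guessed at.)

**Filter.** 4th-order Butterworth band-pass applied forward-backward
(zero phase), as a cascade of second-order sections with steady-state
initial conditions and odd reflection padding. Zero-phase filtering is the
standard EEG choice and preserves the waveform shape that the curve-length
sums see. No filter is named in the source; during development the
implementation was cross-checked against an independent reference
implementation (interior agreement ~5e-6 on white noise), and the shipped
tests pin the passband/stopband contract with FFT oracles.

**Epochs.** Each stimulus type contributes 12 scheduled 10 s intervals
(120 s of material); epochs are the chronologically first 60 s after
concatenating the intervals in schedule order. Each contributing interval
is filtered *before* concatenation so that boundary transients from
stitching never enter the epoch interior. The rest epoch is the first 60 s
of the 90 s rest interval. Which 60 s the original study used is unstated;
"chronologically first" is deterministic, and the split-half control (the
HFD of two consecutive 30 s halves agrees within 0.05 on stationary
epochs) supports the view that the choice is immaterial on stationary
material.

**Artifacts.** The pipeline assumes artifact-cleaned input and provides
only an informational amplitude flag (maximal runs exceeding 200 uV,
padded by 0.1 s). Flags warn; they never excise samples, so epoch lengths
stay exact.

## The synthetic cohort: what it emulates, and what it does not

The generator produces 19-channel, 250 Hz recordings: one 90 s rest
interval, then the 72 stimulus intervals (6 types x 12 repetitions,
10 s each) in seeded random order with 2 s unanalysed rest-like gaps
(inter-stimulus timing is not described in the source; 2 s is a
conventional value and gaps never enter any epoch).

**Why not plain fBm per state.** The classical calibration of the Higuchi
estimator is fBm, where $D = 2 - H$. But a single-exponent process cannot
encode the group structure of interest: band-filtering fBm moves the
complexity of *every* band monotonically in the same direction as $H$,
whereas the emulated findings require opposite orderings in different
bands (severe injury highest in broadband at rest, controls highest in the
alpha band at rest). The cohort generator therefore synthesizes stationary
Gaussian noise with a **piecewise power-law spectrum** over 2-20 Hz:

* the *broadband* Hurst target sets the coarse spectral tilt - how total
  power is apportioned among the slow/alpha/beta chunks - which governs
  the broadband-filtered HFD;
* each sub-band's Hurst target sets the in-band slope
  $S(f) \propto f^{-(2H_b+1)}$, which - because HFD is invariant to
  amplitude scaling - is the *sole* determinant of that band-filtered HFD.

Every band's filtered dimension is thus a monotone function of its own
target, with analytically known direction. Pure fBm (`gen_fbm()`, exact
Davies-Harte circulant embedding) remains available and is what the
dimension-law validation uses.

**Default targets.** Chosen once, as plausible EEG-scale effects, to encode
the qualitative findings being emulated: at rest, broadband $H$ = 0.70 for
control and mild injury vs 0.55 for severe (severe most complex
broadband); alpha-band $H$ = 0.45 / 0.55 / 0.65 for control / mild /
severe (control most complex in alpha, mild intermediate). Under
stimulation the broadband target drops by 0.06 for control and mild
(complexity rises relative to rest) and rises by 0.08 for severe
(complexity falls), scaled per stimulus type (strongest for "laughter",
weakest for "unpleasant noise"). Left-hemisphere channels are offset by
0.04 toward lower $H$ *during stimulation only*, so both raw stimulus HFD
and rest-subtracted responses show the left > right asymmetry (an offset
also present at rest would cancel in the subtraction). A per-subject
$N(0, 0.03)$ Hurst offset shared across states provides between-subject
variability; signals are scaled to a 15 uV standard deviation so EDF files
look physiologically plausible (HFD itself is amplitude-invariant).

**What a green test does not establish.** The generator makes no attempt at
real EEG microstructure: no 1/f background outside 2-20 Hz, no spindles,
eye blinks, muscle artifacts, volume conduction, or channel covariance
(channels are independent given the targets). Recovery of the encoded
orderings demonstrates that the *pipeline* measures what the generator
encodes - it is a software validation, not evidence about brains.

## Statistics

* **Rest subtraction:** $\Delta$HFD = HFD(stimulus) - HFD(rest) per
  (subject, band, channel).
* **MANOVA:** Wilks' $\Lambda = \det(E)/\det(E+H)$ from the within/between
  SSCP matrices, converted to $F$ by Rao's approximation (exact for the
  three-group designs used here, since $\min(p, q) \le 2$ or $q = 2$),
  with partial $\eta^2 = 1 - \Lambda^{1/s}$. The default response set -
  per subject, the mean HFD per state across the 16 lateral channels
  (7 responses) - is recorded in the run config; the "21 independent
  variables" of the source design cannot be reconstructed from its text,
  so the response construction is exposed as an explicit, configurable
  choice.
* **Corrected alpha:** thresholds are the family residual divided by the
  number of comparisons, rounded as conventionally printed (3 decimals;
  1 significant digit below 0.001): 0.017 for 3 comparisons, 0.003 for 18,
  0.0003 for 162 at the 0.05 default.
* **Assumption checks:** Levene's test (mean-centered, with the
  median-centered Brown-Forsythe variant available - the source names only
  "the Leuven test") and a Lilliefors-corrected Kolmogorov-Smirnov
  normality test. Because the normal parameters are estimated, the KS null
  distribution is obtained by seeded Monte Carlo (cached per sample size)
  rather than an analytic approximation whose published coefficients could
  not be independently verified in this environment.
* **Post-hoc:** Tukey HSD (pooled variance), Games-Howell (Welch-adjusted
  studentized range, for unequal variances), two-sided Dunnett many-to-one
  comparisons with critical values from the multivariate-t null by seeded
  Monte Carlo ($10^5$ draws by default), and Bonferroni-adjusted pairwise
  t. Each band is analysed separately with its own corrected alpha.

## Numerical and degenerate-input policy

* Constant signals raise a classed `fe_degenerate_error` (curve lengths
  vanish; a silent sentinel would propagate NaNs into group means).
* Singular within-group SSCP matrices raise `fe_rank_error`, suggesting
  response reduction, rather than pseudo-inverting.
* `run_pipeline()` refuses a non-empty output directory without `force`,
  writes all outputs atomically (temp + rename), stamps them with a hash
  of the scientific config (the output path is excluded from the hash so
  identical configs are bit-identical across locations), and derives every
  sub-seed from the master seed via one documented splitting scheme.
* With very small cohorts the default MANOVA is infeasible (error df
  below the response count); the stats stage records a `stats_skipped`
  event and completes rather than failing the whole run.

## Known limitations

* The synthesis spectrum lives on a padded power-of-two frequency grid
  (the first $n$ samples of the periodic realization are used); spectral
  resolution therefore differs slightly from the natural interval grid
  used by the exported `gen_band_noise()` primitive.
* Narrow-band HFD differences are intrinsically small (the estimator's
  lag window at 250 Hz probes time scales shorter than one alpha cycle),
  so alpha-band group effects, while reliably ordered, are an order of
  magnitude smaller than broadband ones - matching the general experience
  that band-limited HFD compresses dynamic range.
* Channel-level dependence (volume conduction) is not modelled, so
  channel-as-observation analyses on synthetic cohorts are optimistic
  relative to real EEG; the shipped analyses use subjects as observations.
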