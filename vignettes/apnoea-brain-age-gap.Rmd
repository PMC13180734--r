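---
title: "Methods: apnoea rate and the EEG brain age gap in preterm infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apnoea rate and the EEG brain age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question and the model

Apnoea of prematurity is a cessation of breathing caused chiefly by
immaturity of the infant's nervous system. Caffeine treatment is prescribed
and withdrawn on age-based guidelines, yet infants of the same
postmenstrual age (PMA) differ widely in neural maturity. The analysis this
package implements treats the *brain age gap* — the difference between an
EEG-derived brain age and PMA, after removing the systematic linear
dependence of predicted age on true age — as a candidate marker of that
individual maturity, and tests two hypotheses on a repeated-measures cohort
of moderate-to-late preterm infants (31–36 weeks PMA, ~74 infants on ~138
test occasions):

1. apnoea rate (apnoeas/h) depends on the brain age gap but not on PMA,
   whereas respiratory rate (breaths/min) depends on PMA but not on the gap;
2. after caffeine is discontinued, infants with an immature gap (< 0 weeks)
   have more apnoeas and oxygen desaturations than infants with a mature
   gap (> 0 weeks).

The statistical model for hypothesis 1 is a linear mixed-effects model per
outcome/predictor pair,

$$y_{ij} = \beta_0 + \beta_1 x_{ij} + \gamma^\top z_{ij} + u_i +
\varepsilon_{ij},$$

with occasion $j$ of infant $i$, a random intercept $u_i$ for the repeated
occasions, and fixed covariates $z$ (recording data length for the apnoea
models; infection status for all models). Alongside the slope we report a
partial correlation (correlation of the covariate-adjusted residuals of $y$
and $x$), a one-tailed bootstrap comparing the gap's partial correlation
with the PMA's, and E-values for unmeasured confounding.

# Pipeline stages, parameters and rationale

## Respiration (impedance pneumography, 62.5 Hz)

* **Band-pass 0.1–2 Hz**, zero-phase (forward–backward) Hamming
  windowed-sinc FIR, 801 taps. The band retains neonatal breathing
  (10–120 breaths/min) and suppresses baseline wander and the cardiac
  artifact (~2.3 Hz ≈ 140 bpm): measured attenuation at 2.3 Hz exceeds
  99%, and the input is demeaned so DC is removed exactly.
* **Breath detection**: local maxima of the filtered signal accepted when
  their height exceeds **0.4 × SD of the signal spanning the preceding 15
  detected breaths**; before 15 breaths exist the SD is bootstrapped from
  the first 15 s (the cold-start rule is not fixed by the published
  description; this choice is documented and tested). A 0.25-s refractory
  period suppresses double-counting within a cycle.

  The amplitude criterion is applied to *peak height* of the band-passed,
  zero-baseline signal rather than to peak prominence. For a sinusoid-like
  train of amplitude $A$, the windowed SD is $\approx 0.35A$, so the
  threshold is $\approx 0.14A$: peak height (≈ $0.5A$ normally, $0.1A$ in a
  0.2× shallow segment) separates normal from shallow breathing at this
  threshold, whereas peak prominence (peak-to-trough, $0.2A$ when shallow)
  would not. The high-pass edge already removes the baseline wander that
  prominence would otherwise guard against.
* **Apnoeas**: candidate events are inter-breath intervals (IBIs) *strictly*
  longer than 15 s, measured onset-to-onset; an IBI of exactly 15.0 s is
  not a candidate. A linear-kernel SVM labels each candidate `apnoea` or
  `rejected_noise_or_shallow` from three scale-invariant window features
  (log RMS ratio and log SD ratio of the gap vs. its ±15-s context, and the
  in-gap respiratory-band power fraction). The published classifier's
  weights are unavailable, so the classifier is retrained on labelled
  synthetic segments; its feature set is our choice and is documented as
  such. Rejected candidates are removed from the IBI pool entirely — they
  contribute neither to the apnoea count nor to the median IBI.
* **Rates and QC**: respiratory rate = 60 / median IBI; apnoea rate =
  validated apnoeas per hour of IBI data; recordings with fewer than 100
  IBIs fail QC and are excluded.

## Desaturation (SpO2, 0.97 Hz)

An event is a maximal contiguous run of samples strictly below 80%
saturation lasting at least 10 s — one event per run, not overlapping
10-s windows, so the count yields the event rate the analysis reports.
Missing samples break runs. The alternative window reading is exposed via
the run-length parameters.

## Sensory-evoked brain age

Zero-phase Butterworth high-pass at 0.05 Hz (order 2) then low-pass at
33.75 Hz (order 4) retain the 0.1–30 Hz band. Epochs span −0.5 to 1.0 s
around stimulus onsets (visual on Oz, tactile on Cz) and are baseline
corrected by the mean over [−0.5, 0) s. Epochs whose pre-stimulus amplitude
strictly exceeds ±150 µV are rejected; an occasion with fewer than five
surviving epochs has no sensory estimate and falls back to the resting
model. The rejection window is the available pre-stimulus span (−0.5 to
0 s); a full −1 to 0 s window is incompatible with the epoch start and we
do not guess which convention generated any particular dataset.

Woody alignment shifts each epoch by the integer-sample lag (|lag| ≤ 50 ms)
that maximises its cross-correlation with a template, in one pass. The
template is the projection of the current epoch average onto the
modality's NRF subspace — alignment "to the NRFs" without committing to a
single component. Slopes are then ordinary least squares of the epoch
*average* onto the modality's NRFs jointly (4 visual + 2 tactile = 6
coefficients); fitting each epoch and averaging the slopes is available as
a switch (`per_epoch = TRUE`) and is identical for an orthonormal basis
without jitter. The six slopes feed a linear-kernel support vector
regression to age; accuracy is reported as k-fold cross-validated MAE.

The published NRF waveforms (derived elsewhere by principal component
analysis of real evoked responses) are not shipped; `make_nrf_basis()`
builds a deterministic orthonormal stand-in (Gaussian-windowed
Hermite-type bumps at staggered post-stimulus latencies, QR-orthonormalised
with a fixed sign convention). Real-data users must supply the published
basis on the same grid.

## Resting-state brain age (surrogate)

The published resting-state estimator is a pretrained deep network that is
not redistributable; the surrogate preserves its input/output contract —
first 20 min of stimulus-free bipolar C3–C4 at 64 Hz, 30-s epochs, a
10-member ensemble, median over members per epoch then median over epochs —
with transparent members: closed-form ridge regressions (penalty λ = 1 on
standardised features) over eight per-epoch features chosen for neonatal
maturation plausibility (relative power in 0.5–3 / 3–8 / 8–15 / 15–30 Hz,
95% spectral edge, 5th/95th amplitude percentiles, burst fraction from a
1-s RMS envelope). Members are fitted on bootstrap resamples of the
training recordings. All accuracy claims about this stage are
surrogate-level claims, not claims about the published network. Recordings
shorter than 20 min have no resting estimate and rely on the sensory model.

## Brain age gap

The combined brain age is the mean of the available estimates (either one
alone when the other is unavailable). The corrected gap is the residual of
OLS of combined brain age on PMA. The published bias-correction narrative
(predict PMA, subtract the bias) is ambiguous about the regression's
direction; the residual construction is the standard age-bias correction
and provably delivers the stated property that gap and PMA are *exactly*
uncorrelated (and zero-mean), and is invariant to affine perturbations
$a\cdot\mathrm{PMA}+b$ of the brain ages. `bias_correct(..., correct =
FALSE)` disables the correction. Maturity is `mature` iff gap > 0; a gap of
exactly 0 is assigned `immature` (arbitrary but fixed and tested).

## IBI probability densities

Per recording: a histogram of IBIs at 0.1-s resolution on [0, 50) s (IBIs
longer than 50 s removed), scaled to unit area. Conditional densities on a
1-day grid over PMA 31–36 weeks or gap −3 to +3 weeks use Gaussian weights
with FWHM 13 days (σ = 13/(2√(2 ln 2)) days), hard zero beyond 14 days.
Per bin, the *lower weighted median* (smallest value whose cumulative
normalised weight reaches 0.5) combines the recordings; the exact
interpolation convention of the original weighted-median reference is not
printed, so this convention is fixed and tested against a brute-force
oracle. Weighted medians of unit-area curves need not integrate to one, so
each conditional density is renormalised afterwards — preserving the
unit-area presentation. Grid points with no recording within 14 days are
left empty.

## Statistics

* Mixed models via `lmer` (Satterthwaite p-values, Wald CIs). Constant
  covariates are dropped so degenerate synthetic designs still fit; apnoea
  responses are left on the linear scale (matching the published modelling
  choice), with zero-inflation acknowledged as a limitation.
* Partial correlation: residual-on-residual after regressing outcome and
  predictor on the fixed covariates at occasion level (the published report
  gives no formula; the random effect is not conditioned on). Fisher-z CIs.
* Bootstrap comparison: occasions are resampled with replacement 10,000
  times; p = fraction of bootstrap partial correlations ρ̂*(apnoea, PMA)
  that are ≤ the observed ρ̂(apnoea, gap), one-tailed at α = 0.05.
  Degenerate resamples are redrawn and counted. An infant-level cluster
  bootstrap is available behind `cluster = TRUE` (the published text does
  not state cluster resampling).
* E-values: E = RR + √(RR(RR−1)) with reciprocal mapping below 1; the CI
  E-value uses the limit closest to the null and is 1 when the CI crosses
  it. The partial-correlation-to-RR conversion (d = 2ρ/√(1−ρ²),
  RR = exp(0.91·d)) is one convention among several; published E-value
  numbers are not reproducible from printed information and are not
  treated as checks.
* Caffeine-stop: OLS of stop-PMA on the gap assessed within two weeks
  before stopping, with infection as fixed factor (no data-length
  covariate). Post-caffeine comparison: group means ± SD only, no test.

# What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* the analysis assumes,
with every parameter fixed up front at values typical of this population:

* Cohort: 74 infants, 1–3 occasions each (~138 total), PMA uniform on
  31–36 weeks; infection frequencies (0.44, 0.12, 0.44); IBI data length
  gamma-distributed with mean 8.5 h, truncated to [0.4, 24] h.
* Latent gap: marginal N(0, 0.91²) weeks, split into an infant-level
  component and occasion-level jitter (SD 0.45 weeks) so repeated occasions
  correlate — required for the caffeine-stop analysis, whose stop age
  follows 34 − 0.26 × infant gap + noise (SD 0.8 weeks).
* Outcomes: expected apnoea rate = max(0, 0.8 − 0.22 × gap + infant effect
  [SD 0.25]); observed counts Poisson over the data length. Respiratory
  rate = 60 − 1.87 × (PMA − 33.5) plus noise (SD 2 breaths/min). The
  baseline of 0.8 apnoeas/h keeps truncation at zero rare (< 1%), so the
  generating slope is recoverable by linear models.
* IP morphology: raised-cosine breath cycles, multiplicative log-normal
  amplitude drift, 10% cardiac contamination at 2.3 Hz, white noise;
  apnoeas are breath-free gaps from a thinned Poisson process with
  durations 15 s + Exp(mean 5 s); shallow-breathing segments scale the
  local amplitude. Desaturations co-occur with half of the apnoeas plus
  independent events.
* Evoked EEG: epoch = Σ slopeₖ(age)·NRFₖ + jitter + noise, with linear
  slope-age gradients, per-occasion slope deviations (SD 24 a.u. against
  gradients of ~30 a.u./week), ~10% artifact epochs. Resting EEG:
  burst/inter-burst alternation whose inter-burst mean shrinks linearly
  with age (6 s at 31 weeks to ~1 s at 36) and whose slow/fast amplitude
  ratio tilts with age.

The waveform morphologies and the maturation laws are *synthetic
conventions*, not physiology: no raw-signal exemplars are published for
this design. Passing recovery tests therefore demonstrates that the
algorithms recover what they are defined to recover under the assumed data
structure — breath trains with amplitude-coded events, linear maturation,
Gaussian noise — not that they are robust to real-world artifacts
(electrode movement, obstructive apnoeas, sleep-state structure, monitor
dropouts), none of which are modelled. Post-caffeine vitals are generated
as monitored event-rate summaries (Poisson counts over monitored hours),
not as week-long raw traces.

# Numerical choices and degenerate inputs

* All generators and fits are pure functions of (parameters, seed); a
  global seed fans out to per-recording substreams, so adding a recording
  never perturbs the others.
* Filters: `filtfilt` throughout (zero phase, squared magnitude response);
  the IP filter errors on signals shorter than three filter lengths.
* Weighted median ties: the lower median is taken (first value reaching
  cumulative weight 0.5).
* Bias correction requires ≥ 3 occasions and non-constant PMA; errors
  otherwise. `combine_ages` errors when both estimates are unavailable.
* Degenerate bootstrap resamples (constant predictor, rank-deficient
  covariates) are redrawn and counted.
* Resting-age aggregation uses medians at both levels, so a single
  corrupted epoch or a minority of corrupted ensemble members moves the
  output by at most one order statistic.

# Problem sizes used by the tests and drivers

The shipped analyses run at the study scale (74 infants / ~138 occasions)
for the pipeline itself, with signal windows of 15 min of IP per occasion,
20 stimulus epochs per modality at 250 Hz, and 21 min of resting EEG
generated directly at 64 Hz — sizes chosen so the full pipeline completes
in about two minutes while every stage still sees realistic event counts.
Calibration simulations use 200 cohort replicates (slope coverage), 500
permutations (type-I error), and 150 replicates of a 300-rep bootstrap
(comparison calibration); the classifier benchmark uses 30–80 windows per
class. Larger sizes change none of the qualitative conclusions.

# Known limitations

* The one-tailed bootstrap comparison (fixed ρ̂_gap vs. the bootstrap
  distribution of ρ̂_PMA) is **anti-conservative** when the two predictors
  are independent with equal true association: the difference of two
  near-independent estimators has variance ≈ 2σ², so the nominal 0.05 test
  rejects at ≈ Φ(−1.645/√2) ≈ 0.12. Our calibration simulation reproduces
  this (~0.12–0.14). The implementation follows the published definition
  verbatim; a calibrated alternative would bootstrap the *difference* of
  the two partial correlations, which is deliberately not substituted.
* The resting-state stage is a surrogate: it preserves the published
  model's contract and aggregation, not its representation learning; its
  MAE on synthetic data says nothing about the deep network's accuracy.
* Estimated gaps are shrunken towards the cohort mean (regularised
  regression), so gap SDs from the pipeline sit below the generating SD
  and slopes on the estimated gap are correspondingly inflated relative to
  slopes on the latent gap — a generic errors-in-variables effect of
  brain-age pipelines, visible here because the truth is known.
* Only central apnoeas are detectable from impedance pneumography;
  obstructive apnoeas, bradycardia coupling and sleep states are out of
  scope.
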