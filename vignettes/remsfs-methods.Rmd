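---
title: "Fragility Score estimation and evaluation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility Score estimation and evaluation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the score

Radiofrequency Echographic Multi Spectrometry (REMS) analyses the raw,
unfiltered RF echoes backscattered by vertebral or femoral-neck bone during
an ordinary ultrasound scan. Beyond a densitometric T-score, a REMS scan
yields the **Fragility Score (FS)**: the percentage of analysed RF signal
segments whose frequency spectrum correlates better with a reference
spectral model built from *fractured* subjects than with the corresponding
model from *non-fractured* subjects, averaged over the regions of interest
(four lumbar vertebrae, or the femoral neck). FS is designed to capture
bone *quality* — micro-architectural integrity — largely independently of
bone mineral density, and to predict incident fragility fractures over a
short (up to 5-year) horizon.

This package implements the full chain — RF simulation with known ground
truth, FS computation, and the diagnostic-accuracy statistics used to
evaluate a fracture-risk marker — so that every stage is testable without
access to clinical data, which are not publicly deposited.

## The synthetic cohort generator

`generate_cohort()` defines the study conditions. For subject $i$:

* **Covariates.** Sex with a default 71.5% female fraction; age truncated
  normal on [30, 90] years (women $N(60, 9)$, men $N(61, 15)$); height and
  weight normal per sex, BMI derived. These reproduce the cohort's
  descriptive medians and fall inside the reported interquartile ranges;
  that property is tested.
* **Latent fragility.** $f_i = \mathrm{logit}^{-1}(a_{0,\mathrm{sex}} +
  0.5\,(\mathrm{age}_i-60)/10 + \varepsilon_i)$ with
  $\varepsilon_i \sim N(0, 0.8)$ and intercepts $-0.80$ (F) / $-1.15$ (M).
  The intercepts put the median FS near 31 (women) and 24 (men), matching
  the observed lumbar medians.
* **T-scores.** A common BMD latent is correlated 0.45 with the
  standardized fragility driver; DXA and REMS T-scores are two noisy
  readouts of it (measurement SD 0.35). FS therefore carries signal that
  the T-scores cannot fully explain — the core claim under test.
* **Fracture link.** $\Pr(\text{fracture}) = \mathrm{logit}^{-1}(\alpha +
  4 f_i + 0.06\,(\mathrm{age}_i - 60))$. The intercepts
  ($\alpha = -3.59$ lumbar, $-5.47$ femur) were solved numerically once so
  that default cohorts reproduce the observed 5-year incidences of about
  13.7% (major osteoporotic, lumbar analysis) and 2.9% (hip, femoral
  analysis). Follow-up is uniform on 2–5 years; fracture types are major
  osteoporotic for lumbar cohorts and hip-only for femoral cohorts.

Every generator is a pure function of its arguments and a seed;
`derive_seed()` fans one workflow seed out to independent stages.

## The RF scan model

`simulate_rf_scan()` is phenomenological — no wave-propagation physics.
Each scan line holds, at a known depth, a bright specular interface echo (a
Gaussian-windowed 3.5 MHz tone burst, amplitude 8 relative to unit
speckle), and below it a 192-sample backscatter block of coloured Gaussian
speckle. Per line, independently, the speckle is shaped by the *frail*
spectral template with probability $f$ and by the *non-frail* template
otherwise; white acquisition noise (relative SD 0.3 by default) is added.
Because template choice is per-line Bernoulli rather than within-line
mixing, $E[\mathrm{FS}] = 100 f$ up to classification error — a clean
recovery target.

The templates (`spectral_templates()`) are unit-normalised magnitude
spectra: the non-frail template is a Gaussian band centred at the probe's
3.5 MHz nominal frequency (SD 0.8 MHz); the frail template is down-shifted
to 2.7 MHz with a steeper high-frequency roll-off (SD 0.45 MHz above the
centre), a proxy for the spectral signature of degraded trabecular
micro-architecture. An `"orthogonal"` pair with disjoint bands exists for
exact-recovery tests: with it and zero noise, a segment can never correlate
better with the wrong model, so FS/100 equals the realised frail fraction
exactly.

Geometry: 16 MHz sampling (one sample = 48.1 µm of depth at 1540 m/s),
1024 samples per line (≈4.9 cm image), interface no deeper than sample
400 so that at least 3 cm of image remains below the bone surface, as in
the clinical acquisition protocol. Lumbar scans have 128 lines in four
contiguous vertebral ROIs (L1–L4, 80 s acquisition), femoral scans 64
lines in one femoral-neck ROI (40 s).

Repeated scans (`simulate_repeat_scans()`) keep the patient's tissue
realisation fixed — latent fragility, per-line template choices and
baseline speckle do not change between scans — and perturb around it:
interface-depth jitter and partial speckle re-realisation with weight
`perturbation_sd`, fresh additive noise per repeat, and, when several
operators are involved, an operator-specific speckle component of weight
`operator_sd` representing probe-handling differences. Weights mix
orthogonally ($\sum w^2 \le 1$), so unperturbed repeats are bit-identical
and each added component strictly increases repeat-to-repeat variance.

## The reference database

Reference models are stratified exactly as the clinical database: sex ×
5-year age bin ([30,35) … [85,90], with age 90 folded into the last bin) ×
BMI class (<18.5, [18.5,25), [25,30), ≥30 kg/m²) × site, with 100 subjects
per category, half fractured and half not. Synthetic reference subjects
are pure exemplars (fractured at $f=1$, non-fractured at $f=0$); each
subject contributes the mean spectrum of their scan's accepted segments,
and the stratum model is the re-normalised per-bin mean. Stratum lookup is
exact on the four-part key; a missing stratum is an error, never a
fallback to a neighbouring bin — a patient on a bin edge belongs to the
bin containing their age (half-open intervals). No per-stratum spectral
variation is simulated, so stratification here exercises the bookkeeping
and lookup contract rather than an age-dependent spectral effect.

## The FS pipeline

1. **Envelope** (`envelope_image()`): per-line analytic-signal magnitude
   via FFT half-spectrum doubling, compressed with `log1p` (monotone,
   maps zero to zero).
2. **Interface segmentation** (`segment_bone_interface()`): per line, the
   strongest envelope peak below a 100-sample near-field margin;
   confidence is the peak relative to the line median; if more than half
   the lines have no sample above 3× their median, there is no interface.
   A width-5 running median smooths the trace.
3. **ROI selection** (`select_roi()`): the half-open window
   `[depth + 8, depth + 136)` (0-based samples) strictly below the
   interface, one segment per line with confidence ≥ 3, labelled by the
   line's ROI.
4. **Spectrum** (`compute_spectrum()`): Hann-windowed periodogram,
   zero-padded to the next power of two ≥ 4× the segment length,
   restricted to the analysis band [fc/2, 2 fc] = [1.75, 7] MHz and
   normalised to unit area. Welch averaging is deliberately not used: the
   128-sample segments are too short to split.
5. **Classification** (`classify_segment()`): Pearson correlation of the
   band-limited magnitude vector with each stratum model; *frail* iff the
   frail correlation strictly exceeds the non-frail one. Ties go to
   non-frail, so ambiguity never inflates fragility. Pearson correlation
   makes the classification invariant to positive amplitude rescaling.
6. **Aggregation** (`fragility_score()`): per-ROI percent frail, then the
   unweighted mean over ROIs regardless of segment counts.

`score_patient()` composes the five steps (with an internal batched FFT
path that is tested to be numerically identical to the per-segment
estimator); one composite scan per site is assumed. With the default
templates and noise, the end-to-end misclassification rates measured on
pure-template patients are below 2% in both directions, so measured FS
tracks $100f$ with a recovery slope close to 1 (tested within [0.9, 1.1]
at 500 lines, noise off, and mean absolute recovery error within 5 FS
points over $f \in \{0, 0.25, 0.5, 0.75, 1\}$).

## Diagnostic evaluation

All statistics operate on a `marker_series`, which carries the marker's
orientation: FS is higher-is-positive, T-scores lower-is-positive (scores
are negated internally, and thresholds mapped back for reporting; the
conventional osteoporosis rule "T-score ≤ −2.5" becomes "oriented score ≥
2.5").

* **Group comparison**: median/IQR (type-7 quantiles) and the
  Mann–Whitney test — exact by enumeration when both groups have ≤ 8
  observations (enumeration handles ties, which the classical exact
  distribution does not), otherwise the normal approximation with midrank
  tie correction.
* **ROC/AUC** (`roc_curve()`): thresholds at the unique score values with
  the ≥ call rule; trapezoidal AUC, equal to the pair-counting
  concordance with ties counted ½ (tested as an invariant). Per-subject
  placement values are stored as the structural components of the DeLong
  variance estimator.
* **DeLong test** (`delong_compare()`): variance of the paired AUC
  difference from the placement components; two-sided normal p. The
  degenerate self-comparison returns p = 1 exactly.
* **Cut-off** (`optimal_cutoff()`): Youden's J, the standard reading of
  "best trade-off between sensitivity and specificity"; ties break to the
  smallest oriented threshold so the reported cut-off is the most
  inclusive one attaining the maximum.
* **2×2 metrics**: sensitivity, specificity, PPV, NPV as percentages at
  full precision (rounding is presentation-only, half away from zero);
  zero denominators yield `NA` with a warning, never a silent 0.
* **Odds ratio**: cross-product ratio with the Woolf (log-scale Wald)
  interval; a single zero cell triggers the Haldane–Anscombe +0.5
  correction and is flagged; two zero cells in one margin are degenerate.
* **Covariate adjustment** (`covariate_adjust()`): ordinary least squares
  of the score on age and BMI *fitted on the non-fractured subjects
  only*; every subject's adjusted score is their residual. Among the
  readings of "adjustment through linear fitting", this residual approach
  is the one that answers "what does the marker add beyond the
  covariates' normal-population trend", and it can legitimately push an
  adjusted AUC below 0.5 when a marker's apparent performance was carried
  by the covariates.
* **Reconstruction** (`confusion_from_rates()`): published sensitivity
  and specificity plus group sizes determine the integer 2×2 table by
  nearest-integer rounding; the published predictive values and odds
  ratios then follow arithmetically. This is how the package's acceptance
  checks tie computed values to printed ones without patient data.

## Precision

`rms_cv()` implements the densitometric convention: per-patient CV with
the sample (k−1) SD, root-mean-square across patients, and — for "at 95%
confidence level" — the one-sided upper bound from the χ² distribution of
the pooled relative variance with $m(k-1)$ degrees of freedom. Both the
point estimate and the bound are reported, since the clinical phrasing is
ambiguous between them. `run_precision_experiment()` reproduces the
15-patient × 3-repeat design (45 cases per site and arm). The simulated
RMS-CV magnitudes (a few percent with default settings) are *not*
calibrated to the clinical sub-1% values: real-hardware variability is
not modelled, and only the structural properties (zero under no
perturbation, scale invariance, inter ≥ intra in expectation) are claimed.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything from scratch at
these sizes, chosen to keep the full run in the minutes range on one CPU:
the headline study uses one lumbar cohort of 1804 patients scored through
the RF pipeline against a database of ~90 strata × 100 reference subjects;
recovery uses 500-line noise-free scans, 8 patients per $f$ value;
the Mann–Whitney enumeration oracle uses 4+4; the DeLong permutation
oracle uses 10⁵ swaps at n = 40; the operator-effect Monte-Carlo uses 50
replicates of an 8-patient design with the operator component deliberately
dominant. Unit tests use a reduced 16-line geometry, which preserves every
depth constraint of the full one.

Numerical conventions: 0-based sample indices with half-open windows;
depth increases with sample index; seeds are 32-bit; doubles serialise at
17 significant digits so containers round-trip exactly.

## What passing tests do and do not show

The generator emulates the *structure* of the clinical study — covariate
distributions, incidence, a BMD-independent fragility signal, stratified
reference models, repeat-scan designs — not its physics or its exact
effect sizes. Published headline AUCs (e.g. 0.811 for women at the lumbar
spine) depend on the unavailable patient data and are not reproduction
targets; what the package demonstrates is the qualitative claim under
known ground truth: FS, scored through the full spectral pipeline,
significantly out-predicts both simulated T-scores (DeLong p ≪ 0.05 at
study scale), survives age/BMI adjustment with the same ordering, and
recovers the latent fragility it was designed to measure. The
arithmetic-level results — odds ratios, Woolf intervals, predictive
values, incidence percentages reconstructed from printed rates and counts
— are exact and are checked to printed precision.

Known limitations: phenomenological spectra (no k-space/FDTD simulation,
no attenuation or diffraction); a flat interface per scan; one composite
scan per site rather than a frame sequence; no per-stratum spectral
differences; no survival modelling of the time-to-event column; and no
attempt at the vendor's proprietary segmentation, artifact rejection or
spectral features.
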