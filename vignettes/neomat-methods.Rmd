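---
title: "Quantifying preterm EEG maturation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying preterm EEG maturation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The EEG of extremely preterm infants (born before 28 weeks of gestation) is
dominated by *tracé discontinu*: short high-amplitude bursts of activity —
spontaneous activity transients (SATs) — separated by long, deeply
suppressed interburst intervals (IBIs). As the brain matures, activity
becomes more continuous (SAT% rises, IBIs shorten), faster frequencies
appear, and the signal becomes more complex. `neomat` turns 2-channel
bedside aEEG/EEG recordings (bipolar F3-P3 and F4-P4, 256 Hz) into twelve
quantitative maturational features, relates them to postmenstrual age (PMA)
with a mixed-effects brain-age model, and relates early-EEG features and
their per-subject maturation slopes to MRI-derived structural brain metrics
with partial correlation and multiple regression. A two-tier synthetic
cohort generator provides ground truth so every stage is testable without
patient data.

## Signal chain

**Filtering.** Recordings are band-passed 2–40 Hz: a linear-phase Hamming
windowed-sinc FIR high-pass at 2 Hz followed by an FIR low-pass at 40 Hz,
each with a 1 Hz transition band and applied forward–backward for zero
phase, plus a zero-phase second-order IIR notch at 50 Hz (Q = 30) for line
interference. The 2 Hz high-pass reflects the bedside monitors' analogue
front end; it means the 0.5–2 Hz part of the delta band is unavailable,
which is why all relative powers use a 2–30 Hz reference band (see below).
The filter needs at least one filter length (847 samples at 256 Hz) of
signal; passband gain is within ±0.5 dB over 3–38 Hz, and filtering twice
changes passband RMS by <2%.

**Epochs and quality flags.** Analysis runs on 1-h epochs. Clinical
practice selects epochs visually; here a programmatic stand-in rejects an
epoch when more than 20% of its samples are flat (derivative exactly zero
for >1 s) or clipped at the amplitude rail. For a multi-day recording the
best clean epoch (lowest artifact fraction) of each 24-h day is used, up to
three — mirroring the protocol of one representative hour per day of an
initial 72-h recording; shorter recordings contribute their single best
epoch. A recording shorter than one epoch yields one epoch of its true
duration. All window lengths are specified in seconds, so recordings not
sampled at 256 Hz remain analyzable (with a warning).

**Features.** Three families, all computed per channel and then averaged
(features, not signals) over segments → epochs → channels:

* *Spectral* (25-s segments): Welch PSD with 4-s Hann sub-windows at 50%
  overlap (~0.25 Hz resolution); relative power in delta (2–4), theta
  (4–8), alpha (8–12) and beta (12–30 Hz), each relative to total 2–30 Hz
  power, with half-open band edges so shared boundaries count once; and
  spectral edge frequencies SEF75/SEF90, the frequencies below which
  75%/90% of 2–30 Hz power lies, linearly interpolated between PSD bins.
  The reference band is a documented choice: 0.5–2 Hz is removed by the
  high-pass and 30–40 Hz belongs to no feature band, so both are excluded
  from denominators (configurable).
* *Continuity* (whole epoch + 5-min windows): SATs are detected by the
  nonlinear energy operator ψ(n) = x(n)x(n−3) − x(n−1)x(n−2), smoothed
  (moving average, 1.5 s) in absolute value and thresholded at 1.5 µV²;
  bursts shorter than 1 s are dropped, gaps shorter than 0.5 s merged, and
  interior IBIs shorter than 1 s absorbed. These five constants are the
  published detector defaults and are exposed in the configuration; the
  threshold is absolute (µV²), so the mask is not invariant to amplitude
  rescaling unless the threshold is rescaled too. Features: SAT% of the
  whole record, mean SAT% over complete 5-min windows, and the median
  duration of complete IBIs (events truncated by the record edges count
  toward SAT% but are excluded from the IBI median; a fully continuous
  record reports 0 with a flag).
* *Complexity* (100-s segments): multiscale sample entropy, scales
  τ = 1…20 by non-overlapping block averaging, with m = 2 and
  r = 0.2 × SD of the original segment held fixed across scales — the
  standard convention; whether r should be recomputed per scale is an
  open choice, and fixed-r was selected and documented. r is computed per
  segment and channel because preterm EEG amplitude is strongly
  nonstationary across an hour. Matching uses Chebyshev distance with
  strict inequality and no self-matches. Features: complexity index
  (trapezoidal area under the curve), mean slope over scales 1–5, and the
  curve maximum. Degenerate segments (zero SD, or no template matches at
  some scale) are flagged and excluded from aggregation, never imputed.
  The pair counting is compiled (sorted-neighborhood pruning), so a 1-h
  2-channel recording completes in a few minutes on one CPU; an exact
  O(N²) brute-force oracle lives in the test suite.

## Statistical models

**Brain-age model.** Each feature is regressed on PMA with a linear
mixed-effects model, `feature ~ 1 + PMA` with correlated random intercept
and slope per subject (REML), because serial recordings from one infant are
not independent. Estimation and inference choices (unstated in the
clinical workflow): Wald normal inference on the fixed slope with 95% CI;
on a singular random-effects fit the model steps down to a random intercept
only and then to OLS, with the step recorded in the output. R² is reported
in two variance-partition forms, marginal (fixed effects only) and
conditional (fixed + random), since a single unqualified R² is ambiguous
for mixed models; the marginal Pearson ρ with PMA is reported alongside.

**Structure–function associations.** Early-EEG analyses use only each
subject's first recording, so observations are independent and plain OLS
applies: for every (EEG feature, MRI metric) pair we report the partial
correlation controlling for gestational age and morphine exposure
(residual-on-residual Pearson, p on n−2−k df; degenerate controls dropped
with a warning) and the coefficient on the EEG feature in
`metric ~ feature + GA + morphine`. The trajectory analysis replaces the
early feature with the per-subject OLS slope of the feature against PMA
(subjects with ≥2 recordings). Brain volumes can be adjusted for PMA at
scan (within-scan-group residual + mean, exactly orthogonal to scan age),
and growth per week between two scans is (m₂−m₁)/(PMA₂−PMA₁). No
multiplicity correction is applied by default, matching the original
reporting convention; Benjamini–Hochberg is available behind a flag.
Significance is flagged at α = 0.05.

## The synthetic cohort generator

Two tiers, because one generator cannot honestly serve both purposes:
hitting exact statistical parameters in feature space is easy, but
synthesizing waveforms that reproduce exact feature values is ill-posed.

**Tier A (feature space)** draws recordings directly from the generating
mixed model y = a + b·PMA + u₀ + u₁(PMA−28) + ε with independent Gaussian
subject-level effects. The design emulates the study conditions: 52
neonates, GA 24.71–27.86 weeks, a first recording at birth and weekly
recordings retained with probabilities reproducing the observed serial
counts (46, 26, 17, 16, 9, 1), PMA capped at 31.86 weeks, morphine
probability 26/43. Fixed slopes per feature are the reported
brain-age-model coefficients (e.g. 0.28/week for the complexity index,
0.08/week for SAT%, −0.24 s/week for the median IBI); intercepts are
anchored to plausible feature values at 28 weeks. Some reported slopes are
implausibly large on the raw feature scale (e.g. 35.43/week for the
small-scale MSE slope), suggesting standardization in the original
analysis; the generator treats each coefficient self-consistently as the
slope of its own simulated model and makes no claim about the original
scale. SAT% is simulated on the 0–1 fraction scale, on which 0.08/week
gives a plausible excursion over 24–32 weeks. Random-effect SDs default to
10% of the fixed-effect excursion over the ~7-week PMA range (intercept)
and 25% of the fixed slope (slope); the residual SD is solved per feature
so the marginal feature–PMA correlation matches the reported ρ (with the
random slope centered at 28 weeks so its variance does not swamp the
signal). All randomness flows through one seed; the generating parameters
and realized random effects are returned as a truth attribute.

**Tier B (waveforms)** synthesizes the tracé-discontinu process with a
per-sample ground-truth burst mask: an alternating lognormal burst/IBI
renewal sequence shared across the two channels (independent noise per
channel). The PMA parameterization encodes standard maturational
phenomenology, chosen once for realism and then frozen: burst fraction
0.35 + 0.08(PMA−28) clamped to [0.05, 0.95]; median IBI shrinking from
~40 s at 24 weeks toward a 3-s floor; burst RMS decaying exponentially from
~50 µV toward ~6 µV while the interburst floor rises slightly from 2 to
2.5 µV (discontinuity gets shallower); and waveform content mixing a
stereotyped narrowband 2–4 Hz slow component with a broadband 4–30 Hz
(1/f) fast component whose weight grows linearly with PMA — the
delta-brush-like fast activity that makes the maturing signal more complex.
Burst envelopes use 0.8-s raised-cosine ramps because SAT onsets and decays
are gradual; interburst content stays slow-dominated (fast weight capped at
0.4). One deliberate deviation: the IBI median shrinks by ~4 s/week rather
than the ~0.24 s/week fitted slope, because at realistic record lengths a
0.24 s/week trend is indistinguishable from renewal sampling noise — the
fitted slope is matched by tier A, while tier B targets the qualitative
sign pattern with detectable effect sizes.

What tier B does *not* emulate: artifacts (movement, ECG, electrode pops),
sleep-state cycling, asymmetric or focal events, and real SAT morphology.
Passing tests therefore demonstrate that the signal chain recovers the
constructs it claims to measure under clean discontinuous EEG, not that it
is robust to the artifact burden of real cot-side recordings — which is
exactly why the pipeline keeps programmatic quality flags and exposes all
detector constants.

## Numerical choices and degenerate inputs

* Sample-entropy counts are exact integers (compiled, sorted-neighborhood
  pruning; verified against an O(N²) oracle); −ln(A/B) with A or B = 0
  flagged undefined rather than imputed.
* Welch PSD is scaled so its integral matches signal variance (Parseval,
  within 5% for white noise); an all-zero segment has a zero PSD and its
  features are flagged undefined and excluded from aggregation.
* SEF uses linear interpolation inside the crossing bin; band integrals
  use half-open bins so shared edges are counted once.
* Aggregation means exclude missing entries; a feature missing everywhere
  is reported as an empty value with a reason code, never as zero.
* Mixed-model fits disable derivative re-checks for speed; singular fits
  trigger the documented fallback ladder.

## Problem sizes used in validation

The validation suite simulates 200 tier-A cohorts (~115 recordings each)
for slope recovery, 500 null cohorts for the type-I error of the
fixed-slope test, 40 cohorts for the MRI-coupling recovery, 14
two-channel tier-B recordings of 300 s across PMA 25–31 weeks for detector
agreement, and a 12-recording tier-B cohort (300 s each, PMA 25–31.5) for
the end-to-end maturation sign pattern; entropy oracles use 20,000-sample
iid sequences and 25,600-sample (100 s) segments. These sizes keep the
whole suite comfortably reproducible on a single CPU while leaving
Monte-Carlo error well below the tolerances tested.

## Known limitations

* The 2 Hz high-pass discards genuine slow-delta content; delta-band
  features are correspondingly weak, as in the source cohort.
* The detector threshold is absolute; recordings in other units or with
  very different gains require re-calibration via the `sat` config block.
* Tier-A features are unconstrained Gaussians and can stray outside
  physical ranges (fractions slightly outside [0,1]); they are meant for
  estimator validation, not as realistic feature tables.
* `sat_pct_5min_mean` requires at least one complete 5-min window, so
  records shorter than 300 s report it as missing.
* The mixed model assumes Gaussian residuals and linear PMA trends;
  maturation over a wider PMA span than ~25–32 weeks is not linear.
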