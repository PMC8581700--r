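---
title: "Speech markers of neuropsychiatric symptoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech markers of neuropsychiatric symptoms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`speechnpi` relates paralinguistic properties of short narrative speech
recordings (about one minute of "tell me about a positive/negative event in
your life") to caregiver-rated neuropsychiatric symptom scores — the
Neuropsychiatric Inventory (NPI) apathy, depression and anxiety subscales,
each an integer 0–12 formed as frequency (1–4) × severity (1–3), or 0 — in
older adults with mild neurocognitive disorder. The pipeline has three
stages: (1) automatic extraction of five feature families (temporal,
prosodic, formant, source, spectral) from each recording; (2) gender- and
task-stratified Spearman rank correlations, plus partial Spearman
correlations adjusted for global cognition (MMSE), with Benjamini–Hochberg
false-discovery control applied within each feature category; and (3)
leave-one-out cross-validated regression (radial-basis SVR and L1-penalized
linear regression) of each subscale score on the full feature set, scored
by mean absolute error against a training-mean baseline. Because clinical
recordings cannot be redistributed, the package ships a source–filter voice
synthesizer and a cohort simulator with *planted*, calibrated
feature–symptom effects; every stage is validated end to end against that
known ground truth.

# Feature extraction

## Voice activity detection and temporal features

Speech/silence segmentation thresholds each 25 ms frame's RMS energy (10 ms
hop, rectangular window) at 10% of the recording's 95th-percentile frame
RMS. The relative threshold makes the decision invariant to recording
level, and the 95th percentile is robust to files that are mostly silence.
Speech runs shorter than 0.10 s are discarded, then silences shorter than
0.25 s are bridged — common pause-detection conventions; both are settings
of `extraction_config()` because pause counts downstream depend on them. A
frame's decision is attributed to the hop-length interval at its center, so
segment bounds live on the 10 ms hop grid and boundary smear stays within
a few hops. Leading and trailing silence is never counted as a pause:
"number of pauses" is meant to reflect within-speech hesitation, not how
quickly a participant started talking.

Temporal features (speech ratio, total phonation time, number and mean
length of pauses and segments) derive from the interval lists alone.
Whether "speaking rate" should be syllables or segments per second is
ambiguous for free speech; the package exposes segments-per-second and
names it `speaking_rate_proxy` to make the operationalization explicit.

## Pitch

The f0 contour uses 40 ms frames (10 ms hop) — long enough to hold two
periods of the 60 Hz search floor — and the taper-corrected normalized
autocorrelation, searched between `1/f0_max` and `1/f0_min` (default
60–400 Hz, covering adult male and female voices; gender-specific ranges
can be set per call). Among local maxima reaching 85% of the strongest
peak the smallest lag wins, which suppresses octave errors on strongly
harmonic frames, and the winning peak is refined by parabolic
interpolation. Frames outside speech segments, or whose peak falls below
the 0.45 voicing threshold, are unvoiced. Recordings at 16 kHz or above
are tracked at half rate: pitch information lives far below the reduced
Nyquist and the interpolated lag keeps f0 resolution well inside the 2%
validation tolerance.

## Cycle-level voice quality: jitter, shimmer, HNR

Within every run of at least three voiced frames, cycle marks are picked
as waveform extrema one expected period (local `1/f0`) apart, then each
period is refined to sub-sample precision by maximizing the normalized
cross-correlation between consecutive cycle windows, evaluated at
fractional lags via band-limited (windowed-sinc) interpolation. Cycles
whose period deviates more than 25% from the local `1/f0`, boundary cycles
at region edges, and near-silent marks are discarded.

- **Jitter (local)** is `100·mean|T_i − T_{i−1}| / mean(T_i)`. The lag
  estimator's own noise variance — the generalized cross-correlation
  expression `(1 − r²)/(L·r²·|r''|)` per cycle, with `r` the correlation
  peak and `L` the window length — is subtracted in quadrature, so
  additive noise does not masquerade as vocal-fold instability.
- **Shimmer (local)** is the same statistic over per-cycle amplitudes.
  Amplitudes are RMS values over fixed-length windows centered on the
  cycle marks rather than raw peak heights: a fixed centered window is
  invariant to sub-sample cycle placement and keeps its edges in the
  low-energy part of the cycle, and the residual additive-noise
  contribution (`sqrt(q/W)` relative amplitude noise for noise-to-harmonic
  ratio `q` over `W` samples) is removed in quadrature. Raw peak
  amplitudes would inflate shimmer by several points at ordinary noise
  levels.
- **HNR** converts the per-cycle harmonicity `r` as `10·log10(r/(1−r))`,
  averaged over cycles and capped to [−10, 40] dB (the cap keeps clean
  synthetic voices finite). Measuring `r` at the per-cycle *refined* lag
  rather than at a fixed frame-level f0 lag is essential: cycle jitter
  decorrelates a fixed-lag frame autocorrelation so strongly that 1%
  jitter alone caps a fixed-lag estimate near 9 dB, whereas the
  cycle-synchronous estimate isolates additive noise. The "sound-to-noise
  ratio" named in the clinical literature is this estimator; `snr_db` is
  exported as an alias of `hnr_db`.

These choices matter and are therefore tested as a package-level
guarantee: across a 3 × 3 × 3 grid of synthetic voices (f0 110/160/220 Hz,
jitter 0.2/0.5/0.8%, HNR 10/15/20 dB — spanning normal to mildly
dysphonic voice quality), extraction must recover f0 within 2%, jitter
within 0.3 points, shimmer within 1.5 points, HNR within 2 dB, formants
within 50 Hz and the pause count exactly. The HNR grid deliberately stays
at or below 20 dB: with nonzero jitter, cycle-to-cycle waveform changes
(resonator tails re-entering at shifted phases) already contribute
aperiodicity comparable to a 25 dB noise floor, so higher planted ratios
are not recoverable by any cycle-comparison estimator and would make the
target ill-defined.

## Formants

Per speech frame: pre-emphasis (0.97), Hamming window, autocorrelation-
method linear prediction, polynomial roots. Recordings above 10 kHz are
decimated by the smallest integer factor that brings the analysis rate to
10 kHz or below (at 16 kHz: half rate), and the order defaults to
`2 + rate/1000` — formants live under a 4–5 kHz Nyquist, and a fixed-order
model spread over a wider band under-resolves them. Roots with positive
frequency in (90 Hz, Nyquist − 50 Hz) and bandwidth under 400 Hz qualify;
frames with at least three qualifying roots contribute F1 < F2 < F3 to the
track, from which the per-recording SDs are taken. Formant frames use a
20 ms hop by default (formants change slowly relative to pitch).

Recording-level mean frequencies need two extra steps. First, the centers
come from the *pooled* autocorrelation (averaged across frames before the
model fit), which conditions the estimate far better than averaging
per-frame root frequencies — per-frame roots scatter asymmetrically under
noise. Second, for voiced material the means are refined against measured
harmonic powers: frame-level LPC locks onto the nearest harmonic when f0
is high (at 220 Hz the spacing is comparable to a formant bandwidth), a
bias that can reach a substantial fraction of the harmonic spacing. The
refinement measures harmonic powers with
windows of about eight pitch periods — long enough to separate harmonics,
short enough that cumulative cycle jitter does not broaden the upper
harmonics differentially — averaged densely across the voiced material,
subtracts a local noise floor sampled between harmonics,
and fits a Lorentzian resonance (times a log-linear slope absorbing source
tilt) through the harmonics around each initial estimate, weighting each
harmonic by its signal fraction. This removes the harmonic-sampling bias
for periodic sources while leaving noise-excited input (which has no
harmonics, and no bias) untouched.

## Spectral family

MFCCs follow the standard recipe: pre-emphasis, 25 ms Hann frames, power
spectrum, 26 triangular mel filters spanning 0 to Nyquist, log
compression, orthonormal DCT-II keeping 13 coefficients (including the
energy-like c0), with delta and delta-delta tracks by ±2-frame regression,
summarized as per-coefficient means and SDs over speech frames. The
spectral family is flagged `ml_only`: it enters the regression models but
is excluded from the correlation analysis, where coefficients without a
direct articulatory reading would add little interpretable signal and many
hypotheses.

## Missing values

Every extractor returns `NA` — R's explicit missing marker — rather than
propagating NaN: a silent recording keeps its feature-table row with
temporal features at zero and voiced-dependent features missing.
Correlations use jointly complete observations; the regressions impute
with the training-fold mean.

# Statistical analysis

Spearman's rho is the Pearson correlation of mid-ranks (average ranks on
ties), with the t-approximation p-value on n − 2 degrees of freedom — the
behavior of common statistical software at this study's sample sizes
(49–92 per stratum); a seeded Monte-Carlo permutation p-value is
available for very small samples, where the t approximation is coarse.
Depression scores in such cohorts are heavily
zero-inflated, which is exactly why rank methods are used throughout. The
partial correlation rank-transforms all three variables and applies the
first-order formula
`(r_xy − r_xz·r_yz)/sqrt((1 − r_xz²)(1 − r_yz²))` with n − 3 degrees of
freedom; MMSE is partialled out of both the feature and the score (the
standard convention). Plain and partial statistics are computed on the
identical jointly-complete observation set, so their difference reflects
conditioning only. A zero-variance covariate falls back to the plain
correlation with a `degenerate_covariate` flag.

Benjamini–Hochberg correction is applied *within each feature category*,
separately for every (gender × task × subscale) cell and separately for
the plain and partial families — the finest reading of per-category
correction. The finest grouping never pools evidence across unrelated
families, which is the conservative choice when category sizes differ by
an order of magnitude (7 temporal features vs 78 spectral ones, had they
been included). Significance defaults to adjusted q ≤ 0.05 and is
configurable. Strata with fewer than 5 complete observations are skipped
and listed, never silently dropped.

# Regression experiments

The prediction grid is gender × subscale × model × (with/without MMSE as a
feature), with features from both tasks jointly in wide form (task-
suffixed columns) including the spectral family; a per-task restriction is
available via `tasks=`. Leave-one-out cross-validation fits exactly N
models per experiment; z-normalization and mean-imputation are refitted
inside each training fold so the held-out observation never influences any
training statistic (a constant training-fold feature gets SD 1, a no-op).
The baseline is the training-mean predictor, whose LOOCV MAE has the
closed form `mean_i |y_i − mean(y_{-i})|`; it is the natural MAE reference
computable from the scores alone. Hyperparameters are fixed defaults
(SVR: radial basis, C = 1, epsilon = 0.1; lasso penalty 0.1 on z-scored
features) rather than tuned — an inner tuning loop on 49–92 observations
would mostly harvest optimism — and are overridable. For the sparse model,
nonzero-coefficient features are aggregated over folds with their
selection frequency.

One subtlety the simulations exposed: on zero-inflated scores the
mean-predictor baseline is not MAE-optimal (the median is), and an
epsilon-insensitive learner like SVR drifts toward a median-like constant.
It can therefore beat the mean baseline by about 0.1 NPI points *with no
feature signal at all*. The null-scenario validation consequently checks
the feature-attributable margin — each model's margin minus the margin of
the same model fitted on a constant feature — rather than the raw margin,
which is only required to stay far below the 0.3-point level treated as a
meaningful improvement. Raw MAE comparisons between L1-trained models and
a mean baseline on skewed scores should be read with this location effect
in mind.

# The synthetic study

## Voices

`synthesize_voice()` builds a glottal-like excitation of band-limited
pulses (Hann-windowed sinc, cutoff 0.78 Nyquist, unit sampled energy) at
cycle positions `T_i = (1/f0)(1 + eps_i)` with `eps_i ~ N(0, jitter/100)`,
per-cycle gains `1 + N(0, shimmer/100)`, filtered through cascaded
two-pole resonators (default 500/1500/2500 Hz, bandwidths 80/120/160 Hz),
plus white noise at the power ratio implied by the target HNR, with
silences inserted per the pause schedule. Band-limited pulses are the one
non-obvious choice: only a band-limited pulse is shift-invariant under
fractional-sample placement, so planted jitter, shimmer and cycle shapes
survive sampling exactly; a naive narrow pulse changes shape and energy
with its sub-sample position, which reads as spurious shimmer and
harmonicity loss downstream. Everything is deterministic under the spec's
seed.

## Cohorts

`generate_cohort()` draws a study-shaped population: 92 females and 49
males by default, age ≈ 75, MMSE rounded-truncated normal with mean 24 and
SD 3, and NPI subscales that are 0 with probability 0.5 and otherwise a
frequency × severity product weighted toward low values — a regime where
scores rarely exceed 4, matching the mild-symptom populations these
cohorts come from. MMSE and the subscales co-vary through latent normals
(apathy most strongly), so partial correlation has real work to do.

Planted effects act on the *synthesis parameters* — the latent truth —
never on extracted features, so an end-to-end run genuinely tests
extraction and statistics jointly. Each effect row (subscale, acoustic
parameter, target Spearman rho, optional gender/task restriction) is
realized through a Gaussian copula whose latent-normal correlation is
calibrated by root-finding so that the large-sample Spearman correlation
between the continuous parameter and the *discretized, zero-inflated*
score equals the target; the calibration explicitly uses the tie-reduced
variance of the score's mid-ranks. Parameter maps are monotone (speech
proportion 0.65 + 0.12·w clamped to [0.35, 0.85] and realized exactly by
rescaling the schedule's speech segments; jitter and shimmer log-normal
around 0.5% and 2.5%; HNR 18 ± 3 dB; f0 190 ± 20 Hz for females, 120 ± 15
for males), so rank correlations pass through unchanged up to clamping,
and the unclamped latents are stored for calibration checks.

`default_paper_scenario()` encodes the reported effect directions: apathy
lowers the speech proportion (rho −0.50); anxiety raises jitter and
shimmer (+0.30 each) and the harmonics-to-noise ratio (+0.40); and
anxiety raises f0 for females in the negative-story task only (+0.35),
mirroring the stratum-specific finding. Magnitudes are moderate rank
correlations; the speech-proportion link is set strongest because it is
the association reported significant in *every* gender × task cell — for
that to happen in a single 49-subject male stratum (where the sampling SD
of an observed rank correlation is about 0.12), the underlying effect
must be around 0.5, and a weaker planted value would make the scenario's
own detectability claim unreliable at that size. `null_effects = TRUE`
zeroes the table for false-positive studies.

# Validation design and problem sizes

The test suite validates, in order: the DSP round trip on the 27-voice
grid above (10 s voices); the rank statistics against brute-force
mid-rank/Pearson and residual-regression oracles (100 random vectors and
triples, agreement to 1e−12 and 1e−10); FDR control on 1000 replicates of
200 uniform null p-values (mean false-discovery proportion ≤ 0.06); LOOCV
arithmetic against closed forms (exact); end-to-end recovery on the
default scenario at full study size (141 subjects, 10 s recordings, 25
planted and 12 null replicates — the null false-positive rate pools about
3,600 tests, and replicate counts are the package's chosen simulation
sizes); and byte-identical reproducibility of the file pipeline under a
fixed seed. `scripts/acceptance.R` recomputes the same quantities from
scratch at reduced replicate counts (8 planted, 5 null) and writes them as
JSON.

Passing these tests shows that the pipeline recovers known structure from
signals that match its generative assumptions: stationary per-speaker f0,
stable formants, white additive noise, exactly periodic-plus-perturbation
excitation, and rectangular speech/pause alternation. Real narrative
speech has none of these luxuries — intonation contours, coarticulated
formant movement, colored and nonstationary noise, creak and diplophonia,
filled pauses — so the synthetic results bound what the code computes,
not what a clinical deployment would find. The simulator also plants
effects monotonically, which favors rank correlation by construction.

# Known limitations

- The feature registry implements the named members of each family plus
  standard companions; it is a practical, extensible subset rather than a
  canonical inventory.
- "Total power" is implemented as the sum of squared samples (energy);
  the alternative reading (power × duration) differs only by the sampling
  rate factor.
- Formant SDs come from the unrefined frame-level track and inherit its
  harmonic bias; only the means are refinement-corrected.
- The speaking-rate proxy counts segments, not syllables; no syllable
  nuclei detection is attempted.
- LOOCV with fixed hyperparameters estimates performance of exactly those
  settings; no claim is made about tuned models, and the small-sample MAE
  of LOOCV has high variance by nature.
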