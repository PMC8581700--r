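# speechnpi

Paralinguistic speech markers of neuropsychiatric symptoms in mild
neurocognitive disorder.

Affective neuropsychiatric symptoms — apathy, depression, anxiety — are
early, prognostic, and chronically under-detected in older adults with
cognitive decline, because their assessment leans on caregiver interviews
such as the Neuropsychiatric Inventory (NPI; per-symptom score =
frequency 1–4 × severity 1–3, range 0–12). Short narrative speech tasks
("tell me about a positive/negative event in your life") offer an
objective complement: apathy shows up in *how much* someone speaks,
anxiety in *voice quality*. `speechnpi` implements that analysis as a
tested R pipeline for clinicians and methods researchers:

1. **Feature extraction** from mono WAV recordings, in five families —
   *temporal* (speech ratio, phonation time, pause statistics from
   energy-based voice activity detection), *prosodic* (f0 statistics from
   autocorrelation pitch tracking, power, amplitude moments), *source*
   (cycle-level local jitter `100·mean|T_i−T_{i−1}|/mean T`, local
   shimmer, harmonics-to-noise ratio `10·log10(r/(1−r))`), *formant*
   (F1–F3 by linear prediction with harmonic refinement) and *spectral*
   (13 MFCCs with Δ and ΔΔ summaries).
2. **Stratified inference**: per gender × task × subscale, Spearman rank
   correlations and MMSE-partial Spearman correlations
   `(r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))` on ranks, with
   Benjamini–Hochberg false-discovery control applied within each feature
   category (MFCCs are excluded here and reserved for the models).
3. **Prediction**: leave-one-out cross-validated support-vector regression
   and lasso of each subscale score on the full feature set, reported as
   MAE against the training-mean baseline `mean_i |y_i − mean(y_{−i})|`,
   with the lasso's selected features.

Because clinical recordings cannot be shipped, the package includes a
source–filter **voice synthesizer** (controlled f0, jitter, shimmer, HNR,
formants, pause schedule) and a **cohort simulator** that plants
calibrated feature–symptom rank correlations on the synthesis parameters
(92 female / 49 male by default, MMSE ≈ 24, zero-inflated NPI scores).
Every stage is validated end to end against that ground truth.

## Worked example

```r
library(speechnpi)

# a simulated study with the default planted effects, 10 s per recording
cfg <- default_paper_scenario(duration_s = 10)
gen <- generate_cohort(cfg, seed = 11)
recs <- synthesize_study(gen)

ft <- extract_all(recs, fast_extraction_config())
cr <- run_correlation_analysis(ft, gen$cohort)
sig <- significant_correlations(cr)
subset(sig, feature == "speech_ratio" & subscale == "apathy",
       select = c(task, gender, rho, q_value, rho_partial))
#>        task gender        rho      q_value rho_partial
#> 1  positive female -0.6268548 3.241585e-11  -0.5919981
#> 16 negative female -0.6315367 1.037669e-10  -0.5969265
#> 31 positive   male -0.4920424 5.767817e-04  -0.4127053
#> 52 negative   male -0.4919891 6.063098e-04  -0.4079579
```

The planted negative apathy–speech-proportion link (target rank
correlation −0.50) is recovered with the right sign in every gender ×
task stratum and survives both FDR correction and MMSE adjustment; the
female estimates run stronger than the target at this seed's draw, the
male ones sit near it.

```r
ml <- run_ml_experiments(ft, gen$cohort, subscales = "apathy",
                         include_mmse = FALSE)
ml[, c("gender", "model", "mae", "baseline_mae", "beats_baseline")]
#>   gender model      mae baseline_mae beats_baseline
#> 1 female   svr 1.260224     1.680841           TRUE
#> 2 female lasso 1.335186     1.680841           TRUE
#> 3   male   svr 2.005188     2.315476           TRUE
#> 4   male lasso 2.435879     2.315476          FALSE
```

Three of the four model × stratum cells beat the mean-predictor baseline
on this replicate (by 0.31–0.42 NPI points); the male lasso loses to it,
a reminder that a 49-subject leave-one-out MAE is a noisy quantity. File-based equivalents (`simulate_study()`,
`run_extraction()`, `run_correlations()`, `run_regressions()`,
`run_pipeline()`) write CSV/JSON artifacts that embed the package version,
seed and a configuration hash; a thin command-line dispatcher with verbs
`simulate / extract / analyze / ml / report` is installed at
`inst/cli/speechnpi.R`.

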