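# Shared fixtures: small deterministic signals and cohorts built in code.

FS <- 16000L

make_tone <- function(freq, dur_s, fs = FS, amp = 0.8) {
  amp * sin(2 * pi * freq * seq_len(round(dur_s * fs)) / fs)
}

make_noise <- function(dur_s, fs = FS, sd = 0.2, seed = 1) {
  x <- speechnpi:::with_seed(seed, rnorm(round(dur_s * fs), 0, sd))
  pmin(pmax(x, -1), 1)
}

# short synthetic voice for unit tests (4 s speech + one pause)
quick_voice <- function(f0 = 160, jitter = 0.5, shimmer = 3, hnr = 15,
                        seed = 7, schedule = rbind(c(2, 0.5), c(1.5, 0))) {
  synthesize_voice(
    voice_spec(f0, jitter, shimmer, hnr, pause_schedule = schedule,
               seed = seed),
    subject_id = "T01", task = "positive")
}

tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("A", "B", "C", "D", "E", "F"),
    gender = c("female", "female", "female", "male", "male", "male"),
    age = c(71, 75, 80, 68, 77, 82),
    mmse = c(24L, 27L, 18L, 22L, 25L, 29L),
    npi_apathy = c(0L, 4L, 12L, 0L, 6L, 2L),
    npi_depression = c(0L, 0L, 3L, 1L, 0L, 8L),
    npi_anxiety = c(2L, 0L, 9L, 0L, 4L, 0L)
  )
}

# long-form feature table built directly (no audio), for stats/ml tests
synthetic_feature_table <- function(values_by_feature, subjects,
                                    tasks = c("positive", "negative")) {
  reg <- feature_registry()
  rows <- do.call(rbind, lapply(tasks, function(tk) {
    do.call(rbind, lapply(names(values_by_feature), function(fe) {
      data.frame(subject_id = subjects, task = tk, feature = fe,
                 category = reg$category[match(fe, reg$feature)],
                 ml_only = reg$ml_only[match(fe, reg$feature)],
                 value = values_by_feature[[fe]])
    }))
  }))
  class(rows) <- c("feature_table", "data.frame")
  rows
}
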