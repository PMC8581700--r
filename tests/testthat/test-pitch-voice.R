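test_that("the pitch tracker recovers a sawtooth f0 and rejects noise", {
  t <- seq_len(FS) / FS
  saw <- 0.8 * (2 * ((220 * t) %% 1) - 1)
  ct <- estimate_f0_contour(audio_recording(saw, FS))
  expect_gt(sum(ct$voiced), 10)
  expect_lt(abs(mean(ct$f0_hz[ct$voiced]) - 220) / 220, 0.02)

  ctn <- estimate_f0_contour(audio_recording(make_noise(2, seed = 5), FS))
  expect_gte(mean(!ctn$voiced), 0.9)

  ct0 <- estimate_f0_contour(audio_recording(numeric(FS), FS))
  expect_true(all(!ct0$voiced))
})

test_that("period extraction yields exact cycle lengths on clean voices", {
  rec <- quick_voice(f0 = 200, jitter = 0, shimmer = 0, hnr = 40)
  ct <- estimate_f0_contour(rec)
  p <- extract_periods(rec, ct)
  expect_gt(length(p$periods_s), 100)
  expect_true(all(abs(p$periods_s - 0.005) < 1 / FS))
})

test_that("amplitude modulation varies amplitudes but not periods", {
  t <- seq_len(2 * FS) / FS
  am <- 0.6 * (1 + 0.4 * sin(2 * pi * 3 * t)) * sin(2 * pi * 180 * t)
  rec <- audio_recording(am, FS)
  ct <- estimate_f0_contour(rec)
  p <- extract_periods(rec, ct)
  expect_gt(length(p$periods_s), 50)
  expect_lt(sd(p$periods_s) / mean(p$periods_s), 0.01)
  expect_gt(sd(p$peak_amplitudes) / mean(p$peak_amplitudes), 0.1)
})

test_that("an unvoiced contour yields an empty period sequence", {
  rec <- audio_recording(make_noise(1, seed = 9), FS)
  ct <- estimate_f0_contour(rec)
  expect_warning(p <- extract_periods(rec, ct), "cycle|voiced")
  expect_length(p$periods_s, 0)
})

test_that("jitter and shimmer match their first-difference definitions", {
  per <- structure(list(
    periods_s = rep(c(0.010, 0.0102), 3),
    peak_amplitudes = rep(1, 6),
    harmonicity = numeric(0), adjacent = c(FALSE, rep(TRUE, 5)),
    window_len = integer(0), lag_noise_var_s2 = numeric(0)),
    class = "period_sequence")
  expect_equal(jitter_local(per), 100 * 0.0002 / 0.0101, tolerance = 1e-10)

  amp <- structure(list(
    periods_s = rep(0.01, 6),
    peak_amplitudes = rep(c(1.0, 0.9), 3),
    harmonicity = numeric(0), adjacent = c(FALSE, rep(TRUE, 5)),
    window_len = integer(0), lag_noise_var_s2 = numeric(0)),
    class = "period_sequence")
  expect_equal(shimmer_local(amp), 100 * 0.1 / 0.95, tolerance = 1e-10)

  const <- structure(list(
    periods_s = rep(0.01, 5), peak_amplitudes = rep(0.5, 5),
    harmonicity = numeric(0), adjacent = c(FALSE, rep(TRUE, 4)),
    window_len = integer(0), lag_noise_var_s2 = numeric(0)),
    class = "period_sequence")
  expect_equal(jitter_local(const), 0)
  expect_equal(shimmer_local(const), 0)

  short <- structure(list(periods_s = 0.01, peak_amplitudes = 1,
                          harmonicity = numeric(0), adjacent = FALSE,
                          window_len = integer(0),
                          lag_noise_var_s2 = numeric(0)),
                     class = "period_sequence")
  expect_true(is.na(jitter_local(short)))
  expect_true(is.na(shimmer_local(short)))
})

test_that("planted jitter and shimmer are recovered from synthesis", {
  rec <- quick_voice(f0 = 160, jitter = 1, shimmer = 3, hnr = 20, seed = 33,
                     schedule = rbind(c(4, 0)))
  ct <- estimate_f0_contour(rec)
  p <- extract_periods(rec, ct)
  expect_lt(abs(jitter_local(p) - 1), 0.3)
  expect_lt(abs(shimmer_local(p) - 3), 1.5)
  # clean-source limit
  rec0 <- quick_voice(f0 = 160, jitter = 0, shimmer = 0, hnr = 40,
                      seed = 34, schedule = rbind(c(3, 0)))
  p0 <- extract_periods(rec0, estimate_f0_contour(rec0))
  expect_lt(jitter_local(p0), 0.2)
  expect_lt(shimmer_local(p0), 1)
})

test_that("harmonics-to-noise matches a constructed power ratio", {
  t <- seq_len(2 * FS) / FS
  s <- sin(2 * pi * 200 * t)              # power 0.5
  n <- speechnpi:::with_seed(4, rnorm(length(t), 0, sqrt(0.05)))
  x <- (s + n)
  rec <- audio_recording(x / max(abs(x)), FS)
  hnr <- harmonics_to_noise(rec, estimate_f0_contour(rec))
  expect_lt(abs(hnr - 10), 2)
  # clean periodic signal hits the cap
  rec2 <- audio_recording(0.8 * s, FS)
  expect_equal(harmonics_to_noise(rec2, estimate_f0_contour(rec2)), 40)
  # no voiced frames -> missing value
  recn <- audio_recording(make_noise(1, seed = 6), FS)
  expect_true(is.na(harmonics_to_noise(recn, estimate_f0_contour(recn))))
})

test_that("measured HNR decreases monotonically with planted noise", {
  vals <- vapply(c(25, 15, 5), function(h) {
    rec <- quick_voice(f0 = 150, jitter = 0.3, shimmer = 2, hnr = h,
                       seed = 55, schedule = rbind(c(3, 0)))
    harmonics_to_noise(rec, estimate_f0_contour(rec))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("voice-quality features are invariant to gain; power is not", {
  rec <- quick_voice(seed = 77, schedule = rbind(c(3, 0)))
  half <- audio_recording(rec$samples * 0.5, FS)
  v1 <- extract_features_one(rec)
  v2 <- extract_features_one(half)
  for (f in c("f0_mean_hz", "jitter_local_pct", "shimmer_local_pct",
              "hnr_db", "f1_mean_hz", "f2_mean_hz", "f3_mean_hz")) {
    expect_equal(v2[[f]], v1[[f]], tolerance = 1e-6, label = f)
  }
  expect_equal(v2[["mean_power"]], 0.25 * v1[["mean_power"]],
               tolerance = 1e-9)
  expect_equal(v2[["total_power"]], 0.25 * v1[["total_power"]],
               tolerance = 1e-9)
})
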