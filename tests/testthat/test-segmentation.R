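test_that("tone-silence-tone segmentation recovers the constructed pause", {
  x <- c(make_tone(300, 0.5), numeric(FS / 2), make_tone(300, 0.5))
  seg <- detect_voice_activity(audio_recording(x, FS))
  expect_equal(nrow(seg$speech_segments), 2)
  expect_equal(nrow(seg$pauses), 1)
  expect_lt(abs((seg$pauses[1, 2] - seg$pauses[1, 1]) - 0.5), 0.031)
  # interval bounds sit on the hop grid
  bounds <- c(seg$speech_segments, seg$pauses)
  expect_true(all(abs(bounds / seg$hop_s - round(bounds / seg$hop_s)) <
                    1e-9))
})

test_that("silence and continuous voicing are degenerate segmentations", {
  seg0 <- detect_voice_activity(audio_recording(numeric(2 * FS), FS))
  expect_equal(nrow(seg0$speech_segments), 0)
  expect_equal(nrow(seg0$pauses), 0)

  seg1 <- detect_voice_activity(audio_recording(make_tone(250, 2), FS))
  expect_equal(nrow(seg1$speech_segments), 1)
  expect_equal(nrow(seg1$pauses), 0)
  expect_gt(seg1$speech_segments[1, 2] - seg1$speech_segments[1, 1], 1.9)
})

test_that("leading and trailing silence is never counted as a pause", {
  x <- c(numeric(FS), make_tone(300, 1), numeric(FS))
  seg <- detect_voice_activity(audio_recording(x, FS))
  expect_equal(nrow(seg$speech_segments), 1)
  expect_equal(nrow(seg$pauses), 0)
  tf <- temporal_features(seg)
  expect_equal(tf$num_pauses, 0)
  expect_lt(tf$speech_ratio, 0.4)
})

test_that("temporal features derive from the interval lists alone", {
  seg <- structure(list(speech_segments = cbind(0.5, 1.5),
                        pauses = matrix(numeric(0), ncol = 2),
                        total_duration_s = 2, hop_s = 0.01),
                   class = "segmentation")
  tf <- temporal_features(seg)
  expect_equal(tf$speech_ratio, 0.5)
  expect_equal(tf$num_pauses, 0)
  expect_equal(tf$mean_pause_length_s, 0)

  seg2 <- structure(list(speech_segments = rbind(c(0, 0.5), c(1.0, 1.5)),
                         pauses = cbind(0.5, 1.0),
                         total_duration_s = 1.5, hop_s = 0.01),
                    class = "segmentation")
  tf2 <- temporal_features(seg2)
  expect_equal(tf2$total_phonation_time_s, 1.0)
  expect_equal(tf2$mean_pause_length_s, 0.5)
  expect_equal(tf2$num_pauses, 1)
  expect_equal(tf2$speaking_rate_proxy, 2 / 1.5)

  seg3 <- structure(list(speech_segments = matrix(numeric(0), ncol = 2),
                         pauses = matrix(numeric(0), ncol = 2),
                         total_duration_s = 2, hop_s = 0.01),
                    class = "segmentation")
  tf3 <- temporal_features(seg3)
  expect_equal(tf3$speech_ratio, 0)
  expect_equal(tf3$num_segments, 0)
})

test_that("raising the energy threshold never increases phonation time", {
  rec <- quick_voice(seed = 21)
  phon <- vapply(c(0.05, 0.1, 0.2, 0.4), function(th) {
    temporal_features(
      detect_voice_activity(rec, energy_threshold_rel = th)
    )$total_phonation_time_s
  }, numeric(1))
  expect_true(all(diff(phon) <= 1e-9))
})

test_that("inserting silence never increases the speech ratio", {
  rec <- quick_voice(seed = 22)
  sr1 <- temporal_features(detect_voice_activity(rec))$speech_ratio
  rec2 <- audio_recording(c(rec$samples[1:(2 * FS)], numeric(FS),
                            rec$samples[-(1:(2 * FS))]), FS)
  sr2 <- temporal_features(detect_voice_activity(rec2))$speech_ratio
  expect_lte(sr2, sr1 + 1e-9)
})

test_that("segmentation exports as an ordered labeled interval table", {
  x <- c(make_tone(300, 0.5), numeric(FS / 2), make_tone(300, 0.5))
  seg <- detect_voice_activity(audio_recording(x, FS))
  path <- tempfile(fileext = ".csv")
  df <- segmentation_table(seg, path)
  expect_equal(df$label, c("speech", "pause", "speech"))
  expect_true(all(diff(df$start_s) > 0))
  expect_true(file.exists(path))
  unlink(path)
})
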