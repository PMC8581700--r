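test_that("WAV write/read round trip preserves samples to 16-bit precision", {
  x <- speechnpi:::with_seed(42, runif(8000, -0.95, 0.95))
  path <- file.path(tempdir(), "S07_negative.wav")
  write_wav(audio_recording(x, FS), path)
  rec <- read_wav(path)
  expect_equal(rec$sample_rate, FS)
  expect_lt(max(abs(rec$samples - x)), 1 / 32768 + 1e-12)
  # metadata parsed from the filename pattern
  expect_equal(rec$subject_id, "S07")
  expect_equal(rec$task, "negative")
  unlink(path)
})

test_that("full-scale and all-zero payloads follow the PCM16 conventions", {
  path <- tempfile(fileext = ".wav")
  write_wav(audio_recording(c(32767 / 32768, 0, -1), FS), path)
  rec <- read_wav(path, subject_id = "x", task = "positive")
  expect_equal(rec$samples[1], 32767 / 32768)
  expect_equal(rec$samples[3], -1)

  write_wav(audio_recording(numeric(FS) , FS), path)
  rec0 <- read_wav(path, subject_id = "x")
  expect_length(rec0$samples, FS)
  expect_true(all(rec0$samples == 0))
  unlink(path)
})

test_that("stereo PCM input is downmixed by the channel mean", {
  # hand-written 2-channel RIFF payload
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  left <- as.integer(c(16384, -16384, 8192))
  right <- as.integer(c(0, 0, 8192))
  inter <- as.vector(rbind(left, right))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, 4, endian = "little")
  writeBin(c(1L, 2L), con, 2, endian = "little")
  writeBin(c(8000L, 32000L), con, 4, endian = "little")
  writeBin(c(4L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  rec <- read_wav(path, subject_id = "s", task = "positive")
  expect_equal(rec$samples, (left + right) / 2 / 32768)
  unlink(path)
})

test_that("unreadable files and empty payloads raise format errors", {
  bad <- tempfile(fileext = ".wav")
  writeLines("not audio", bad)
  expect_error(read_wav(bad), "RIFF")
  unlink(bad)
  expect_error(audio_recording(numeric(0), FS), "nonempty")
  expect_error(audio_recording(c(0, 1.5), FS), "normalize")
})

test_that("frame counts follow floor((L - frame)/hop) + 1 with no padding", {
  fs <- 1000
  x <- seq_len(100) / 100
  fr <- frame_signal(x, 0.025, 0.010, sample_rate = fs)
  expect_equal(ncol(fr$frames), 8)        # floor((100-25)/10)+1
  fr1 <- frame_signal(x[1:25], 0.025, 0.010, sample_rate = fs)
  expect_equal(ncol(fr1$frames), 1)       # boundary: exactly one frame
  expect_warning(
    fr0 <- frame_signal(x[1:10], 0.025, 0.010, sample_rate = fs),
    "shorter")
  expect_equal(ncol(fr0$frames), 0)
  # no frame extends past the signal end
  expect_lte(max(fr$starts) + 25, length(x))
})

test_that("hann windowing and framing conservation behave as defined", {
  fs <- 1000
  fr <- frame_signal(rep(1, 50), 0.025, 0.025, window = "hann",
                     sample_rate = fs)
  expect_equal(fr$frames[, 1], speechnpi:::hann_window(25))
  # rectangular frames at hop = frame length reconstruct the signal
  x <- speechnpi:::with_seed(3, rnorm(98))
  fr2 <- frame_signal(x, 0.02, 0.02, sample_rate = fs)
  expect_equal(as.vector(fr2$frames), x[1:(20 * ncol(fr2$frames))])
})

test_that("rms energy matches closed forms and scales with |c|", {
  expect_equal(rms_energy(rep(0.3, 50)), 0.3)
  expect_equal(rms_energy(numeric(5) + 0), 0)
  expect_equal(rms_energy(sin(2 * pi * seq_len(1000) / 100)), sqrt(0.5),
               tolerance = 1e-3)
  expect_error(rms_energy(numeric(0)), "empty")
  for (cc in c(-2.5, 0.1, 7)) {
    x <- speechnpi:::with_seed(8, rnorm(200))
    expect_equal(rms_energy(cc * x), abs(cc) * rms_energy(x))
  }
})
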