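#' Audio recording container
#'
#' Bundles a mono waveform with its sample rate and the study metadata
#' (subject identifier and narrative task label) used by every downstream
#' extractor.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer-valued scalar).
#' @param subject_id Opaque participant identifier.
#' @param task Task label, one of `"positive"` or `"negative"`.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate`, `subject_id`, `task`.
#' @export
audio_recording <- function(samples, sample_rate, subject_id = NA_character_,
                            task = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("samples must be a nonempty numeric vector", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  if (!is.na(task)) task <- match.arg(task, c("positive", "negative"))
  rng <- range(samples)
  if (rng[1] < -1.000001 || rng[2] > 1.000001) {
    stop("samples must lie in [-1, 1]; normalize before constructing",
         call. = FALSE)
  }
  structure(
    list(samples = pmin(pmax(as.double(samples), -1), 1),
         sample_rate = as.integer(round(sample_rate)),
         subject_id = as.character(subject_id), task = task),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> subject=%s task=%s %.3f s @ %d Hz\n",
              x$subject_id, x$task, length(x$samples) / x$sample_rate,
              x$sample_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [audio_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$sample_rate

# Parse "<subject>_<positive|negative>.wav" into metadata.
parse_wav_name <- function(path) {
  base <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^(.*)_(positive|negative)$", base))[[1]]
  if (length(m) == 3) list(subject_id = m[2], task = m[3])
  else list(subject_id = base, task = NA_character_)
}

#' Read a RIFF WAV file
#'
#' Reads mono or stereo PCM 16-bit or IEEE float-32 WAV files. Stereo input
#' is downmixed by the arithmetic channel mean. Integer samples are scaled to
#' `[-1, 1]` with the 16-bit full-scale convention (32768). Subject and task
#' metadata are parsed from a `<subject>_<positive|negative>.wav` filename
#' unless supplied explicitly.
#'
#' @param path Path to a `.wav` file.
#' @param subject_id,task Optional metadata overriding the filename pattern.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, subject_id = NULL, task = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("'%s' is not a RIFF WAV file", path), call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("'%s' is not a WAVE file", path), call. = FALSE)
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little",
                         signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little",
                           signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little",
                       signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                           signed = TRUE) / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        stop(sprintf(
          "unsupported WAV encoding (format %d, %d bit); only PCM16 and float32 are readable",
          fmt$format, fmt$bits), call. = FALSE)
      }
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2)))
    }
  }
  if (is.null(samples) || length(samples) == 0) {
    stop(sprintf("'%s' contains no audio payload", path), call. = FALSE)
  }
  if (fmt$channels > 1) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  meta <- parse_wav_name(path)
  audio_recording(pmin(pmax(samples, -1), 1), fmt$rate,
                  subject_id %||% meta$subject_id,
                  task %||% meta$task)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as 16-bit PCM WAV
#'
#' @param rec An [audio_recording()] (or numeric vector with `sample_rate`).
#' @param path Output path.
#' @param sample_rate Required when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate = NULL) {
  if (is.numeric(rec)) rec <- audio_recording(rec, sample_rate)
  x <- pmin(pmax(rec$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")  # PCM
  writeBin(1L, con, 2, endian = "little")  # mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Slice a signal into fixed-length analysis frames
#'
#' Frames never extend past the signal end (no padding); the frame count is
#' `floor((L - frame_len) / hop) + 1` in samples when the signal is at least
#' one frame long, else zero (with a warning).
#'
#' @param rec An [audio_recording()] or numeric vector.
#' @param frame_length_s Frame length in seconds.
#' @param hop_s Hop between frame starts in seconds.
#' @param window `"rectangular"` or `"hann"`; the window is applied
#'   multiplicatively to each frame.
#' @param sample_rate Required when `rec` is a bare numeric vector.
#' @return A `frame_sequence`: list with `frames` (frame_len x n matrix),
#'   `starts` (0-based sample offsets), `times_s` (frame start times),
#'   `frame_length_s`, `hop_s`, `window`, `sample_rate`.
#' @export
frame_signal <- function(rec, frame_length_s = 0.025, hop_s = 0.010,
                         window = c("rectangular", "hann"),
                         sample_rate = NULL) {
  window <- match.arg(window)
  if (is.numeric(rec)) rec <- list(samples = rec, sample_rate = sample_rate)
  fs <- rec$sample_rate
  stopifnot(hop_s > 0, frame_length_s >= hop_s)
  flen <- round(frame_length_s * fs)
  hop <- round(hop_s * fs)
  L <- length(rec$samples)
  if (L < flen) {
    warning("signal shorter than one frame; empty frame sequence")
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, L - flen, by = hop)
  }
  frames <- if (length(starts)) {
    matrix(rec$samples[outer(seq_len(flen), starts, `+`)], nrow = flen)
  } else {
    matrix(numeric(0), nrow = flen, ncol = 0)
  }
  if (window == "hann" && length(starts)) {
    frames <- frames * hann_window(flen)
  }
  structure(list(frames = frames, starts = as.integer(starts),
                 times_s = starts / fs, frame_length_s = flen / fs,
                 hop_s = hop / fs, window = window, sample_rate = fs),
            class = "frame_sequence")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Root-mean-square energy of a frame
#'
#' @param frame Nonempty numeric vector.
#' @return `sqrt(mean(frame^2))`.
#' @export
rms_energy <- function(frame) {
  if (length(frame) == 0) stop("empty frame", call. = FALSE)
  sqrt(mean(frame^2))
}

# Frame starts (0-based) for a given frame/hop length in samples.
frame_starts <- function(L, flen, hop) {
  if (L < flen) integer(0) else as.integer(seq.int(0L, L - flen, by = hop))
}
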