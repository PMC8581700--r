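hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mel x (nfft/2 + 1), filters spanning 0..fs/2.
mel_filterbank <- function(n_mel, nfft, fs) {
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2),
                         length.out = n_mel + 2))
  bins <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, n_mel, nfft / 2 + 1)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bins - lo) / (ce - lo)
    down <- (hi - bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), rows are basis functions.
dct_matrix <- function(n_out, n_in) {
  d <- outer(0:(n_out - 1), 0:(n_in - 1), function(k, n) {
    cos(pi * k * (2 * n + 1) / (2 * n_in))
  })
  d * sqrt(2 / n_in)
  # first row scaled below for orthonormality
}

# Delta coefficients by +-2-frame linear regression with edge replication.
delta_coeffs <- function(C, width = 2L) {
  n <- ncol(C)
  if (n == 0) return(C)
  idx <- function(k) pmin(pmax(seq_len(n) + k, 1L), n)
  num <- 0
  for (k in seq_len(width)) num <- num + k * (C[, idx(k), drop = FALSE] -
                                              C[, idx(-k), drop = FALSE])
  num / (2 * sum(seq_len(width)^2))
}

#' Mel-frequency cepstral coefficients with delta and delta-delta summaries
#'
#' Per speech frame: pre-emphasis, Hann window, power spectrum, 26-filter
#' mel filterbank spanning 0 to Nyquist, log compression and an orthonormal
#' DCT-II keeping `n_coeffs` coefficients (including the energy-like
#' coefficient 0). Delta and delta-delta tracks use the standard +-2-frame
#' regression. Summaries (mean and SD per coefficient) are taken over speech
#' frames only.
#'
#' @param rec An [audio_recording()] sampled at 8 kHz or above.
#' @param seg Optional `segmentation`; computed with defaults when missing.
#' @param n_coeffs Number of cepstral coefficients kept (default 13).
#' @param n_mel Number of mel filters (default 26).
#' @param frame_length_s,hop_s Analysis frame geometry.
#' @return List with `mfcc_means`, `mfcc_sds`, `delta_means`, `delta_sds`,
#'   `delta_delta_means`, `delta_delta_sds` (each length `n_coeffs`; all NA
#'   when the recording contains no speech frames).
#' @export
mfcc_features <- function(rec, seg = NULL, n_coeffs = 13, n_mel = 26,
                          frame_length_s = 0.025, hop_s = 0.010) {
  fs <- rec$sample_rate
  if (fs < 8000) stop("MFCC analysis requires sample_rate >= 8000",
                      call. = FALSE)
  if (is.null(seg)) seg <- detect_voice_activity(rec)
  nas <- rep(NA_real_, n_coeffs)
  missing_out <- list(mfcc_means = nas, mfcc_sds = nas, delta_means = nas,
                      delta_sds = nas, delta_delta_means = nas,
                      delta_delta_sds = nas)
  if (!nrow(seg$speech_segments)) return(missing_out)
  x <- c(rec$samples[1],
         rec$samples[-1] - 0.97 * rec$samples[-length(rec$samples)])
  flen <- round(frame_length_s * fs)
  hop <- round(hop_s * fs)
  starts <- frame_starts(length(x), flen, hop)
  if (!length(starts)) return(missing_out)
  centers <- (starts + flen / 2) / fs
  starts <- starts[point_in_intervals(centers, seg$speech_segments)]
  if (length(starts) < 1) return(missing_out)
  nfft <- 2^ceiling(log2(flen))
  P <- cpp_frame_powspec(x, starts, flen, hann_window(flen), nfft)
  fb <- mel_filterbank(n_mel, nfft, fs)
  E <- log(pmax(fb %*% P, 1e-12))
  D <- dct_matrix(n_coeffs, n_mel)
  D[1, ] <- D[1, ] / sqrt(2)
  C <- D %*% E
  d1 <- delta_coeffs(C)
  d2 <- delta_coeffs(d1)
  msd <- function(M) {
    list(mean = rowMeans(M),
         sd = if (ncol(M) > 1) apply(M, 1, sd) else rep(0, nrow(M)))
  }
  c0 <- msd(C); s1 <- msd(d1); s2 <- msd(d2)
  list(mfcc_means = c0$mean, mfcc_sds = c0$sd, delta_means = s1$mean,
       delta_sds = s1$sd, delta_delta_means = s2$mean,
       delta_delta_sds = s2$sd)
}
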