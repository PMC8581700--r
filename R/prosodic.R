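#' Prosodic feature family
#'
#' Fundamental-frequency statistics over voiced frames (range as the 95th
#' minus 5th percentile, robust to stray tracker errors), overall power
#' measures, and amplitude shape moments within speech segments. Kurtosis
#' and skewness follow the Pearson moment convention (a Gaussian has
#' kurtosis 3, a full-cycle sine 1.5); both are `NA` for zero-variance
#' amplitude.
#'
#' @param rec An [audio_recording()].
#' @param contour An `f0_contour` from [estimate_f0_contour()].
#' @param seg Optional `segmentation` (computed with defaults when missing)
#'   delimiting the samples entering the amplitude moments.
#' @return Named list: `f0_mean_hz`, `f0_sd_hz`, `f0_range_hz`,
#'   `voiced_fraction`, `mean_power`, `total_power`, `amplitude_kurtosis`,
#'   `amplitude_skewness`.
#' @export
prosodic_features <- function(rec, contour, seg = NULL) {
  if (is.null(seg)) seg <- detect_voice_activity(rec)
  x <- rec$samples
  f0 <- contour$f0_hz[contour$voiced]
  n_frames <- nrow(contour)
  f0_stats <- if (length(f0) >= 2) {
    q <- quantile(f0, c(0.05, 0.95), names = FALSE, type = 7)
    list(mean = mean(f0), sd = sd(f0), range = q[2] - q[1])
  } else if (length(f0) == 1) {
    list(mean = f0, sd = 0, range = 0)
  } else {
    list(mean = NA_real_, sd = NA_real_, range = NA_real_)
  }
  sp <- if (nrow(seg$speech_segments)) {
    a <- pmax(1L, floor(seg$speech_segments[, 1] * rec$sample_rate) + 1L)
    b <- pmin(length(x), ceiling(seg$speech_segments[, 2] * rec$sample_rate))
    keep <- b >= a
    x[sequence(b[keep] - a[keep] + 1L, from = a[keep])]
  } else numeric(0)
  mom <- if (length(sp) >= 4 && sd(sp) > 0) {
    z <- sp - mean(sp)
    s2 <- mean(z^2)
    list(kurt = mean(z^4) / s2^2, skew = mean(z^3) / s2^1.5)
  } else {
    list(kurt = NA_real_, skew = NA_real_)
  }
  list(
    f0_mean_hz = f0_stats$mean, f0_sd_hz = f0_stats$sd,
    f0_range_hz = f0_stats$range,
    voiced_fraction = if (n_frames) mean(contour$voiced) else 0,
    mean_power = mean(x^2), total_power = sum(x^2),
    amplitude_kurtosis = mom$kurt, amplitude_skewness = mom$skew
  )
}
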