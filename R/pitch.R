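#' Autocorrelation pitch tracking
#'
#' Estimates a fundamental-frequency contour on 40 ms frames with a 10 ms
#' hop. For each frame inside a speech segment the taper-corrected normalized
#' autocorrelation is searched in the lag range `[1/f0_max, 1/f0_min]`; among
#' local maxima reaching 85% of the strongest one the smallest lag wins
#' (octave-error guard) and is refined by parabolic interpolation. Frames
#' whose peak falls below `voicing_threshold`, or that lie outside speech
#' segments, are marked unvoiced.
#'
#' @param rec An [audio_recording()].
#' @param seg Optional `segmentation`; computed with defaults when missing.
#' @param f0_min,f0_max Search range in Hz; `f0_max` must not exceed a
#'   quarter of the sample rate.
#' @param voicing_threshold Normalized-autocorrelation floor for voicing
#'   (default 0.45).
#' @param frame_length_s,hop_s Pitch analysis frame geometry.
#' @return An `f0_contour`: data frame with `time_s` (frame start), `f0_hz`
#'   (NA when unvoiced), `voiced`, `acf_peak`; attributes `sample_rate`,
#'   `frame_length_s`, `hop_s`.
#' @export
estimate_f0_contour <- function(rec, seg = NULL, f0_min = 60, f0_max = 400,
                                voicing_threshold = 0.45,
                                frame_length_s = 0.040, hop_s = 0.010) {
  fs <- rec$sample_rate
  if (!(f0_min < f0_max && f0_max <= fs / 4)) {
    stop("need f0_min < f0_max <= sample_rate / 4", call. = FALSE)
  }
  if (is.null(seg)) seg <- detect_voice_activity(rec)
  # pitch lives well below 2 kHz: track on a half-rate signal when the
  # recording is sampled at 16 kHz or above (parabolic lag interpolation
  # keeps the f0 resolution far inside tolerance at half rate)
  dec <- if (fs >= 16000) 2L else 1L
  if (dec > 1L) {
    lpf <- signal::butter(6, 0.85 / dec)
    xd <- cpp_iir(lpf$b, lpf$a, rec$samples)[seq(1L, length(rec$samples),
                                                 by = dec)]
  } else {
    xd <- rec$samples
  }
  fsd <- fs / dec
  flen <- round(frame_length_s * fsd)
  hop <- round(hop_s * fsd)
  starts <- frame_starts(length(xd), flen, hop)
  out0 <- data.frame(time_s = numeric(0), f0_hz = numeric(0),
                     voiced = logical(0), acf_peak = numeric(0))
  attr(out0, "sample_rate") <- fs
  attr(out0, "frame_length_s") <- flen / fs
  attr(out0, "hop_s") <- hop / fs
  class(out0) <- c("f0_contour", "data.frame")
  if (!length(starts) || !nrow(seg$speech_segments)) return(out0)

  centers <- (starts + flen / 2) / fsd
  in_speech <- point_in_intervals(centers, seg$speech_segments)
  lag_min <- max(2L, floor(fsd / f0_max))
  lag_max <- ceiling(fsd / f0_min)
  if (lag_max + 1 >= flen) {
    stop("pitch frame too short for f0_min", call. = FALSE)
  }
  f0 <- rep(NA_real_, length(starts))
  peak <- numeric(length(starts))
  idx <- which(in_speech)
  if (length(idx)) {
    acf <- cpp_frame_acf(xd, starts[idx], flen, lag_max + 1L)
    pk <- cpp_f0_peaks(acf, lag_min, lag_max, flen)
    f0[idx] <- fsd / pk[, 1]
    peak[idx] <- pk[, 2]
  }
  voiced <- in_speech & !is.na(f0) & peak >= voicing_threshold &
    f0 >= f0_min & f0 <= f0_max
  f0[!voiced] <- NA_real_
  out <- data.frame(time_s = starts / fsd, f0_hz = f0, voiced = voiced,
                    acf_peak = peak)
  attr(out, "sample_rate") <- fs
  attr(out, "frame_length_s") <- flen / fs
  attr(out, "hop_s") <- hop / fs
  class(out) <- c("f0_contour", "data.frame")
  out
}

# TRUE for points lying inside any [start, end) interval of a 2-col matrix.
point_in_intervals <- function(x, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(x)))
  res <- rep(FALSE, length(x))
  for (i in seq_len(nrow(intervals))) {
    res <- res | (x >= intervals[i, 1] & x < intervals[i, 2])
  }
  res
}

# Runs of >= min_run consecutive voiced frames -> sample-index regions.
voiced_regions <- function(contour, min_run = 3L) {
  if (!nrow(contour)) return(list())
  fs <- attr(contour, "sample_rate")
  flen <- round(attr(contour, "frame_length_s") * fs)
  runs <- rle(contour$voiced)
  ends <- cumsum(runs$lengths)
  begs <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= min_run)
  lapply(keep, function(i) {
    fr <- begs[i]:ends[i]
    list(frames = fr,
         from = round(contour$time_s[begs[i]] * fs) + 1L,
         to = round(contour$time_s[ends[i]] * fs) + flen,
         f0 = contour$f0_hz[fr],
         times = contour$time_s[fr])
  })
}

# Cycle-level analysis shared by extract_periods and harmonics_to_noise.
# Runs the waveform-matching pulse tracker in every voiced region and
# returns per-cycle periods, amplitudes, harmonicity coefficients and a
# same-region adjacency flag. Amplitudes are RMS values over fixed-length
# windows centered on the cycle marks: a fixed window makes the estimate
# invariant to the sub-sample cycle position, and centering keeps the
# window edges in the low-energy part of the cycle, so period quantization
# cannot leak a neighboring pulse in or out of the window.
pulse_analysis <- function(rec, contour, max_period_dev = 0.25) {
  fs <- rec$sample_rate
  regions <- voiced_regions(contour)
  acc <- list(periods = numeric(0), amps = numeric(0), ccs = numeric(0),
              adjacent = logical(0), wlen = integer(0), tauvar = numeric(0))
  for (rg in regions) {
    to <- min(rg$to, length(rec$samples))
    if (to - rg$from < 3 * fs / median(rg$f0)) next
    x <- rec$samples[rg$from:to]
    tr <- cpp_track_pulses(x, fs / median(rg$f0))
    if (length(tr$periods) < 1) next
    e2 <- c(0, cumsum(x^2))
    m <- tr$marks
    nper <- length(tr$periods)
    L0 <- max(8L, round(0.9 * median(diff(m))))
    a <- pmax(1L, m[seq_len(nper)] + 1L - L0 %/% 2L)
    b <- pmin(length(x), a + L0 - 1L)
    tr$amps <- sqrt(pmax(e2[b + 1L] - e2[a], 0) / pmax(b - a + 1L, 1L))
    tr$wlen <- b - a + 1L
    # local expected period per cycle from the nearest voiced frame's f0
    marks_t <- (rg$from - 1 + tr$marks[seq_along(tr$periods)]) / fs
    fi <- findInterval(marks_t, rg$times)
    fi[fi < 1] <- 1L
    t_exp <- 1 / rg$f0[pmin(fi, length(rg$f0))]
    per <- tr$periods / fs
    ok <- is.finite(per) & abs(per - t_exp) <= max_period_dev * t_exp
    # boundary cycles touch the region edges (fade-in/out, silence) and
    # near-silent marks are tracking artifacts; both are excluded
    if (length(per) > 2) ok[c(1, length(per))] <- FALSE
    ok <- ok & tr$amps > 0.15 * median(tr$amps)
    if (!any(ok)) next
    adj <- c(FALSE, ok[-length(ok)] & ok[-1])[ok]
    acc$periods <- c(acc$periods, per[ok])
    acc$amps <- c(acc$amps, tr$amps[ok])
    acc$ccs <- c(acc$ccs, tr$ccs[ok])
    acc$adjacent <- c(acc$adjacent, adj)
    acc$wlen <- c(acc$wlen, tr$wlen[ok])
    acc$tauvar <- c(acc$tauvar, tr$tauvar[ok] / fs^2)
  }
  acc
}

#' Extract glottal cycle lengths and amplitudes
#'
#' Locates cycle marks in every voiced region by peak picking one expected
#' period (from the local f0) apart, then refines each period to sub-sample
#' precision by waveform matching between consecutive cycles. Cycles whose
#' period deviates more than 25% from the local `1/f0` are discarded. The
#' per-cycle amplitude is the RMS over a fixed-length window centered on
#' the cycle mark, which is robust to additive noise and to sub-sample
#' cycle placement (a raw peak amplitude would inflate shimmer at
#' realistic noise levels).
#'
#' @param rec An [audio_recording()].
#' @param contour An `f0_contour` from [estimate_f0_contour()].
#' @return A `period_sequence`: list with `periods_s`, `peak_amplitudes`,
#'   `harmonicity` (per-cycle normalized cross-correlation) and `adjacent`
#'   (TRUE when the previous cycle is the immediately preceding cycle of the
#'   same voiced region, i.e. a valid first-difference pair).
#' @export
extract_periods <- function(rec, contour) {
  if (sum(contour$voiced) < 3) {
    warning("fewer than 3 voiced frames; empty period sequence")
    res <- list(periods_s = numeric(0), peak_amplitudes = numeric(0),
                harmonicity = numeric(0), adjacent = logical(0))
    class(res) <- "period_sequence"
    return(res)
  }
  acc <- pulse_analysis(rec, contour)
  if (length(acc$periods) < 3) {
    warning("fewer than 3 usable cycles; empty period sequence")
    acc <- list(periods = numeric(0), amps = numeric(0), ccs = numeric(0),
                adjacent = logical(0), wlen = integer(0),
                tauvar = numeric(0))
  }
  res <- list(periods_s = acc$periods, peak_amplitudes = acc$amps,
              harmonicity = acc$ccs, adjacent = acc$adjacent,
              window_len = acc$wlen, lag_noise_var_s2 = acc$tauvar)
  class(res) <- "period_sequence"
  res
}

#' @export
print.period_sequence <- function(x, ...) {
  cat(sprintf("<period_sequence> %d cycles, mean period %.2f ms\n",
              length(x$periods_s),
              if (length(x$periods_s)) 1000 * mean(x$periods_s) else NA))
  invisible(x)
}

# Mean absolute consecutive difference relative to the mean, in percent.
local_perturbation_pct <- function(values, adjacent) {
  d <- abs(diff(values))[adjacent[-1]]
  if (length(d) < 1 || mean(values) <= 0) return(NA_real_)
  100 * mean(d) / mean(values)
}

#' Local jitter (%)
#'
#' `100 * mean(|T_i - T_(i-1)|) / mean(T_i)` over consecutive cycle pairs of
#' the same voiced region. Returns `NA` (an explicit missing marker, not an
#' error) with fewer than two usable periods.
#'
#' When the sequence carries per-cycle lag-noise variances (the extraction
#' path always does), the period-measurement noise contribution - the
#' generalized cross-correlation variance `(1 - r^2)/(L r^2 |r''|)` of each
#' refined lag - is removed in quadrature, so additive noise does not read
#' as vocal-fold instability.
#'
#' @param p A `period_sequence` from [extract_periods()].
#' @return Jitter in percent, or `NA`.
#' @export
jitter_local <- function(p) {
  if (length(p$periods_s) < 2) return(NA_real_)
  raw <- local_perturbation_pct(p$periods_s, p$adjacent)
  if (is.na(raw)) return(raw)
  tv <- p$lag_noise_var_s2
  if (length(tv) == length(p$periods_s) && any(is.finite(tv))) {
    sigma_u <- sqrt(mean(tv, na.rm = TRUE)) / mean(p$periods_s)
    k <- 100 * sqrt(4 / pi)
    raw <- k * sqrt(max((raw / k)^2 - sigma_u^2, 0))
  }
  raw
}

#' Local shimmer (%)
#'
#' `100 * mean(|A_i - A_(i-1)|) / mean(A_i)` over consecutive cycle pairs,
#' with `A_i` the per-cycle amplitudes of the sequence. `NA` with fewer
#' than two usable cycles.
#'
#' When the sequence carries harmonicity information (the extraction path
#' always does), the additive-noise contribution to the amplitude
#' fluctuation is removed: a window of `W` samples with noise-to-harmonic
#' power ratio `q` perturbs each cycle amplitude by a relative standard
#' deviation `sqrt(q / W)`, which inflates the raw first-difference
#' statistic in quadrature and is subtracted out. Without the correction,
#' shimmer is biased upward by several points at moderate noise levels.
#'
#' @param p A `period_sequence` from [extract_periods()].
#' @return Shimmer in percent, or `NA`.
#' @export
shimmer_local <- function(p) {
  if (length(p$peak_amplitudes) < 2) return(NA_real_)
  raw <- local_perturbation_pct(p$peak_amplitudes, p$adjacent)
  if (is.na(raw)) return(raw)
  if (length(p$harmonicity) == length(p$peak_amplitudes) &&
      length(p$window_len) == length(p$peak_amplitudes) &&
      all(is.finite(p$harmonicity))) {
    r <- pmin(pmax(p$harmonicity, 1e-3), 1 - 1e-6)
    sigma_n <- sqrt(mean((1 - r) / r) / mean(p$window_len))
    k <- 100 * sqrt(4 / pi)  # E|d| of a N(0, 2 sigma^2) first difference
    raw <- k * sqrt(max((raw / k)^2 - sigma_n^2, 0))
  }
  raw
}

#' Harmonics-to-noise ratio (dB)
#'
#' Converts per-cycle harmonicity coefficients `r` (normalized
#' cross-correlation between consecutive cycles at the refined period lag,
#' from the pulse tracker) as `10 log10(r / (1 - r))` and averages over
#' cycles; the result is capped to `[-10, 40]` dB. Measuring `r` at the
#' per-cycle refined lag rather than at a fixed frame-level f0 lag keeps the
#' estimate insensitive to jitter, so it reflects additive noise only.
#'
#' @param rec An [audio_recording()].
#' @param contour An `f0_contour`.
#' @param periods Optional precomputed `period_sequence` (avoids re-running
#'   the pulse tracker).
#' @return HNR in dB, or `NA` when no voiced cycles are found.
#' @export
harmonics_to_noise <- function(rec, contour, periods = NULL) {
  if (is.null(periods)) {
    if (sum(contour$voiced) < 1) return(NA_real_)
    periods <- suppressWarnings(extract_periods(rec, contour))
  }
  r <- periods$harmonicity
  r <- r[is.finite(r)]
  if (!length(r)) return(NA_real_)
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  hnr <- mean(10 * log10(r / (1 - r)))
  min(max(hnr, -10), 40)
}
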