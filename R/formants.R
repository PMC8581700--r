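# Mean power at harmonic frequencies k*f0 (and at half-harmonic offsets,
# used as a local noise-floor estimate that is subtracted) over Hann
# windows of about eight pitch periods inside voiced regions. The window
# length balances harmonic separation against cycle jitter: cumulative
# phase drift over a long window broadens the upper harmonics
# differentially and biases the fitted resonance centers downward.
# Returns the comb frequencies, the floor-corrected harmonic powers and
# the median f0.
harmonic_powers <- function(rec, contour, fmax = 3400, cycles = 8,
                            max_windows = 128L) {
  fs <- rec$sample_rate
  f0bar <- median(contour$f0_hz[contour$voiced])
  if (!is.finite(f0bar)) return(NULL)
  nwin <- min(1024L, as.integer(round(cycles * fs / f0bar)))
  K <- floor(min(fmax, fs / 2 - f0bar) / f0bar)
  if (K < 4) return(NULL)
  starts <- unlist(lapply(voiced_regions(contour), function(rg) {
    to <- min(rg$to, length(rec$samples))
    if (to - rg$from + 1 < nwin) integer(0)
    else seq(rg$from, to - nwin + 1, by = nwin %/% 4)
  }))
  if (length(starts) < 2) return(NULL)
  if (length(starts) > max_windows) {
    starts <- starts[round(seq(1, length(starts), length.out = max_windows))]
  }
  fk <- (1:K) * f0bar
  h <- hann_window(nwin)
  Eh <- exp(-2i * pi * outer(0:(nwin - 1), fk) / fs) * h
  En <- exp(-2i * pi * outer(0:(nwin - 1), fk + 0.5 * f0bar) / fs) * h
  X <- matrix(rec$samples[outer(0:(nwin - 1), starts, `+`)], nrow = nwin)
  p <- rowMeans(Mod(crossprod(Eh, X))^2)
  pn <- rowMeans(Mod(crossprod(En, X))^2)
  list(fk = fk, p = pmax(p - pn, p * 0.02), pn = pn, f0 = f0bar)
}

# Refine one formant frequency by fitting a Lorentzian resonance (times a
# log-linear local slope) to the harmonic powers around the initial
# estimate. Grid search over center and half-bandwidth with the two linear
# parameters profiled out. Counteracts the harmonic-sampling bias of
# frame-level linear prediction, which locks onto the nearest harmonic
# when f0 is high.
refine_formant <- function(hp, f_init, passes = 2L) {
  f0 <- hp$f0
  # re-center on the strongest noise-corrected harmonic near the initial
  # estimate: frame-level LPC can sit hundreds of Hz off at low HNR, while
  # the resonance peak must lie near the locally dominant harmonic
  nb0 <- which(abs(hp$fk - f_init) <= 2.6 * f0 & is.finite(hp$p) &
                 hp$p > 0)
  f_cur <- if (length(nb0)) hp$fk[nb0[which.max(hp$p[nb0])]] else f_init
  for (pass in seq_len(passes)) {
    nb <- which(abs(hp$fk - f_cur) <= 2.6 * f0 & is.finite(hp$p) &
                  hp$p > 0)
    if (length(nb) < 4) return(f_cur)
    fk <- hp$fk[nb]
    lp <- log(hp$p[nb])
    w2 <- hp$p[nb] / (hp$p[nb] + hp$pn[nb])  # down-weight noisy lines
    centers <- seq(f_cur - 1.1 * f0, f_cur + 1.1 * f0, by = 4)
    U <- outer(fk, centers, `-`)              # points x centers
    sw <- sum(w2)
    sx <- colSums(w2 * U)
    sxx <- colSums(w2 * U^2)
    best_sse <- Inf
    best_f <- f_cur
    for (G in c(30, 50, 70, 100, 140, 200, 280)) {
      Y <- lp + log(U^2 + G^2)
      sy <- colSums(w2 * Y)
      sxy <- colSums(w2 * U * Y)
      syy <- colSums(w2 * Y^2)
      det <- sw * sxx - sx^2
      b <- (sw * sxy - sx * sy) / det         # weighted LS slope
      a <- (sy - b * sx) / sw                 # and intercept, profiled out
      sse <- syy - 2 * a * sy - 2 * b * sxy + a^2 * sw +
        2 * a * b * sx + b^2 * sxx
      j <- which.min(sse)
      if (sse[j] < best_sse) {
        best_sse <- sse[j]
        best_f <- centers[j]
      }
    }
    f_cur <- best_f
  }
  f_cur
}

#' Formant estimation by linear prediction
#'
#' Per speech frame: pre-emphasis, Hamming window, autocorrelation-method
#' linear prediction, and polynomial root finding. Roots with positive
#' frequency, bandwidth below `max_bandwidth_hz` and frequency inside
#' `(90, Nyquist - 50)` Hz qualify; a frame needs at least three qualifying
#' roots to contribute, and F1 < F2 < F3 are the three lowest. Recordings
#' sampled above 10 kHz are decimated by the smallest integer factor that
#' brings the analysis rate to 10 kHz or below (formants live well under a
#' 5 kHz Nyquist; a fixed-order model over a wider band under-resolves
#' them), and the prediction order defaults to `2 + analysis_rate/1000`.
#'
#' For voiced recordings (a pitch contour is supplied or computable) the
#' per-recording mean frequencies are additionally refined against the
#' measured harmonic powers: frame-level linear prediction locks onto the
#' nearest harmonic when the harmonic spacing is comparable to the formant
#' bandwidth, and fitting a local resonance curve through the harmonic
#' amplitudes removes that bias.
#'
#' @param rec An [audio_recording()] sampled at 8 kHz or above.
#' @param seg Optional `segmentation`; computed with defaults when missing.
#' @param contour Optional `f0_contour`; enables harmonic refinement of the
#'   mean formant frequencies (skipped for unvoiced material).
#' @param lpc_order Prediction order; `NULL` picks `round(2 + rate/1000)`
#'   at the (possibly decimated) analysis rate.
#' @param max_bandwidth_hz Bandwidth ceiling for formant roots (default 400).
#' @param frame_length_s,hop_s Analysis frame geometry.
#' @param harmonic_windows Number of long windows averaged for the
#'   harmonic refinement (default 128).
#' @return A list with `f1_mean_hz`, `f2_mean_hz`, `f3_mean_hz`,
#'   `f1_sd_hz`, `f2_sd_hz`, `f3_sd_hz` (NA when no frame yields three
#'   formants) plus a `frames` attribute holding the per-frame track.
#' @export
formants_lpc <- function(rec, seg = NULL, contour = NULL, lpc_order = NULL,
                         max_bandwidth_hz = 400, frame_length_s = 0.025,
                         hop_s = 0.010, harmonic_windows = 128L) {
  fs <- rec$sample_rate
  if (fs < 8000) stop("formant analysis requires sample_rate >= 8000",
                      call. = FALSE)
  if (is.null(seg)) seg <- detect_voice_activity(rec)
  missing_out <- function() {
    out <- list(f1_mean_hz = NA_real_, f2_mean_hz = NA_real_,
                f3_mean_hz = NA_real_, f1_sd_hz = NA_real_,
                f2_sd_hz = NA_real_, f3_sd_hz = NA_real_)
    attr(out, "frames") <- data.frame(time_s = numeric(0), f1 = numeric(0),
                                      f2 = numeric(0), f3 = numeric(0))
    out
  }
  if (!nrow(seg$speech_segments)) return(missing_out())

  dec <- max(1L, as.integer(ceiling(fs / 10000)))
  x <- rec$samples
  if (dec > 1L) {
    lp <- signal::butter(6, 0.85 / dec)
    x <- cpp_iir(lp$b, lp$a, x)[seq(1L, length(x), by = dec)]
  }
  fsa <- fs / dec
  if (is.null(lpc_order)) lpc_order <- round(2 + fsa / 1000)
  x <- c(x[1], x[-1] - 0.97 * x[-length(x)])  # pre-emphasis

  flen <- round(frame_length_s * fsa)
  hop <- round(hop_s * fsa)
  starts <- frame_starts(length(x), flen, hop)
  if (!length(starts)) return(missing_out())
  centers <- (starts + flen / 2) / fsa
  keep <- point_in_intervals(centers, seg$speech_segments)
  starts <- starts[keep]
  if (!length(starts)) return(missing_out())
  hamming <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  fm <- cpp_lpc_formants(x, starts, flen, hamming, as.integer(lpc_order),
                         fsa, max_bandwidth_hz, 90)
  ok <- stats::complete.cases(fm[, 1:3, drop = FALSE])
  track <- data.frame(time_s = starts[ok] / fsa, f1 = fm[ok, 1],
                      f2 = fm[ok, 2], f3 = fm[ok, 3])
  if (!nrow(track)) return(missing_out())
  means <- c(mean(track$f1), mean(track$f2), mean(track$f3))
  # recording-level centers from the pooled autocorrelation: averaging the
  # acf across frames before the model fit conditions the estimate far
  # better than averaging per-frame root frequencies
  ac <- rowMeans(cpp_frame_acf(x, starts, flen, as.integer(lpc_order)))
  if (ac[1] > 0) {
    a <- tryCatch(
      solve(stats::toeplitz(ac[seq_len(lpc_order)] *
                              c(1 + 1e-9, rep(1, lpc_order - 1))),
            ac[2:(lpc_order + 1)]),
      error = function(e) NULL)
    if (!is.null(a)) {
      rt <- polyroot(rev(c(1, -a)))
      f <- Arg(rt) * fsa / (2 * pi)
      bw <- -log(Mod(rt)) * fsa / pi
      ok <- Im(rt) > 1e-9 & f > 90 & f < fsa / 2 - 50 &
        bw < max_bandwidth_hz & Mod(rt) < 1
      if (sum(ok) >= 3) means <- sort(f[ok])[1:3]
    }
  }
  if (!is.null(contour) && sum(contour$voiced) >= 10) {
    hp <- harmonic_powers(rec, contour, max_windows = harmonic_windows)
    if (!is.null(hp)) {
      means <- vapply(means, function(f) refine_formant(hp, f), numeric(1))
      means <- sort(means)
    }
  }
  out <- list(
    f1_mean_hz = means[1], f2_mean_hz = means[2], f3_mean_hz = means[3],
    f1_sd_hz = if (nrow(track) > 1) sd(track$f1) else 0,
    f2_sd_hz = if (nrow(track) > 1) sd(track$f2) else 0,
    f3_sd_hz = if (nrow(track) > 1) sd(track$f3) else 0
  )
  attr(out, "frames") <- track
  out
}
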