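#' Energy-based voice activity detection
#'
#' Classifies fixed frames as speech or silence by comparing each frame's RMS
#' energy with a threshold relative to the recording's robust energy scale
#' (the 95th-percentile frame RMS, which is insensitive to long silences).
#' Speech runs shorter than `min_segment_s` are merged into the surrounding
#' silence, then silences shorter than `min_pause_s` are merged into the
#' surrounding speech. Interval bounds are reported on the hop grid; a
#' frame's decision is attributed to the hop-length interval at its center.
#' Leading and trailing silence is not counted as a pause.
#'
#' @param rec An [audio_recording()].
#' @param energy_threshold_rel Threshold as a fraction of the robust energy
#'   scale (level-invariant). Default 0.1.
#' @param min_pause_s Minimum silence duration kept as a pause (default 0.25).
#' @param min_segment_s Minimum speech-run duration kept (default 0.10).
#' @param frame_length_s,hop_s Analysis frame geometry (rectangular window).
#' @return A `segmentation` object: list with `speech_segments` and `pauses`
#'   (two-column matrices of half-open `[start_s, end_s)` intervals),
#'   `total_duration_s`, `hop_s`.
#' @export
detect_voice_activity <- function(rec, energy_threshold_rel = 0.1,
                                  min_pause_s = 0.25, min_segment_s = 0.10,
                                  frame_length_s = 0.025, hop_s = 0.010) {
  stopifnot(energy_threshold_rel > 0, min_pause_s > 0, min_segment_s > 0)
  fs <- rec$sample_rate
  flen <- round(frame_length_s * fs)
  hop <- round(hop_s * fs)
  L <- length(rec$samples)
  total <- L / fs
  starts <- frame_starts(L, flen, hop)
  empty <- function() {
    structure(list(speech_segments = matrix(numeric(0), ncol = 2),
                   pauses = matrix(numeric(0), ncol = 2),
                   total_duration_s = total, hop_s = hop / fs),
              class = "segmentation")
  }
  if (!length(starts)) return(empty())
  rms <- cpp_frame_rms(rec$samples, starts, flen)
  scale <- quantile(rms, 0.95, names = FALSE, type = 7)
  if (scale <= 0) return(empty())
  speech <- rms >= energy_threshold_rel * scale

  # decision interval of frame k: one hop, offset so it sits at frame center
  off <- round((flen - hop) / (2 * hop))
  runs <- rle(speech)
  ends <- cumsum(runs$lengths)
  begs <- ends - runs$lengths + 1
  keep <- runs$values & (runs$lengths * hop / fs >= min_segment_s)
  segs <- cbind(begs[keep], ends[keep])
  if (!nrow(segs)) return(empty())
  # merge segments separated by less than min_pause_s
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      gap <- (segs[i, 1] - merged[nrow(merged), 2] - 1) * hop / fs
      if (gap < min_pause_s) {
        merged[nrow(merged), 2] <- segs[i, 2]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
  }
  to_s <- function(k) (k + off) * hop / fs  # frame index -> boundary time
  seg_s <- cbind(to_s(merged[, 1] - 1), pmin(to_s(merged[, 2]), total))
  pauses <- if (nrow(seg_s) > 1) {
    cbind(seg_s[-nrow(seg_s), 2], seg_s[-1, 1])
  } else {
    matrix(numeric(0), ncol = 2)
  }
  structure(list(speech_segments = seg_s, pauses = pauses,
                 total_duration_s = total, hop_s = hop / fs),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d speech segment(s), %d pause(s) in %.2f s\n",
              nrow(x$speech_segments), nrow(x$pauses), x$total_duration_s))
  invisible(x)
}

#' Temporal feature family from a segmentation
#'
#' All quantities derive from the interval lists alone. Mean pause/segment
#' lengths are 0 by convention when the corresponding list is empty; the
#' speaking-rate proxy is speech segments per second of recording (syllable
#' rates are out of scope).
#'
#' @param seg A `segmentation` from [detect_voice_activity()].
#' @return Named list: `speech_ratio`, `total_phonation_time_s`,
#'   `num_pauses`, `mean_pause_length_s`, `num_segments`,
#'   `mean_segment_length_s`, `speaking_rate_proxy`.
#' @export
temporal_features <- function(seg) {
  stopifnot(seg$total_duration_s > 0)
  seg_len <- if (nrow(seg$speech_segments)) {
    seg$speech_segments[, 2] - seg$speech_segments[, 1]
  } else numeric(0)
  pause_len <- if (nrow(seg$pauses)) {
    seg$pauses[, 2] - seg$pauses[, 1]
  } else numeric(0)
  phon <- sum(seg_len)
  list(
    speech_ratio = phon / seg$total_duration_s,
    total_phonation_time_s = phon,
    num_pauses = length(pause_len),
    mean_pause_length_s = if (length(pause_len)) mean(pause_len) else 0,
    num_segments = length(seg_len),
    mean_segment_length_s = if (length(seg_len)) mean(seg_len) else 0,
    speaking_rate_proxy = length(seg_len) / seg$total_duration_s
  )
}

#' Export a segmentation as a labeled interval table
#'
#' @param seg A `segmentation`.
#' @param path Optional CSV path; when given the table is written there.
#' @return Data frame with columns `label` (speech/pause), `start_s`, `end_s`.
#' @export
segmentation_table <- function(seg, path = NULL) {
  df <- rbind(
    if (nrow(seg$speech_segments)) {
      data.frame(label = "speech", start_s = seg$speech_segments[, 1],
                 end_s = seg$speech_segments[, 2])
    },
    if (nrow(seg$pauses)) {
      data.frame(label = "pause", start_s = seg$pauses[, 1],
                 end_s = seg$pauses[, 2])
    }
  )
  if (is.null(df)) {
    df <- data.frame(label = character(0), start_s = numeric(0),
                     end_s = numeric(0))
  }
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
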