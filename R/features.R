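#' Extraction settings
#'
#' Collects every tunable of the extraction stage with speech-analysis
#' defaults: 25 ms frames with a 10 ms hop (40 ms for pitch, whose lowest
#' search frequency needs longer windows), a level-invariant voice-activity
#' threshold at 10% of the robust energy scale, 0.25 s minimum pauses,
#' 0.10 s minimum speech runs, a 60-400 Hz f0 search range covering adult
#' male and female voices (gender-specific ranges can be set per call), and
#' 13 MFCCs from a 26-filter mel bank.
#'
#' @param ... Overrides for any default listed above.
#' @return A named list of settings.
#' @export
extraction_config <- function(...) {
  cfg <- list(
    frame_length_s = 0.025, hop_s = 0.010, f0_frame_length_s = 0.040,
    energy_threshold_rel = 0.1, min_pause_s = 0.25, min_segment_s = 0.10,
    f0_min = 60, f0_max = 400, voicing_threshold = 0.45,
    n_mfcc = 13L, n_mel = 26L, lpc_order = NULL, max_bandwidth_hz = 400,
    formant_hop_s = 0.020, f0_hop_s = NULL, mfcc_hop_s = NULL,
    harmonic_windows = 128L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown extraction settings: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  cfg
}

#' Throughput-oriented extraction settings
#'
#' The same extractors with coarser analysis hops (15 ms pitch, 20 ms
#' MFCC, 30 ms formant frames) and fewer harmonic-averaging windows, for
#' large simulation studies where thousands of recordings are processed.
#' Feature estimates are statistically equivalent, only marginally noisier.
#'
#' @param ... Further overrides, as in [extraction_config()].
#' @return A named list of settings.
#' @export
fast_extraction_config <- function(...) {
  extraction_config(f0_hop_s = 0.015, mfcc_hop_s = 0.020,
                    formant_hop_s = 0.030, harmonic_windows = 16L, ...)
}

#' Feature registry
#'
#' The fixed column schema of the feature table: every feature with its
#' category (temporal, prosodic, formant, source, spectral) and whether it
#' is reserved for the machine-learning stage (`ml_only`, true for the
#' MFCC/delta/delta-delta family, which is excluded from the correlation
#' analysis).
#'
#' @param n_mfcc Number of cepstral coefficients (default 13).
#' @return Data frame with columns `feature`, `category`, `ml_only`.
#' @export
feature_registry <- function(n_mfcc = 13L) {
  ix <- sprintf("%02d", 0:(n_mfcc - 1))
  spectral <- c(paste0("mfcc_mean_", ix), paste0("mfcc_sd_", ix),
                paste0("delta_mean_", ix), paste0("delta_sd_", ix),
                paste0("deltadelta_mean_", ix), paste0("deltadelta_sd_", ix))
  reg <- rbind(
    data.frame(feature = c("speech_ratio", "total_phonation_time_s",
                           "num_pauses", "mean_pause_length_s",
                           "num_segments", "mean_segment_length_s",
                           "speaking_rate_proxy"),
               category = "temporal"),
    data.frame(feature = c("f0_mean_hz", "f0_sd_hz", "f0_range_hz",
                           "voiced_fraction", "mean_power", "total_power",
                           "amplitude_kurtosis", "amplitude_skewness"),
               category = "prosodic"),
    data.frame(feature = c("jitter_local_pct", "shimmer_local_pct",
                           "hnr_db", "snr_db"),
               category = "source"),
    data.frame(feature = c("f1_mean_hz", "f2_mean_hz", "f3_mean_hz",
                           "f1_sd_hz", "f2_sd_hz", "f3_sd_hz"),
               category = "formant"),
    data.frame(feature = spectral, category = "spectral")
  )
  reg$ml_only <- reg$category == "spectral"
  reg
}

#' Extract the full feature set from one recording
#'
#' Runs segmentation and all extractor families and returns one named value
#' per registry feature. Voiced-dependent features are `NA` for silent or
#' unvoiced recordings; temporal features are defined (zero speech) for any
#' nonempty recording. The sound-to-noise ratio `snr_db` is exported as an
#' alias of the harmonics-to-noise estimator `hnr_db`.
#'
#' @param rec An [audio_recording()].
#' @param config An [extraction_config()].
#' @return Named numeric vector over [feature_registry()] features.
#' @export
extract_features_one <- function(rec, config = extraction_config()) {
  cfg <- config
  seg <- detect_voice_activity(rec, cfg$energy_threshold_rel,
                               cfg$min_pause_s, cfg$min_segment_s,
                               cfg$frame_length_s, cfg$hop_s)
  tf <- temporal_features(seg)
  contour <- estimate_f0_contour(rec, seg, cfg$f0_min, cfg$f0_max,
                                 cfg$voicing_threshold,
                                 cfg$f0_frame_length_s,
                                 cfg$f0_hop_s %||% cfg$hop_s)
  per <- suppressWarnings(extract_periods(rec, contour))
  hnr <- harmonics_to_noise(rec, contour, periods = per)
  pros <- prosodic_features(rec, contour, seg)
  form <- formants_lpc(rec, seg, contour, cfg$lpc_order,
                       cfg$max_bandwidth_hz, cfg$frame_length_s,
                       cfg$formant_hop_s,
                       harmonic_windows = cfg$harmonic_windows)
  spec <- mfcc_features(rec, seg, cfg$n_mfcc, cfg$n_mel,
                        cfg$frame_length_s, cfg$mfcc_hop_s %||% cfg$hop_s)
  ix <- sprintf("%02d", 0:(cfg$n_mfcc - 1))
  vals <- c(
    unlist(tf), unlist(pros),
    jitter_local_pct = jitter_local(per),
    shimmer_local_pct = shimmer_local(per),
    hnr_db = hnr, snr_db = hnr,
    unlist(form[c("f1_mean_hz", "f2_mean_hz", "f3_mean_hz",
                  "f1_sd_hz", "f2_sd_hz", "f3_sd_hz")]),
    setNames(spec$mfcc_means, paste0("mfcc_mean_", ix)),
    setNames(spec$mfcc_sds, paste0("mfcc_sd_", ix)),
    setNames(spec$delta_means, paste0("delta_mean_", ix)),
    setNames(spec$delta_sds, paste0("delta_sd_", ix)),
    setNames(spec$delta_delta_means, paste0("deltadelta_mean_", ix)),
    setNames(spec$delta_delta_sds, paste0("deltadelta_sd_", ix))
  )
  reg <- feature_registry(cfg$n_mfcc)
  out <- setNames(rep(NA_real_, nrow(reg)), reg$feature)
  out[names(vals)] <- vals
  out
}

#' Assemble the analysis-ready feature table
#'
#' Runs the full extractor battery over a collection of recordings and
#' returns the canonical long-form table, one row per (subject, task,
#' feature). Per-recording extraction failures are logged and leave the row
#' present with missing values; duplicated (subject, task) pairs are an
#' integrity error. The column schema is fixed by [feature_registry()]
#' regardless of which recordings are present.
#'
#' @param recordings List of [audio_recording()] objects.
#' @param config An [extraction_config()].
#' @return A `feature_table`: data frame with columns `subject_id`, `task`,
#'   `feature`, `category`, `ml_only`, `value`; attribute `log` holds
#'   per-recording failure messages.
#' @export
extract_all <- function(recordings, config = extraction_config()) {
  reg <- feature_registry(config$n_mfcc)
  keys <- vapply(recordings, function(r) {
    paste(r$subject_id, r$task, sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject_id, task) recordings: ",
         paste(unique(gsub("\r", "/", keys[duplicated(keys)])),
               collapse = ", "), call. = FALSE)
  }
  log <- character(0)
  vals <- vapply(recordings, function(rec) {
    tryCatch(unname(extract_features_one(rec, config)[reg$feature]),
             error = function(e) {
               log <<- c(log, sprintf("extraction failed for %s/%s: %s",
                                      rec$subject_id, rec$task,
                                      conditionMessage(e)))
               rep(NA_real_, nrow(reg))
             })
  }, numeric(nrow(reg)))
  out <- if (length(recordings)) {
    data.frame(
      subject_id = rep(vapply(recordings, `[[`, "", "subject_id"),
                       each = nrow(reg)),
      task = rep(vapply(recordings, `[[`, "", "task"), each = nrow(reg)),
      feature = rep(reg$feature, length(recordings)),
      category = rep(reg$category, length(recordings)),
      ml_only = rep(reg$ml_only, length(recordings)),
      value = as.vector(vals))
  } else {
    data.frame(subject_id = character(0), task = character(0),
               feature = character(0), category = character(0),
               ml_only = logical(0), value = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "registry") <- reg
  attr(out, "log") <- log
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Pivot the long feature table to one row per subject
#'
#' Features are suffixed by task (`_pos`, `_neg`), the layout used by the
#' regression stage.
#'
#' @param features A `feature_table` from [extract_all()].
#' @param include_spectral Keep the MFCC family columns (default TRUE).
#' @return Data frame with `subject_id` and one column per feature x task.
#' @export
pivot_features_wide <- function(features, include_spectral = TRUE) {
  ft <- features
  if (!include_spectral) ft <- ft[!ft$ml_only, , drop = FALSE]
  ft$col <- paste0(ft$feature, ifelse(ft$task == "positive", "_pos", "_neg"))
  subjects <- unique(ft$subject_id)
  cols <- unique(ft$col)
  wide <- matrix(NA_real_, length(subjects), length(cols),
                 dimnames = list(subjects, cols))
  wide[cbind(match(ft$subject_id, subjects), match(ft$col, cols))] <- ft$value
  data.frame(subject_id = subjects, wide, row.names = NULL,
             check.names = FALSE)
}

#' Write a feature table to CSV
#'
#' @param features A `feature_table`.
#' @param path Output CSV path (long form).
#' @param meta Optional named list written as `# key=value` header comments.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, meta = NULL) {
  write_csv_with_meta(as.data.frame(features), path, meta)
}

#' Read a long-form feature CSV back into a feature table
#'
#' @param path CSV written by [write_feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "task", "feature", "category", "ml_only", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature CSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("feature_table", "data.frame")
  df
}

write_csv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, as.character, character(1))), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
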