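# File-based pipeline stages: each stage writes CSV/JSON artifacts that
# embed the package version, master seed and a configuration hash, so a run
# is reproducible from its outputs alone.

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

artifact_meta <- function(seed, cfg) {
  list(package = "speechnpi",
       version = as.character(packageVersion("speechnpi")),
       seed = seed, config_md5 = config_hash(cfg))
}

#' Simulate a study to disk
#'
#' Writes one WAV per subject and task, the cohort CSV, and a ground-truth
#' JSON with the latent acoustic parameters per recording (the reference
#' for oracle comparisons).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_sim_config()]; default scenario when `NULL`.
#' @param seed Master seed (default `config$seed`).
#' @param sample_rate Sampling rate (default 16000).
#' @param write_wavs Write waveforms (set `FALSE` to emit only cohort and
#'   ground truth).
#' @return Invisible list with `cohort_csv`, `truth_json`, `wav_dir` and
#'   the generated objects.
#' @export
simulate_study <- function(out_dir, config = NULL, seed = NULL,
                           sample_rate = 16000, write_wavs = TRUE) {
  if (is.null(config)) config <- default_paper_scenario()
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohort(config, seed)
  meta <- artifact_meta(seed, config)
  cohort_csv <- file.path(out_dir, "cohort.csv")
  write_cohort(gen$cohort, cohort_csv, meta)
  truth_json <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(meta = meta, latents = gen$latents), truth_json,
                       auto_unbox = TRUE, digits = NA)
  wav_dir <- file.path(out_dir, "audio")
  if (write_wavs) {
    dir.create(wav_dir, showWarnings = FALSE)
    for (key in names(gen$specs)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      rec <- synthesize_voice(gen$specs[[key]], sample_rate,
                              subject_id = parts[1], task = parts[2])
      write_wav(rec, file.path(wav_dir,
                               paste0(parts[1], "_", parts[2], ".wav")))
    }
  }
  invisible(list(cohort_csv = cohort_csv, truth_json = truth_json,
                 wav_dir = if (write_wavs) wav_dir else NULL, gen = gen))
}

read_manifest <- function(manifest) {
  mf <- read.csv(manifest, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "task", "path")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  missing_files <- mf$path[!file.exists(mf$path)]
  if (length(missing_files)) {
    stop("manifest references missing file(s): ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  mf
}

#' Extract features for a directory or manifest of recordings
#'
#' Recordings come either from `audio_dir` (files matching
#' `<subject>_<positive|negative>.wav`) or from a manifest CSV with columns
#' `subject_id,task,path` (the manifest wins when both are given). Writes
#' the long and wide feature CSVs and a per-recording log.
#'
#' @param out_dir Output directory.
#' @param audio_dir Directory of WAV files.
#' @param manifest Manifest CSV path.
#' @param config An [extraction_config()].
#' @param seed Seed recorded in the artifacts (extraction itself is
#'   deterministic).
#' @return Invisible list with `features`, `long_csv`, `wide_csv`,
#'   `log_file`.
#' @export
run_extraction <- function(out_dir, audio_dir = NULL, manifest = NULL,
                           config = extraction_config(), seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(manifest)) {
    mf <- read_manifest(manifest)
    recs <- lapply(seq_len(nrow(mf)), function(i) {
      read_wav(mf$path[i], subject_id = mf$subject_id[i], task = mf$task[i])
    })
  } else if (!is.null(audio_dir)) {
    paths <- sort(list.files(audio_dir, pattern = "\\.wav$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(paths)) stop("no .wav files in ", audio_dir, call. = FALSE)
    recs <- lapply(paths, read_wav)
    bad <- vapply(recs, function(r) is.na(r$task), logical(1))
    if (any(bad)) {
      stop("cannot parse task from filename(s): ",
           paste(basename(paths[bad]), collapse = ", "), call. = FALSE)
    }
  } else {
    stop("provide audio_dir or manifest", call. = FALSE)
  }
  features <- extract_all(recs, config)
  meta <- artifact_meta(seed, config)
  long_csv <- file.path(out_dir, "features_long.csv")
  write_feature_table(features, long_csv, meta)
  wide_csv <- file.path(out_dir, "features_wide.csv")
  write_csv_with_meta(pivot_features_wide(features), wide_csv, meta)
  log_file <- file.path(out_dir, "extraction_log.txt")
  writeLines(c(sprintf("# %d recording(s) processed", length(recs)),
               attr(features, "log")), log_file)
  invisible(list(features = features, long_csv = long_csv,
                 wide_csv = wide_csv, log_file = log_file))
}

as_feature_table <- function(features) {
  if (inherits(features, "feature_table")) features
  else read_feature_table(features)
}

as_cohort_table <- function(cohort) {
  if (inherits(cohort, "cohort_table")) cohort else load_cohort(cohort)
}

#' Run the stratified correlation analysis and write its reports
#'
#' Writes the full results CSV, the significant-only CSV (plain and
#' MMSE-partial estimates side by side), and a run-summary JSON with counts
#' per stratum and any skipped strata.
#'
#' @param out_dir Output directory.
#' @param features A `feature_table` or path to a long feature CSV.
#' @param cohort A `cohort_table` or path to a cohort CSV.
#' @param q_level FDR level (default 0.05).
#' @param min_n Minimum observations per test (default 5).
#' @param seed Seed recorded in the artifacts.
#' @return Invisible list with `results`, `full_csv`, `significant_csv`,
#'   `summary_json`.
#' @export
run_correlations <- function(out_dir, features, cohort, q_level = 0.05,
                             min_n = 5, seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- as_feature_table(features)
  co <- as_cohort_table(cohort)
  res <- run_correlation_analysis(ft, co, q_level = q_level, min_n = min_n)
  cfg <- list(q_level = q_level, min_n = min_n)
  meta <- artifact_meta(seed, cfg)
  full_csv <- file.path(out_dir, "correlations_full.csv")
  write_csv_with_meta(as.data.frame(res), full_csv, meta)
  sig <- significant_correlations(res)
  sig_csv <- file.path(out_dir, "correlations_significant.csv")
  write_csv_with_meta(sig, sig_csv, meta)
  strata <- unique(res[, c("gender", "task")])
  summary_json <- file.path(out_dir, "correlation_summary.json")
  jsonlite::write_json(list(
    meta = meta, n_tests = nrow(res), n_significant_plain =
      sum(res$significant & !res$partial, na.rm = TRUE),
    n_significant_partial = sum(res$significant & res$partial, na.rm = TRUE),
    strata = if (nrow(strata)) strata else list(),
    skipped_strata = attr(res, "skipped")
  ), summary_json, auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, full_csv = full_csv,
                 significant_csv = sig_csv, summary_json = summary_json))
}

#' Run the regression experiments and write their reports
#'
#' Writes a results CSV shaped like a per-subscale/gender MAE table (model
#' MAE, baseline MAE, beats-baseline flag) and the selected-features CSV of
#' the sparse model.
#'
#' @param out_dir Output directory.
#' @param features A `feature_table` or path to a long feature CSV.
#' @param cohort A `cohort_table` or path to a cohort CSV.
#' @param ... Passed to [run_ml_experiments()].
#' @param seed Seed recorded in the artifacts.
#' @return Invisible list with `results`, `results_csv`, `selected_csv`.
#' @export
run_regressions <- function(out_dir, features, cohort, ..., seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- as_feature_table(features)
  co <- as_cohort_table(cohort)
  res <- run_ml_experiments(ft, co, ...)
  meta <- artifact_meta(seed, list(...))
  results_csv <- file.path(out_dir, "regression_results.csv")
  write_csv_with_meta(as.data.frame(res), results_csv, meta)
  selected_csv <- file.path(out_dir, "selected_features.csv")
  write_csv_with_meta(attr(res, "selected"), selected_csv, meta)
  invisible(list(results = res, results_csv = results_csv,
                 selected_csv = selected_csv))
}

#' End-to-end pipeline over simulated or recorded data
#'
#' Chains extraction, correlation analysis and regression experiments,
#' writing every artifact under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param audio_dir,manifest Audio source (see [run_extraction()]).
#' @param cohort Cohort CSV path or `cohort_table`.
#' @param extraction An [extraction_config()].
#' @param q_level,min_n Correlation settings.
#' @param ml_args List of extra arguments for [run_ml_experiments()].
#' @param seed Seed recorded in all artifacts.
#' @return Invisible list with the three stage results.
#' @export
run_pipeline <- function(out_dir, cohort, audio_dir = NULL, manifest = NULL,
                         extraction = extraction_config(), q_level = 0.05,
                         min_n = 5, ml_args = list(), seed = 0L) {
  ex <- run_extraction(out_dir, audio_dir = audio_dir, manifest = manifest,
                       config = extraction, seed = seed)
  co <- as_cohort_table(cohort)
  an <- run_correlations(out_dir, ex$features, co, q_level = q_level,
                         min_n = min_n, seed = seed)
  ml <- do.call(run_regressions,
                c(list(out_dir, ex$features, co, seed = seed), ml_args))
  invisible(list(extraction = ex, correlations = an, regressions = ml))
}
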