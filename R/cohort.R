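npi_valid_scores <- function() {
  sort(unique(c(0, as.vector(outer(1:4, 1:3)))))  # frequency x severity
}

#' Validate a participant table
#'
#' Checks the clinical-table invariants: unique subject identifiers, gender
#' in {female, male}, MMSE between 0 and 30, and each NPI subscale score in
#' {0..12} and expressible as frequency (1-4) times severity (1-3) or 0.
#' Validation is total: either every row satisfies the invariants or the
#' call fails with a diagnostic listing every offending row.
#'
#' @param df Data frame with columns `subject_id`, `gender`, `age`, `mmse`,
#'   `npi_apathy`, `npi_depression`, `npi_anxiety`.
#' @return A `cohort_table` (the validated data frame with attributes `n`,
#'   `n_female`, `n_male`).
#' @export
validate_cohort <- function(df) {
  need <- c("subject_id", "gender", "age", "mmse", "npi_apathy",
            "npi_depression", "npi_anxiety")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$gender <- tolower(as.character(df$gender))
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d (%s): %s", rows,
                                       df$subject_id[rows], what))
    }
  }
  note(which(duplicated(df$subject_id)), "duplicate subject_id")
  note(which(!df$gender %in% c("female", "male")),
       "gender must be 'female' or 'male'")
  note(which(!is.finite(df$mmse) | df$mmse < 0 | df$mmse > 30 |
               df$mmse != round(df$mmse)), "mmse must be an integer in [0, 30]")
  valid <- npi_valid_scores()
  for (sc in c("npi_apathy", "npi_depression", "npi_anxiety")) {
    note(which(!df[[sc]] %in% valid),
         sprintf("%s must be 0 or frequency (1-4) x severity (1-3)", sc))
  }
  if (length(problems)) {
    stop("invalid cohort table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(df, n = nrow(df), n_female = sum(df$gender == "female"),
            n_male = sum(df$gender == "male"),
            class = c("cohort_table", "data.frame"))
}

#' Load and validate a cohort CSV
#'
#' Expected schema:
#' `subject_id,gender,age,mmse,npi_apathy,npi_depression,npi_anxiety`.
#'
#' @param path CSV path.
#' @return A `cohort_table`; see [validate_cohort()].
#' @export
load_cohort <- function(path) {
  validate_cohort(read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE))
}

#' Write a cohort table to CSV
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @param meta Optional named list of `# key=value` header comments.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, meta = NULL) {
  write_csv_with_meta(as.data.frame(cohort), path, meta)
}

#' Spearman correlations between MMSE and the NPI subscales, per gender
#'
#' @param cohort A `cohort_table`.
#' @param min_n Minimum stratum size (strata below it are skipped with a
#'   warning; default 5).
#' @return Data frame with columns `gender`, `subscale`, `rho`, `p_value`,
#'   `n`.
#' @export
mmse_subscale_correlations <- function(cohort, min_n = 5) {
  out <- list()
  for (g in c("female", "male")) {
    sub <- cohort[cohort$gender == g, , drop = FALSE]
    if (nrow(sub) < min_n) {
      if (nrow(sub) > 0) {
        warning(sprintf("stratum '%s' has %d participants (< %d); skipped",
                        g, nrow(sub), min_n))
      }
      next
    }
    for (sc in c("apathy", "depression", "anxiety")) {
      r <- spearman(sub$mmse, sub[[paste0("npi_", sc)]], min_n = min_n)
      out[[length(out) + 1]] <- data.frame(
        gender = g, subscale = sc, rho = r$rho, p_value = r$p_value,
        n = r$n_used)
    }
  }
  if (!length(out)) {
    return(data.frame(gender = character(0), subscale = character(0),
                      rho = numeric(0), p_value = numeric(0), n = integer(0)))
  }
  do.call(rbind, out)
}
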