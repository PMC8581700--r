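#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with the
#' t-approximation p-value on `n - 2` degrees of freedom, the behavior of
#' common statistical software at moderate sample sizes. Pairs with missing
#' values are dropped (pairwise-complete).
#'
#' @param x,y Equal-length numeric vectors.
#' @param min_n Minimum complete pairs required (default 5).
#' @param p_method `"t"` (default) or `"permutation"`, a seeded Monte-Carlo
#'   permutation p-value recommended for very small samples (n < 10) where
#'   the t approximation is coarse.
#' @param n_perm,perm_seed Permutation count and seed for the permutation
#'   mode.
#' @return List with `rho`, `p_value`, `n_used`; `rho` is `NA` (with a
#'   `reason` field) when a vector has zero rank variance or too few pairs.
#' @export
spearman <- function(x, y, min_n = 5, p_method = c("t", "permutation"),
                     n_perm = 2000, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                reason = "too few complete pairs"))
  }
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                reason = "zero rank variance"))
  }
  rho <- cor(rx, ry)
  p <- if (p_method == "t") {
    t_approx_p(rho, n - 2)
  } else {
    with_seed(perm_seed, {
      null_rho <- vapply(seq_len(n_perm), function(i) {
        cor(rx, sample(ry))
      }, numeric(1))
      (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rho = rho, p_value = p, n_used = n)
}

t_approx_p <- function(r, df) {
  r <- min(max(r, -1), 1)
  if (df <= 0) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tval), df)
}

#' Partial Spearman correlation given a covariate
#'
#' Rank-transforms `x`, `y` and `z` and computes the first-order partial
#' correlation `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` on the
#' ranks, with a t-approximation p-value on `n - 3` degrees of freedom.
#' Observations are complete on all three vectors jointly, so plain and
#' partial results computed from the same triples differ only by the
#' conditioning. A covariate with zero rank variance cannot be partialled
#' out; the plain Spearman result is returned with `degenerate_covariate`
#' set.
#'
#' @param x,y,z Equal-length numeric vectors (`z` is the covariate).
#' @param min_n Minimum complete triples (default 5).
#' @return List with `rho`, `p_value`, `n_used`, `degenerate_covariate`.
#' @export
partial_spearman <- function(x, y, z, min_n = 5) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < min_n) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                degenerate_covariate = FALSE,
                reason = "too few complete triples"))
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (var(rx) == 0 || var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                degenerate_covariate = FALSE,
                reason = "zero rank variance"))
  }
  if (var(rz) == 0) {
    res <- spearman(x, y, min_n)
    res$degenerate_covariate <- TRUE
    return(res)
  }
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                degenerate_covariate = FALSE,
                reason = "covariate collinear with a variable"))
  }
  rho <- (rxy - rxz * ryz) / den
  list(rho = rho, p_value = t_approx_p(rho, n - 3), n_used = n,
       degenerate_covariate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (the standard
#' `p.adjust(..., "BH")` computation) and rejection flags at `q_level`.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param q_level FDR level for the rejection flags (default 0.05).
#' @return List with `q_values` and `reject`.
#' @export
benjamini_hochberg <- function(p_values, q_level = 0.05) {
  if (!length(p_values)) {
    return(list(q_values = numeric(0), reject = logical(0)))
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= q_level)
}

#' Stratified correlation analysis of speech features and NPI subscales
#'
#' For every stratum (gender x task) and subscale, computes the plain
#' Spearman correlation and the MMSE-partial Spearman correlation between
#' each non-spectral feature and the subscale score, on the jointly complete
#' observations. Benjamini-Hochberg correction is applied within each
#' feature category separately for every (gender, task, subscale) cell and
#' separately for the plain and partial families, the finest reading of
#' per-category correction; p-values are never pooled across categories or
#' strata.
#'
#' @param features A `feature_table` from [extract_all()].
#' @param cohort A `cohort_table`.
#' @param q_level FDR level (default 0.05).
#' @param min_n Minimum complete observations per test (strata below it are
#'   skipped and listed in the `skipped` attribute; default 5).
#' @return A `correlation_results` data frame: one row per (feature, task,
#'   gender, subscale, partial) with `rho`, `p_value`, `q_value`,
#'   `significant`, `n_used`.
#' @export
run_correlation_analysis <- function(features, cohort, q_level = 0.05,
                                     min_n = 5) {
  shared <- intersect(unique(features$subject_id), cohort$subject_id)
  if (!length(shared)) {
    stop("feature table and cohort share no subject ids", call. = FALSE)
  }
  ft <- features[!features$ml_only & features$subject_id %in% shared, ,
                 drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (g in c("female", "male")) {
    co <- cohort[cohort$gender == g & cohort$subject_id %in% shared, ,
                 drop = FALSE]
    for (task in c("positive", "negative")) {
      sub <- ft[ft$task == task, , drop = FALSE]
      wide <- sub[sub$subject_id %in% co$subject_id, , drop = FALSE]
      if (nrow(co) < min_n || !nrow(wide)) {
        skipped <- c(skipped, sprintf("%s/%s", g, task))
        next
      }
      feats <- unique(wide$feature)
      vals <- matrix(NA_real_, nrow(co), length(feats),
                     dimnames = list(co$subject_id, feats))
      vals[cbind(match(wide$subject_id, co$subject_id),
                 match(wide$feature, feats))] <- wide$value
      cat_of <- wide$category[match(feats, wide$feature)]
      for (sc in c("apathy", "depression", "anxiety")) {
        y <- co[[paste0("npi_", sc)]]
        z <- co$mmse
        for (i in seq_along(feats)) {
          x <- vals[, i]
          ok <- is.finite(x) & is.finite(y) & is.finite(z)
          plain <- spearman(x[ok], y[ok], min_n)
          part <- partial_spearman(x[ok], y[ok], z[ok], min_n)
          rows[[length(rows) + 1]] <- data.frame(
            feature = feats[i], category = cat_of[i], task = task,
            gender = g, subscale = sc,
            rho = c(plain$rho, part$rho),
            p_value = c(plain$p_value, part$p_value),
            partial = c(FALSE, TRUE),
            n_used = c(plain$n_used, part$n_used))
        }
      }
    }
  }
  if (!length(rows)) {
    res <- data.frame(feature = character(0), category = character(0),
                      task = character(0), gender = character(0),
                      subscale = character(0), rho = numeric(0),
                      p_value = numeric(0), partial = logical(0),
                      n_used = integer(0), q_value = numeric(0),
                      significant = logical(0))
    attr(res, "skipped") <- skipped
    class(res) <- c("correlation_results", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  res$significant <- FALSE
  grp <- interaction(res$category, res$task, res$gender, res$subscale,
                     res$partial, drop = TRUE)
  for (g in levels(grp)) {
    ix <- which(grp == g & is.finite(res$p_value))
    if (!length(ix)) next
    bh <- benjamini_hochberg(res$p_value[ix], q_level)
    res$q_value[ix] <- bh$q_values
    res$significant[ix] <- bh$reject
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "q_level") <- q_level
  class(res) <- c("correlation_results", "data.frame")
  res
}

#' Significant-only view of correlation results
#'
#' One row per feature/stratum/subscale that is significant after FDR
#' correction in the plain analysis, with the partial (MMSE-corrected)
#' estimate side by side - the tabular equivalent of a signed correlation
#' dot plot.
#'
#' @param results A `correlation_results` data frame.
#' @return Data frame with plain and partial rho/q columns.
#' @export
significant_correlations <- function(results) {
  plain <- results[!results$partial, , drop = FALSE]
  part <- results[results$partial, , drop = FALSE]
  key <- function(d) paste(d$feature, d$task, d$gender, d$subscale)
  m <- match(key(plain), key(part))
  keep <- plain$significant | (!is.na(m) & part$significant[m])
  out <- data.frame(
    feature = plain$feature, category = plain$category, task = plain$task,
    gender = plain$gender, subscale = plain$subscale,
    rho = plain$rho, q_value = plain$q_value,
    significant = plain$significant,
    rho_partial = part$rho[m], q_value_partial = part$q_value[m],
    significant_partial = part$significant[m],
    n_used = plain$n_used
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
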