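col_sds <- function(m) apply(m, 2, sd)

#' Leave-one-out cross-validated regression
#'
#' Fits exactly N models, each trained on N - 1 observations and evaluated
#' on the held-out one; the reported error is the mean of the N absolute
#' errors. Missing-feature imputation (training-fold column mean) and
#' z-score normalization (training-fold mean and SD) are fitted inside each
#' training fold, never touching the held-out observation; a constant
#' feature within a training fold gets SD 1 (no-op scaling). Supported
#' models: `"svr"` (radial-basis support vector regression), `"lasso"`
#' (L1-penalized linear regression) and `"mean"` (training-mean baseline).
#'
#' @param X Numeric feature matrix (rows = observations); may contain NAs.
#' @param y Numeric response without missing values, `length(y) == nrow(X)`.
#' @param model One of `"svr"`, `"lasso"`, `"mean"`.
#' @param params Hyperparameters: `svr_cost` (1), `svr_epsilon` (0.1),
#'   `lasso_lambda` (0.1).
#' @return List with `mae`, `predictions`, `abs_errors`, `n_models` and,
#'   for the lasso, `selected` (per-fold character vectors of
#'   nonzero-coefficient features).
#' @export
loocv_evaluate <- function(X, y, model = c("svr", "lasso", "mean"),
                           params = list()) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 3, all(is.finite(y)))
  par <- list(svr_cost = 1, svr_epsilon = 0.1, lasso_lambda = 0.1)
  par[names(params)] <- params
  preds <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    te <- X[i, , drop = FALSE]
    mu <- colMeans(tr, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (j in seq_len(ncol(tr))) {
      tr[is.na(tr[, j]), j] <- mu[j]
      te[is.na(te[, j]), j] <- mu[j]
    }
    sdv <- apply(tr, 2, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    trs <- scale(tr, center = mu, scale = sdv)
    tes <- scale(te, center = mu, scale = sdv)
    ytr <- y[-i]
    if (sd(ytr) == 0) {
      # degenerate training response: every model collapses to the mean
      preds[i] <- mean(ytr)
      next
    }
    preds[i] <- switch(
      model,
      mean = mean(ytr),
      svr = {
        fit <- e1071::svm(x = trs, y = ytr, type = "eps-regression",
                          kernel = "radial", cost = par$svr_cost,
                          epsilon = par$svr_epsilon, scale = FALSE)
        as.numeric(predict(fit, tes))
      },
      lasso = {
        Xl <- trs; Tl <- tes
        if (ncol(Xl) < 2) {  # glmnet needs >= 2 columns
          Xl <- cbind(Xl, `.dummy` = 0)
          Tl <- cbind(Tl, `.dummy` = 0)
        }
        if (all(col_sds(Xl) == 0)) {
          # nothing to regress on: the penalized fit is the intercept
          selected[[i]] <- character(0)
          mean(ytr)
        } else {
        fit <- glmnet::glmnet(Xl, ytr, alpha = 1,
                              lambda = par$lasso_lambda,
                              standardize = FALSE)
        b <- as.matrix(coef(fit))[-1, 1]
        selected[[i]] <- setdiff(names(b)[b != 0], ".dummy")
        as.numeric(predict(fit, Tl))
        }
      }
    )
  }
  abs_err <- abs(y - preds)
  out <- list(mae = mean(abs_err), predictions = preds,
              abs_errors = abs_err, n_models = n)
  if (model == "lasso") out$selected <- selected
  out
}

#' Leave-one-out baseline error of the training-mean predictor
#'
#' Closed form `mean_i |y_i - mean(y[-i])|`, exactly the LOOCV error of the
#' predictor that always outputs its training-fold mean.
#'
#' @param y Numeric score vector, `length(y) >= 2`.
#' @return Baseline MAE in the units of `y`.
#' @export
baseline_mae <- function(y) {
  n <- length(y)
  stopifnot(n >= 2, all(is.finite(y)))
  loo_mean <- (sum(y) - y) / (n - 1)
  mean(abs(y - loo_mean))
}

#' Stratified regression experiments on the speech feature table
#'
#' Runs the model grid gender x subscale x model x (with/without MMSE as a
#' feature) with leave-one-out cross-validation. Features from both tasks
#' enter jointly (wide form, `_pos`/`_neg` suffixes) including the spectral
#' family - the contrast with the correlation stage, where that family is
#' excluded. Each result reports the model MAE next to the training-mean
#' baseline MAE; for the lasso, features with nonzero coefficients are
#' aggregated over folds with their selection frequency.
#'
#' @param features A `feature_table` from [extract_all()].
#' @param cohort A `cohort_table`.
#' @param models Subset of `c("svr", "lasso")`.
#' @param include_mmse Logical vector of MMSE-feature settings to run
#'   (default `c(FALSE, TRUE)`).
#' @param subscales Subset of `c("apathy", "depression", "anxiety")`.
#' @param genders Subset of `c("female", "male")`.
#' @param params Hyperparameters passed to [loocv_evaluate()].
#' @param min_n Minimum stratum size (default 10); smaller strata are
#'   skipped with a warning.
#' @param tasks `"both"` (default, joint wide features) or one of
#'   `"positive"`/`"negative"` to restrict to a single task's features.
#' @return A `regression_results` data frame (one row per experiment) with
#'   `mae`, `baseline_mae`, `beats_baseline`, `n`; attribute `selected`
#'   holds the per-experiment lasso selection table.
#' @export
run_ml_experiments <- function(features, cohort,
                               models = c("svr", "lasso"),
                               include_mmse = c(FALSE, TRUE),
                               subscales = c("apathy", "depression",
                                             "anxiety"),
                               genders = c("female", "male"),
                               params = list(), min_n = 10,
                               tasks = "both") {
  models <- match.arg(models, c("svr", "lasso"), several.ok = TRUE)
  ft <- features
  if (!identical(tasks, "both")) {
    ft <- ft[ft$task %in% tasks, , drop = FALSE]
  }
  wide <- pivot_features_wide(ft, include_spectral = TRUE)
  merged <- merge(as.data.frame(cohort), wide, by = "subject_id")
  feat_cols <- setdiff(names(wide), "subject_id")
  rows <- list()
  sel_rows <- list()
  for (g in genders) {
    sub <- merged[merged$gender == g, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning(sprintf("stratum '%s' has %d subjects (< %d); skipped",
                      g, nrow(sub), min_n))
      next
    }
    for (sc in subscales) {
      y <- sub[[paste0("npi_", sc)]]
      base <- baseline_mae(y)
      for (use_mmse in include_mmse) {
        X <- as.matrix(sub[, feat_cols, drop = FALSE])
        if (use_mmse) X <- cbind(X, mmse = sub$mmse)
        for (m in models) {
          ev <- loocv_evaluate(X, y, model = m, params = params)
          rows[[length(rows) + 1]] <- data.frame(
            gender = g, subscale = sc, model = m, include_mmse = use_mmse,
            n = nrow(sub), mae = ev$mae, baseline_mae = base,
            beats_baseline = ev$mae < base)
          if (m == "lasso") {
            tab <- table(unlist(ev$selected))
            if (length(tab)) {
              sel_rows[[length(sel_rows) + 1]] <- data.frame(
                gender = g, subscale = sc, include_mmse = use_mmse,
                feature = names(tab),
                selection_frequency = as.numeric(tab) / ev$n_models)
            }
          }
        }
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gender = character(0), subscale = character(0),
               model = character(0), include_mmse = logical(0),
               n = integer(0), mae = numeric(0), baseline_mae = numeric(0),
               beats_baseline = logical(0))
  }
  rownames(res) <- NULL
  sel <- if (length(sel_rows)) do.call(rbind, sel_rows) else {
    data.frame(gender = character(0), subscale = character(0),
               include_mmse = logical(0), feature = character(0),
               selection_frequency = numeric(0))
  }
  rownames(sel) <- NULL
  attr(res, "selected") <- sel
  class(res) <- c("regression_results", "data.frame")
  res
}
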