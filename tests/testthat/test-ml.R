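test_that("leave-one-out evaluation matches the hand-computed mean model", {
  y <- c(1, 2, 3)
  ev <- loocv_evaluate(matrix(0, 3, 1), y, model = "mean")
  expect_equal(ev$predictions, c(2.5, 2.0, 1.5))
  expect_equal(ev$mae, 1.0)
  expect_equal(ev$n_models, 3)
})

test_that("the baseline closed form equals the generic LOOCV loop", {
  expect_equal(baseline_mae(c(1, 2, 3)), 1.0)
  expect_equal(baseline_mae(c(5, 5, 5, 5)), 0)
  for (s in 1:100) {
    y <- speechnpi:::with_seed(300 + s, rnorm(sample(3:12, 1), 3, 2))
    ev <- loocv_evaluate(matrix(0, length(y), 1), y, model = "mean")
    expect_equal(baseline_mae(y), ev$mae)
    expect_equal(ev$n_models, length(y))
  }
})

test_that("fold statistics never touch the held-out observation", {
  # one feature; the held-out row's x is missing, so its prediction must
  # use the training-fold mean of x under a fitted linear-ish model;
  # with the mean model the prediction is exactly the training mean of y
  X <- matrix(c(NA, 2, 3, 4), ncol = 1)
  y <- c(10, 2, 3, 4)
  ev <- loocv_evaluate(X, y, model = "mean")
  expect_equal(ev$predictions[1], mean(y[-1]))
  # constant feature inside a fold scales as a no-op, not an error
  Xc <- cbind(c(1, 1, 1, 2), c(1, 2, 3, 4))
  expect_silent(loocv_evaluate(Xc, y, model = "lasso"))
})

test_that("both regressors learn a strong linear signal", {
  d <- speechnpi:::with_seed(17, {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    list(X = X, y = 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.5))
  })
  base <- baseline_mae(d$y)
  for (m in c("svr", "lasso")) {
    expect_lt(loocv_evaluate(d$X, d$y, model = m)$mae, base)
  }
  sel <- loocv_evaluate(d$X, d$y, model = "lasso")$selected
  expect_true(all(vapply(sel, function(s) "V1" %in% s ||
                           any(grepl("1$", s)), logical(1))))
})

planted_ml_tables <- function(n_per_gender = 24, seed = 50,
                              apathy_from_mmse = FALSE) {
  speechnpi:::with_seed(seed, {
    n <- 2 * n_per_gender
    mmse <- sample(16:30, n, TRUE)
    apathy <- if (apathy_from_mmse) {
      # map cognitive impairment onto valid frequency x severity products
      c(0L, 1L, 2L, 3L, 4L, 6L, 8L, 9L)[
        pmin(pmax(round((30 - mmse) / 2), 0), 7) + 1]
    } else {
      sample(c(0L, 0L, 1L, 2L, 3L, 4L, 6L), n, TRUE)
    }
    sr <- -0.7 * scale(apathy)[, 1] + 0.5 * rnorm(n)
    cohort <- validate_cohort(data.frame(
      subject_id = sprintf("P%02d", 1:n),
      gender = rep(c("female", "male"), each = n_per_gender),
      age = 75, mmse = mmse, npi_apathy = as.integer(apathy),
      npi_depression = 0L, npi_anxiety = sample(c(0L, 2L), n, TRUE)))
    features <- synthetic_feature_table(
      list(speech_ratio = sr, hnr_db = rnorm(n, 15),
           mfcc_mean_00 = rnorm(n)),
      sprintf("P%02d", 1:n))
    list(cohort = cohort, features = features)
  })
}

test_that("the experiment grid reports per-stratum MAE against baseline", {
  d <- planted_ml_tables()
  res <- run_ml_experiments(d$features, d$cohort, subscales = "apathy",
                            min_n = 10)
  expect_equal(nrow(res), 2 * 1 * 2 * 2)  # gender x subscale x model x mmse
  expect_true(all(res$baseline_mae >= 0))
  expect_identical(res$beats_baseline, res$mae < res$baseline_mae)
  # the planted speech-ratio signal is learnable in most cells
  expect_gt(mean(res$beats_baseline), 0.5)
  # spectral features do enter the design matrix here (ml-only contract)
  sel <- attr(res, "selected")
  expect_s3_class(sel, "data.frame")
  # lasso on the planted signal picks the informative feature
  expect_true(any(grepl("speech_ratio", sel$feature)))
})

test_that("MMSE is selected when the score is a function of MMSE", {
  d <- planted_ml_tables(seed = 51, apathy_from_mmse = TRUE)
  res <- run_ml_experiments(d$features, d$cohort, models = "lasso",
                            subscales = "apathy", include_mmse = TRUE,
                            min_n = 10)
  sel <- attr(res, "selected")
  expect_true("mmse" %in% sel$feature)
})

test_that("undersized strata are skipped and model flags restrict output", {
  d <- planted_ml_tables(n_per_gender = 4, seed = 52)
  w <- capture_warnings(res <- run_ml_experiments(d$features, d$cohort,
                                                  subscales = "apathy"))
  expect_match(w, "skipped", all = TRUE)
  expect_length(w, 2)
  expect_equal(nrow(res), 0)
  d2 <- planted_ml_tables(seed = 53)
  res2 <- run_ml_experiments(d2$features, d2$cohort, models = "lasso",
                             subscales = "apathy", include_mmse = FALSE)
  expect_setequal(unique(res2$model), "lasso")
})
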