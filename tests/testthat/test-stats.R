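# independent oracle: Spearman via explicit mid-ranks and Pearson sums
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  a <- midrank(x); b <- midrank(y)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

test_that("spearman matches the sum-of-squared-differences closed form", {
  r <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))  # = 0.8
  expect_equal(r$rho, 0.8)
  # monotone and antitone limits
  x <- c(0.3, 1.2, 5, 9, 11, 14)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # degenerate input -> explicit missing with diagnostic
  z <- spearman(rep(1, 6), x)
  expect_true(is.na(z$rho))
  expect_match(z$reason, "variance")
})

test_that("spearman agrees with a brute-force rank-Pearson oracle", {
  worst <- 0
  for (s in 1:100) {
    xy <- speechnpi:::with_seed(s, {
      n <- sample(8:40, 1)
      list(x = sample(rnorm(n)), y = round(rnorm(n), 1))  # with ties
    })
    worst <- max(worst, abs(spearman(xy$x, xy$y)$rho -
                              oracle_spearman(xy$x, xy$y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("the permutation p-value mode is seeded and sane at small n", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2, 1, 4, 3, 6, 5, 7)
  p1 <- spearman(x, y, p_method = "permutation", perm_seed = 3)
  p2 <- spearman(x, y, p_method = "permutation", perm_seed = 3)
  expect_identical(p1$p_value, p2$p_value)
  expect_lt(p1$p_value, 0.05)
  expect_equal(p1$rho, spearman(x, y)$rho)
  # near-exchangeable data: permutation p well above any threshold
  pn <- spearman(c(3, 1, 4, 1, 5, 9, 2), c(6, 2, 6, 4, 3, 3, 8),
                 p_method = "permutation", perm_seed = 4)
  expect_gt(pn$p_value, 0.1)
})

test_that("partial spearman removes a shared covariate", {
  res <- speechnpi:::with_seed(10, {
    z <- rnorm(50)
    partial_spearman(rnorm(50), z + rnorm(50, 0, 0.3), z)
  })
  expect_lt(abs(res$rho), 0.25)
  # constant covariate falls back to plain spearman with a flag
  x <- c(5, 3, 8, 1, 9, 2)
  y <- c(1, 2, 3, 4, 5, 6)
  pc <- partial_spearman(x, y, rep(7, 6))
  expect_true(pc$degenerate_covariate)
  expect_equal(pc$rho, spearman(x, y)$rho)
})

test_that("partial spearman equals the residual-regression oracle", {
  worst <- 0
  for (s in 1:100) {
    d <- speechnpi:::with_seed(200 + s, {
      n <- sample(10:50, 1)
      list(x = rnorm(n), y = rnorm(n), z = rnorm(n))
    })
    rx <- rank(d$x); ry <- rank(d$y); rz <- rank(d$z)
    ex <- residuals(lm(rx ~ rz))
    ey <- residuals(lm(ry ~ rz))
    worst <- max(worst, abs(partial_spearman(d$x, d$y, d$z)$rho -
                              cor(ex, ey)))
  }
  expect_lt(worst, 1e-10)
})

test_that("the step-up FDR adjustment matches its worked example", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(bh$q_values, rep(0.04, 4))
  expect_true(all(bh$reject))
  expect_equal(benjamini_hochberg(0.03)$q_values, 0.03)
  expect_length(benjamini_hochberg(numeric(0))$q_values, 0)
  # agreement with a hand-coded step-up adjustment
  p <- speechnpi:::with_seed(5, runif(37)^2)
  m <- length(p)
  o <- order(p)
  q_manual <- numeric(m)
  q_manual[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(benjamini_hochberg(p)$q_values, pmin(q_manual, 1))
})

make_planted_features <- function(n, seed, rho = 0.6) {
  speechnpi:::with_seed(seed, {
    apathy <- sample(c(0L, 0L, 0L, 1L, 2L, 3L, 4L, 6L, 8L), n,
                     replace = TRUE)
    sr <- -rho * scale(apathy)[, 1] + sqrt(1 - rho^2) * rnorm(n)
    list(
      cohort = validate_cohort(data.frame(
        subject_id = sprintf("P%02d", 1:n), gender = "female", age = 75,
        mmse = sample(18:30, n, TRUE), npi_apathy = apathy,
        npi_depression = 0L,
        npi_anxiety = sample(c(0L, 1L, 2L), n, TRUE))),
      features = synthetic_feature_table(
        list(speech_ratio = sr, num_pauses = rnorm(n),
             hnr_db = rnorm(n, 15), jitter_local_pct = rnorm(n, 1, 0.2),
             f1_mean_hz = rnorm(n, 500, 30),
             mfcc_mean_00 = rnorm(n)),
        sprintf("P%02d", 1:n)))
  })
}

test_that("the stratified analysis covers the full design and excludes
           the spectral family", {
  d <- make_planted_features(40, seed = 9)
  res <- run_correlation_analysis(d$features, d$cohort)
  expect_false("mfcc_mean_00" %in% res$feature)
  # depression has zero variance -> missing rho rows are retained
  expect_true(all(c("apathy", "depression", "anxiety") %in% res$subscale))
  # completeness: feature x task x subscale x {plain, partial} for the
  # one populated gender
  feats <- setdiff(unique(d$features$feature), "mfcc_mean_00")
  expect_equal(nrow(res), length(feats) * 2 * 3 * 2)
  expect_equal(anyDuplicated(res[, c("feature", "task", "gender",
                                     "subscale", "partial")]), 0)
  # planted link found with the right sign
  hit <- res[res$feature == "speech_ratio" & res$subscale == "apathy" &
               !res$partial, ]
  expect_true(all(hit$rho < 0))
  expect_true(all(hit$significant))
  sig <- significant_correlations(res)
  expect_true("speech_ratio" %in% sig$feature)
  expect_true(all(c("rho_partial", "q_value_partial") %in% names(sig)))
})

test_that("FDR correction never pools across categories", {
  d <- make_planted_features(40, seed = 13)
  res <- run_correlation_analysis(d$features, d$cohort)
  cell <- res[res$task == "positive" & res$subscale == "apathy" &
                !res$partial, ]
  for (categ in unique(cell$category)) {
    ix <- cell$category == categ & is.finite(cell$p_value)
    if (!any(ix)) next
    expect_equal(cell$q_value[ix],
                 benjamini_hochberg(cell$p_value[ix])$q_values,
                 label = categ)
  }
})

test_that("plain and partial tests share one observation set", {
  d <- make_planted_features(30, seed = 21)
  # punch asymmetric missingness into x
  d$features$value[3] <- NA
  res <- run_correlation_analysis(d$features, d$cohort)
  expect_true(all(res$n_used[!res$partial] == res$n_used[res$partial]))
})

test_that("disjoint subject ids fail loudly", {
  d <- make_planted_features(20, seed = 31)
  d$features$subject_id <- paste0("Z", d$features$subject_id)
  expect_error(run_correlation_analysis(d$features, d$cohort), "share no")
})
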