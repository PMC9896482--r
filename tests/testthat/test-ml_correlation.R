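small_study_fm <- function(seed = 5) {
  st <- generate_study(n_configs = 10, M = 20, seed = seed)
  list(study = st, fm = feature_matrix(st$features, st$configs))
}

test_that("preprocessing log-transforms J, standardizes and one-hot encodes", {
  s <- small_study_fm()
  prep <- preprocess(s$fm, "J", s$study$truth)
  # training columns standardized to mean 0, variance 1
  num_cols <- setdiff(names(prep$train),
                      c("config_id", "y", "impeller_RC", "impeller_PBT"))
  for (col in num_cols) {
    expect_lt(abs(mean(prep$train[[col]])), 1e-10)
    expect_equal(var(prep$train[[col]]), 1, tolerance = 1e-10)
  }
  # y is log10(J): a config with J = 1 would map to 0
  idx <- match(prep$train$config_id, s$study$truth$config_id)
  expect_equal(prep$train$y, log10(s$study$truth$J[idx]), tolerance = 1e-12)
  # one-hot impeller type
  is_rc <- s$fm$impeller_type[match(prep$train$config_id, s$fm$config_id)] == "RC"
  expect_equal(prep$train$impeller_RC, as.numeric(is_rc))
  expect_equal(prep$train$impeller_PBT, as.numeric(!is_rc))
  expect_equal(prep$train$impeller_RC + prep$train$impeller_PBT,
               rep(1, nrow(prep$train)))
})

test_that("preprocessing rejects zero-variance columns and nonpositive J", {
  s <- small_study_fm()
  fm <- s$fm
  fm$k_mean <- 1
  expect_error(preprocess(fm, "J", s$study$truth), "k_mean")
  bad <- s$study$truth
  bad$J[1] <- -1
  expect_error(preprocess(s$fm, "J", bad), "log10")
})

test_that("standardization statistics come only from the training split", {
  s <- small_study_fm()
  prep1 <- preprocess(s$fm, "tg", s$study$truth)
  # mutate the test rows: training table and stats must not move
  fm2 <- s$fm
  test_rows <- fm2$split == "testing"
  fm2$sr_mean[test_rows] <- 1e6
  prep2 <- preprocess(fm2, "tg", s$study$truth)
  expect_identical(prep1$centers, prep2$centers)
  expect_identical(prep1$scales, prep2$scales)
  expect_identical(prep1$train, prep2$train)
  expect_false(identical(prep1$test$sr_mean, prep2$test$sr_mean))
})

test_that("collinearity reduction survives only near-independent columns", {
  cols4 <- c("sr_mean", "ep_mean", "k_mean", "U_mean")
  # duplicated signal under two names: exactly one survives
  set.seed(1)
  x <- rnorm(50)
  dup <- canonical_tibble(cbind(x, x, rnorm(50), rnorm(50)), cols4)
  red <- reduce_features(dup)
  expect_equal(red$kept, c("sr_mean", "k_mean", "U_mean"))
  expect_equal(red$dropped, "ep_mean")
  # mutually independent columns all retained
  ind <- canonical_tibble(matrix(rnorm(200 * 4), 200), cols4)
  expect_length(reduce_features(ind)$dropped, 0)
})

test_that("reduction of latent-block features keeps one column per block", {
  # 9 columns from 3 latent factors plus tiny noise -> 3 survivors,
  # verified against a brute-force scan of the pairwise correlations
  set.seed(9)
  n <- 120
  z <- matrix(rnorm(n * 3), n)
  X <- cbind(z[, 1], z[, 1] * 2 + 1e-4 * rnorm(n), z[, 1] + 1e-4 * rnorm(n),
             z[, 2], z[, 2] * -3 + 1e-4 * rnorm(n), z[, 2] + 1e-4 * rnorm(n),
             z[, 3], z[, 3] * 5 + 1e-4 * rnorm(n), z[, 3] + 1e-4 * rnorm(n))
  cols <- c("sr_mean", "sr_q25", "sr_q50", "ep_mean", "ep_q25", "ep_q50",
            "k_mean", "k_q25", "k_q50")
  ft <- canonical_tibble(X, cols)
  red <- reduce_features(ft, r_max = 0.95)
  expect_length(red$kept, 3L)
  # brute force: no surviving pair correlates beyond the threshold
  surv <- as.matrix(ft[, red$kept])
  cc <- abs(cor(surv))
  diag(cc) <- 0
  expect_true(all(cc <= 0.95))
  # and every dropped column exceeds the threshold against some survivor
  for (dcol in red$dropped)
    expect_true(any(abs(cor(ft[[dcol]], surv)) > 0.95))
})

test_that("PCA variance fractions behave on structured and isotropic data", {
  fracs <- function(X, cols) pca_variance(canonical_tibble(X, cols))
  cols4 <- c("sr_mean", "ep_mean", "k_mean", "U_mean")
  set.seed(2)
  f <- fracs(matrix(rnorm(80 * 4), 80), cols4)
  expect_equal(sum(f), 1, tolerance = 1e-10)
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= 0))
  # rank-2 data: components beyond the second explain nothing
  z <- matrix(rnorm(60 * 2), 60)
  X2 <- cbind(z[, 1], z[, 2], z[, 1] + z[, 2], z[, 1] - 2 * z[, 2])
  f2 <- fracs(X2, cols4)
  expect_lt(sum(f2[3:4]), 1e-10)
  # isotropic data with n >> p: leading fraction stays near 1/p
  p <- 10
  cols10 <- c("sr_mean", "sr_q25", "sr_q50", "sr_q75", "ep_mean",
              "ep_q25", "ep_q50", "ep_q75", "k_mean", "k_q25")
  f3 <- fracs(matrix(rnorm(500 * p), 500), cols10)
  expect_lt(f3[1], 1.5 * 2 / p)
})

test_that("R-squared uses the NaN convention for poor fits", {
  expect_equal(r2_with_nan(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2_with_nan(rep(2, 3), c(1, 2, 3)), 0)  # predicting the mean
  expect_true(is.nan(r2_with_nan(c(3, 3, 3), c(1, 2, 3))))  # raw R^2 = -1.5
  expect_true(is.nan(r2_with_nan(c(1, 2), c(5, 5))))  # zero-variance actuals
  expect_error(r2_with_nan(1:3, 1:2), "mismatch")
})

test_that("constant-value predictions are training group means", {
  vals <- c(10, 20, 60)
  expect_equal(constant_value_predictions(vals), 30)
  expect_equal(constant_value_predictions(5), 5)  # single-row group
  g <- c("RC", "PBT", "RC", "PBT")
  v <- c(10, 100, 20, 200)
  pred <- constant_value_predictions(v, g, "by_impeller_type",
                                     new_groups = c("RC", "PBT"))
  expect_equal(pred, c(15, 150))
  expect_error(constant_value_predictions(v, g, "by_impeller_type",
                                          new_groups = "ANCHOR"), "ANCHOR")
})

test_that("error-band metrics count predictions inside the band", {
  band <- structure(list(m5 = 0.2, m20 = 0.2, target = "J"), class = "nk_band")
  m <- error_band_metrics(c(1, 2, 3), c(1, 2, 3), band)
  expect_equal(m$pct_within_m5, 100)
  expect_equal(m$pct_within_m20, 100)
  expect_equal(m$rmse, 0)
  m2 <- error_band_metrics(c(0.1, 2.0, -1.05), c(0, 1, -1), band)
  expect_equal(m2$pct_within_m5, 100 * 2 / 3, tolerance = 1e-10)
  zero_band <- structure(list(m5 = 0, m20 = 0, target = "J"), class = "nk_band")
  m3 <- error_band_metrics(c(1, 2.5), c(1, 2), zero_band)
  expect_equal(m3$pct_within_m5, 50)  # only exact matches
  expect_error(error_band_metrics(1:3, 1:2, band), "mismatch")
})

test_that("leave-one-out training recovers exact and degenerate targets", {
  s <- small_study_fm(seed = 11)
  prep <- preprocess(s$fm, "tg", s$study$truth)
  # exactly linear noiseless target: linear model LOO error vanishes
  lin_y <- 2 * prep$train$sr_mean - 3 * prep$train$impeller_speed + 1
  prep_lin <- prep
  prep_lin$train$y <- lin_y
  fit <- train_regressors(prep_lin,
                          list(list(name = "L", type = "linear",
                                    features = c("sr_mean", "impeller_speed"))))
  expect_lt(fit$L$loo_rmse, 1e-6)
  expect_equal(nrow(fit$L$loo), nrow(prep$train))  # one fold per row
  # constant target: every model type scores (near) zero
  prep_const <- prep
  prep_const$train$y <- rep(5, nrow(prep$train))
  zoo <- list(
    list(name = "lin", type = "linear", features = c("sr_mean")),
    list(name = "rf", type = "random_forest", features = c("sr_mean", "ep_mean")),
    list(name = "gb", type = "gradient_boosting", features = c("sr_mean", "ep_mean")),
    list(name = "knn", type = "knn", features = c("sr_mean", "ep_mean")),
    list(name = "c", type = "constant"))
  # randomForest warns about the (deliberately) degenerate constant response
  fits <- suppressWarnings(train_regressors(prep_const, zoo, seed = 2))
  for (m in fits) expect_lt(m$loo_rmse, 1e-6)
  expect_error(train_regressors(prep, list(list(name = "x", type = "svm"))),
               "unknown model type")
})

test_that("a multivariate model outperforms every univariate benchmark on the shipped study", {
  run <- cached_pipeline_run(seed = 1)
  ev <- run$evaluation$J
  uni <- ev$test_rmse[ev$type == "univariate"]
  multi <- ev$test_rmse[!ev$type %in% c("univariate", "constant")]
  expect_lt(min(multi), min(uni))
})
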