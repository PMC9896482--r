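# Oracle models: constant predictors returning known parameters, letting the
# ensemble machinery be tested against the closed-form distribution.
oracle_model <- function(target, value, prep) {
  structure(
    list(name = paste0("oracle_", target), type = "constant",
         features = character(0), fit = list(mean = value), hyper = list(),
         target = target, prep = prep,
         loo = tibble::tibble(config_id = character(0), actual = numeric(0),
                              pred = numeric(0)),
         loo_rmse = NA_real_),
    class = "nk_model")
}

make_prep <- function(seed = 5) {
  st <- generate_study(n_configs = 8, M = 15, seed = seed)
  fm <- feature_matrix(st$features, st$configs)
  list(study = st, fm = fm, prep = preprocess(fm, "J", st$truth))
}

test_that("ensemble curves are exact model CDF evaluations", {
  s <- make_prep()
  p_true <- distribution_params(0.25, 8000)
  mJ <- oracle_model("J", log10(p_true$J), s$prep)
  mt <- oracle_model("tg", p_true$tg, s$prep)
  row <- s$fm[1, ]
  grid <- seq(0, 40000, length.out = 300)
  curve <- ensemble_predict(mJ, mt, row, volume = 0.01, time_grid = grid)
  expect_equal(curve$probabilities, model_cdf(grid, p_true, 0.01),
               tolerance = 1e-12)
  expect_true(all(diff(curve$probabilities) >= 0))
  expect_true(all(curve$probabilities >= 0 & curve$probabilities <= 1))
  expect_true(all(curve$probabilities[grid <= p_true$tg] == 0))
  expect_equal(curve$params$J, p_true$J, tolerance = 1e-12)
  # negative growth-time predictions are floored at zero
  mt_neg <- oracle_model("tg", -500, s$prep)
  cv2 <- ensemble_predict(mJ, mt_neg, row, 0.01, grid)
  expect_identical(cv2$params$tg, 0)
  expect_error(ensemble_predict(mJ, mJ, row, 0.01, grid), "targets")
})

test_that("ensemble scoring pools residuals at the observed times", {
  s <- make_prep()
  p <- distribution_params(0.1, 10000)
  mJ <- oracle_model("J", log10(p$J), s$prep)
  mt <- oracle_model("tg", p$tg, s$prep)
  grid <- seq(0, 50000, length.out = 100)
  # observations at exact model quantiles: residuals vanish
  tq <- invert_cdf((1:12) / 12 - 1e-9, p, 0.01)
  dq <- induction_dataset(s$fm$config_id[1], tq, 0.01)
  cv <- ensemble_predict(mJ, mt, s$fm[1, ], 0.01, grid)
  ev <- evaluate_ensemble(list(cv), list(dq))
  expect_lt(ev$rmse, 1e-7)
  # frozen arithmetic oracle: observations {10000, 11000, 12000}
  d3 <- induction_dataset(s$fm$config_id[1], c(10000, 11000, 12000), 0.01)
  ev3 <- evaluate_ensemble(list(cv), list(d3))
  res <- c(1 / 3, 2 / 3 - (1 - exp(-1)), 1 - (1 - exp(-2)))
  expect_equal(ev3$rmse, sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(ev3$rmse, 0.2087, tolerance = 5e-4)
  # predicted growth time beyond all observations is flagged, not an error
  mt_late <- oracle_model("tg", 1e6, s$prep)
  cv_late <- ensemble_predict(mJ, mt_late, s$fm[1, ], 0.01, grid)
  ev_late <- evaluate_ensemble(list(cv_late), list(d3))
  expect_true(ev_late$per_config$all_zero[1])
  # config mismatch errors
  d_other <- induction_dataset("elsewhere", c(1000, 2000), 0.01)
  expect_error(evaluate_ensemble(list(cv), list(d_other)), "mismatch")
})

test_that("linear Shapley attributions are exact and additive", {
  s <- make_prep(seed = 13)
  prep <- preprocess(s$fm, "J", s$study$truth)
  # single-feature linear model: phi = beta * (x - mean(x))
  uni <- train_regressors(prep, list(list(name = "u", type = "univariate",
                                          features = "tip_speed")))$u
  att <- feature_attribution(uni)
  beta <- unname(coef(uni$fit)[2])
  x <- prep$train$tip_speed
  expect_equal(unname(att$phi[, "tip_speed"]), beta * (x - mean(x)),
               tolerance = 1e-8)
  # additivity: attributions sum to prediction minus baseline
  lin <- train_regressors(prep, list(list(
    name = "L", type = "linear",
    features = c("sr_mean", "impeller_speed", "volume"))))$L
  attL <- feature_attribution(lin)
  preds <- predict(lin, prep$train)
  expect_equal(unname(rowSums(attL$phi)), preds - attL$baseline,
               tolerance = 1e-8)
})

test_that("constant models attribute nothing and tree models respect additivity", {
  run <- cached_pipeline_run(seed = 1)
  # constant model: zero attribution for every feature
  attc <- feature_attribution(run$models$tg$T1)
  expect_true(all(abs(attc$phi) < 1e-10))
  # TreeSHAP on gradient boosting: rows sum to prediction - bias
  gb <- run$models$J$J9
  attg <- feature_attribution(gb)
  preds <- predict(gb, gb$prep$train)
  contrib <- rowSums(attg$phi)
  # the TreeSHAP bias equals prediction minus summed contributions; it must
  # be a single shared constant across rows
  bias <- preds - contrib
  expect_lt(max(bias) - min(bias), 1e-5)
})

test_that("permutation Shapley attribution is finite and seeded", {
  s <- make_prep(seed = 17)
  prep <- preprocess(s$fm, "J", s$study$truth)
  knn <- train_regressors(prep, list(list(name = "k", type = "knn",
                                          features = c("sr_mean", "ep_mean"))),
                          seed = 1)$k
  att1 <- feature_attribution(knn, n_perm = 16, seed = 3)
  att2 <- feature_attribution(knn, n_perm = 16, seed = 3)
  expect_true(grepl("permutation", att1$method))
  expect_identical(att1$phi, att2$phi)
  expect_true(all(is.finite(att1$phi)))
  expect_error(feature_attribution(list()), "nk_model")
})
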