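test_that("MLE evaluates to the closed-form identities", {
  d <- induction_dataset("x", c(10000, 11000, 12000), 0.01)
  f <- fit_mle(d)
  expect_identical(f$params$tg, 10000)
  expect_equal(f$params$J, 0.1, tolerance = 1e-12)  # JV = 3/3000 = 1e-3
  expect_error(fit_mle(induction_dataset("x", c(5, 5, 5), 0.01)), "degenerate")
  expect_error(fit_mle(induction_dataset("x", 5, 0.01)), "at least 2")
})

test_that("MLE identities hold exactly on random datasets", {
  set.seed(31)
  for (i in 1:200) {
    M <- sample(2:40, 1)
    p <- distribution_params(runif(1, 0.01, 5), runif(1, 0, 20000))
    V <- runif(1, 1e-5, 0.05)
    d <- generate_induction_times(p, V, M, seed = i)
    f <- fit_mle(d)
    expect_identical(f$params$tg, min(d$times))
    expect_equal(f$params$J * V * sum(d$times - f$params$tg), M,
                 tolerance = 1e-9)
  }
})

test_that("the log-likelihood is maximised at the closed-form JV", {
  # brute-force grid oracle on l(JV) = M log(JV) - JV * sum(t_i - tg_hat)
  d <- generate_induction_times(ref_params(), ref_volume, 25, seed = 4)
  f <- fit_mle(d)
  JV_hat <- f$params$J * ref_volume
  ssum <- sum(d$times - f$params$tg)
  ll <- function(jv) d$M * log(jv) - jv * ssum
  grid <- JV_hat * seq(0.2, 5, length.out = 401)
  expect_equal(grid[which.max(ll(grid))], JV_hat, tolerance = 0.01)
  expect_true(all(ll(JV_hat) >= ll(grid)))
})

test_that("MLE is upward-biased for both parameters", {
  # min(t_i) >= tg always; JV-hat inherits the bias
  p <- ref_params()
  est <- t(vapply(1:500, function(i) {
    f <- fit_mle(generate_induction_times(p, ref_volume, 10, seed = 20000 + i))
    c(f$params$J, f$params$tg)
  }, numeric(2)))
  expect_gte(mean(est[, 2]), p$tg)
  expect_gte(mean(est[, 1]), p$J)
})

test_that("direct fit recovers parameters from noise-free quantile data", {
  p <- ref_params()
  M <- 20L
  times <- invert_cdf((1:M) / (M + 1), p, ref_volume)
  d <- induction_dataset("x", times, ref_volume)
  f <- fit_direct(d, convention = "i_over_M1")
  expect_equal(f$params$J, p$J, tolerance = 0.01)
  expect_equal(f$params$tg, p$tg, tolerance = 0.01)
  expect_lt(f$fit_rmse, 1e-8)  # perfect fit
  expect_error(fit_direct(induction_dataset("x", 100, ref_volume)), "at least 2")
  expect_error(fit_direct(d, bounds_J = c(2, 1)), "lower < upper")
})

test_that("direct fit clamps to an active box constraint", {
  # data generated with tg = 1000 s, below the default 3000 s lower bound
  p <- distribution_params(0.5, 1000)
  times <- invert_cdf((1:15) / 16, p, ref_volume)
  f <- fit_direct(induction_dataset("x", times, ref_volume),
                  convention = "i_over_M1")
  expect_identical(f$params$tg, 3000)
  expect_gte(f$fit_rmse, 0)
})

test_that("fit RMSE matches direct arithmetic", {
  d <- induction_dataset("x", c(10000, 11000, 12000), 0.01)
  p <- ref_params()
  # residuals (1/3 - 0, 2/3 - (1 - e^-1), 1 - (1 - e^-2))
  res <- c(1 / 3, 2 / 3 - (1 - exp(-1)), 1 - (1 - exp(-2)))
  expect_equal(fit_quality(d, p), sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(fit_quality(d, p), 0.2087, tolerance = 5e-4)
  # growth time beyond every observation: model predicts 0 everywhere
  p2 <- distribution_params(0.1, 20000)
  expect_equal(fit_quality(d, p2), sqrt(mean((c(1, 2, 3) / 3)^2)),
               tolerance = 1e-12)
  # exact model quantiles score zero
  tq <- invert_cdf((1:10) / 11, p, ref_volume)
  dq <- induction_dataset("q", tq, ref_volume)
  expect_lt(fit_quality(dq, p, convention = "i_over_M1"), 1e-10)
})

test_that("bootstrap is seeded, reproducible and reports spread", {
  d <- generate_induction_times(ref_params(), ref_volume, 15, seed = 9)
  b1 <- bootstrap_fit(d, n_boot = 200, base = "mle", seed = 5)
  b2 <- bootstrap_fit(d, n_boot = 200, base = "mle", seed = 5)
  expect_identical(b1$params$J, b2$params$J)
  expect_identical(b1$params$tg, b2$params$tg)
  expect_identical(b1$std_J, b2$std_J)
  expect_gte(b1$std_J, 0)
  expect_gte(b1$std_tg, 0)
  expect_lte(b1$params$tg, max(d$times))  # mean of resampled minima
  expect_equal(b1$method, "mle_bootstrap")
  bd <- bootstrap_fit(d, n_boot = 25, base = "direct", seed = 5)
  expect_equal(bd$method, "bootstrap")
  expect_true(is.finite(bd$params$J))
})

test_that("two independent bootstrap runs agree within Monte-Carlo error", {
  d <- generate_induction_times(ref_params(), ref_volume, 20, seed = 3)
  n_boot <- 1000L
  b1 <- bootstrap_fit(d, n_boot = n_boot, base = "mle", seed = 1)
  b2 <- bootstrap_fit(d, n_boot = n_boot, base = "mle", seed = 99)
  expect_lt(abs(b1$params$J - b2$params$J), 3 * b1$std_J / sqrt(n_boot))
  expect_lt(abs(b1$params$tg - b2$params$tg), 3 * b1$std_tg / sqrt(n_boot))
})

test_that("bootstrap growth-time spread shrinks with more observations", {
  p <- ref_params()
  std_at <- function(M) {
    mean(vapply(1:50, function(i) {
      d <- generate_induction_times(p, ref_volume, M, seed = 40000 + i)
      bootstrap_fit(d, n_boot = 200, base = "mle", seed = i)$std_tg
    }, numeric(1)))
  }
  expect_lt(std_at(40L), std_at(10L))
})

test_that("all-tie resamples are skipped and counted", {
  # two distinct times: ~50% of resamples of size 2 are all-equal draws
  d <- induction_dataset("x", c(10000, 12000), 0.01)
  b <- bootstrap_fit(d, n_boot = 100, base = "mle", seed = 2)
  expect_gt(b$n_skipped, 0)
  expect_equal(b$n_boot + b$n_skipped, 100L)
  expect_error(
    bootstrap_fit(induction_dataset("x", c(5000, 5000), 0.01),
                  n_boot = 10, base = "mle", seed = 1),
    "degenerate|failed")
})

test_that("fit_induction dispatches on the method name", {
  d <- generate_induction_times(ref_params(), ref_volume, 12, seed = 11)
  expect_equal(fit_induction(d, "mle")$method, "mle")
  expect_equal(fit_induction(d, "direct")$method, "direct")
  expect_equal(fit_induction(d, "mle_bootstrap", n_boot = 50, seed = 1)$method,
               "mle_bootstrap")
  expect_error(fit_induction(d, "weibull"))
})
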