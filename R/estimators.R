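#' @importFrom stats optim sd setNames median coef lm predict prcomp var cor
NULL

new_estimator_result <- function(params, method, fit_rmse,
                                 std_J = NULL, std_tg = NULL,
                                 n_boot = NULL, n_skipped = NULL,
                                 diagnostics = NULL) {
  structure(
    list(params = params, method = method, fit_rmse = fit_rmse,
         std_J = std_J, std_tg = std_tg, n_boot = n_boot,
         n_skipped = n_skipped, diagnostics = diagnostics),
    class = "nk_fit")
}

#' @export
print.nk_fit <- function(x, ...) {
  cat(sprintf("Induction-time fit (%s): J = %.4g #/(m^3 s), t_g = %.6g s, RMSE = %.4g\n",
              x$method, x$params$J, x$params$tg, x$fit_rmse))
  if (!is.null(x$n_boot))
    cat(sprintf("  bootstrap: n = %d (skipped %d), std J = %.3g, std t_g = %.4g s\n",
                x$n_boot, x$n_skipped %||% 0L, x$std_J, x$std_tg))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root-mean-square misfit between model and observed cumulative probability
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{M}\sum_i (P_{\mathrm{emp}}(t_i) -
#' P_{\mathrm{model}}(t_i))^2}} over the observed induction times.
#'
#' @param dataset An [induction_dataset()].
#' @param params An [distribution_params()] object.
#' @param convention Plotting-position convention passed to [empirical_cdf()].
#' @return Non-negative scalar.
#' @export
fit_quality <- function(dataset, params, convention = c("i_over_M", "i_over_M1")) {
  convention <- match.arg(convention)
  emp <- empirical_cdf(dataset, convention)
  pred <- model_cdf(emp$time, params, dataset$volume)
  sqrt(mean((emp$prob - pred)^2))
}

# Sum-of-squares objective for the direct fit, on (J, tg), with its
# analytic gradient (finite differences stall well short of the optimum).
direct_objective <- function(par, times, pemp, volume) {
  J <- par[1L]; tg <- par[2L]
  pmod <- ifelse(times <= tg, 0, -expm1(-J * volume * (times - tg)))
  sum((pemp - pmod)^2)
}

direct_gradient <- function(par, times, pemp, volume) {
  J <- par[1L]; tg <- par[2L]
  act <- times > tg
  e <- exp(-J * volume * (times - tg))
  pmod <- ifelse(act, 1 - e, 0)
  r <- pmod - pemp
  c(sum(2 * r[act] * volume * (times[act] - tg) * e[act]),
    sum(-2 * r[act] * J * volume * e[act]))
}

#' Direct nonlinear least-squares fit of the induction-time distribution
#'
#' Fits the Poisson model CDF to the observed cumulative probabilities by
#' bounded nonlinear least squares, minimising the sum of squared
#' differences between [empirical_cdf()] and [model_cdf()] at the observed
#' times. The objective is flat in \eqn{t_g} above \eqn{\min t_i}, so the
#' optimiser is multi-started at `tg` = min(t), 0.5 min(t) and the lower
#' bound.
#'
#' @param dataset An [induction_dataset()] with at least 2 observations.
#' @param bounds_J Box constraint for `J`, #/(m^3 s). Default `c(0.01, 20)`.
#' @param bounds_tg Box constraint for `tg`, s. Default `c(3000, 30000)`.
#' @param convention Plotting-position convention for the empirical CDF.
#' @return An `nk_fit` with `method = "direct"`.
#' @export
fit_direct <- function(dataset, bounds_J = c(0.01, 20),
                       bounds_tg = c(3000, 30000),
                       convention = c("i_over_M", "i_over_M1")) {
  stopifnot(inherits(dataset, "nk_dataset"))
  convention <- match.arg(convention)
  if (dataset$M < 2L)
    stop("direct fit needs at least 2 induction times", call. = FALSE)
  check_bounds <- function(b, nm) {
    if (length(b) != 2L || anyNA(b) || any(!is.finite(b)) || b[1] >= b[2])
      stop(sprintf("`%s` must be finite with lower < upper", nm), call. = FALSE)
  }
  check_bounds(bounds_J, "bounds_J"); check_bounds(bounds_tg, "bounds_tg")

  emp <- empirical_cdf(dataset, convention)
  times <- emp$time; pemp <- emp$prob; V <- dataset$volume
  clamp <- function(x, b) min(max(x, b[1]), b[2])

  tmin <- min(times)
  # MLE-like moment start for J, clamped into the box
  j0 <- clamp(dataset$M / (V * max(sum(times - tmin), .Machine$double.eps)), bounds_J)
  starts <- list(
    c(j0, clamp(tmin, bounds_tg)),
    c(j0, clamp(0.5 * tmin, bounds_tg)),
    c(clamp(sqrt(bounds_J[1] * bounds_J[2]), bounds_J), bounds_tg[1]))

  best <- NULL
  diags <- list()
  for (s in starts) {
    res <- tryCatch(
      optim(s, direct_objective, direct_gradient,
            times = times, pemp = pemp, volume = V,
            method = "L-BFGS-B",
            lower = c(bounds_J[1], bounds_tg[1]),
            upper = c(bounds_J[2], bounds_tg[2]),
            control = list(factr = 10, maxit = 1000)),
      error = function(e) NULL)
    if (is.null(res)) next
    diags[[length(diags) + 1L]] <- res[c("convergence", "message", "value")]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("direct fit failed from every start", call. = FALSE)
  # code 52 = line search cannot improve at numerical precision: converged
  # for practical purposes, the best candidate is at the objective floor
  if (!best$convergence %in% c(0L, 51L, 52L)) {
    cnd <- simpleError(sprintf(
      "direct fit did not converge (code %d: %s); best candidate J = %.4g, tg = %.5g, SSE = %.4g",
      best$convergence, best$message %||% "", best$par[1], best$par[2], best$value))
    cnd$candidate <- best
    stop(cnd)
  }
  params <- distribution_params(best$par[1], best$par[2])
  new_estimator_result(params, "direct",
                       fit_rmse = sqrt(best$value / dataset$M),
                       diagnostics = diags)
}

#' Maximum likelihood estimate of the induction-time distribution
#'
#' Under the shifted-exponential induction-time model the likelihood is
#' increasing in \eqn{t_g} up to \eqn{\min t_i} and zero beyond, so
#' \eqn{\hat t_g = \min_i t_i} exactly; maximising the log-likelihood
#' \eqn{M \ln(JV) - JV \sum_i (t_i - \hat t_g)} in \eqn{JV} then gives
#' \eqn{\widehat{JV} = M / \sum_i (t_i - \hat t_g)}.
#'
#' @param dataset An [induction_dataset()] with at least 2 observations,
#'   not all identical.
#' @param convention Convention used only for the reported `fit_rmse`.
#' @return An `nk_fit` with `method = "mle"`.
#' @export
fit_mle <- function(dataset, convention = c("i_over_M", "i_over_M1")) {
  stopifnot(inherits(dataset, "nk_dataset"))
  convention <- match.arg(convention)
  if (dataset$M < 2L)
    stop("MLE needs at least 2 induction times", call. = FALSE)
  tg_hat <- min(dataset$times)
  ssum <- sum(dataset$times - tg_hat)
  if (ssum <= 0)
    stop("degenerate data: all induction times identical", call. = FALSE)
  J_hat <- (dataset$M / ssum) / dataset$volume
  params <- distribution_params(J_hat, tg_hat)
  new_estimator_result(params, "mle",
                       fit_rmse = fit_quality(dataset, params, convention))
}

# MLE on a bare numeric vector; returns c(J, tg) or NULL if degenerate.
mle_raw <- function(times, volume) {
  tg <- min(times)
  ssum <- sum(times - tg)
  if (ssum <= 0) return(NULL)
  c((length(times) / ssum) / volume, tg)
}

#' Bootstrap estimate of induction-time distribution parameters
#'
#' Resamples the observed induction times with replacement `n_boot` times,
#' refits the base estimator (direct least squares or MLE) to each
#' resample, and reports the mean and standard deviation of the resampled
#' parameter estimates. Resamples on which the base estimator is degenerate
#' (all drawn times identical) or fails are skipped and counted.
#'
#' @param dataset An [induction_dataset()].
#' @param n_boot Number of resamples (default 1000).
#' @param base Base estimator, `"direct"` or `"mle"`.
#' @param seed Integer seed; the resampling uses R's Mersenne-Twister
#'   generator via `sample.int()`, so identical seeds give identical fits.
#' @param ... Passed to the base estimator (`bounds_J`, `bounds_tg`,
#'   `convention`).
#' @return An `nk_fit` with `method` `"bootstrap"` (direct base) or
#'   `"mle_bootstrap"`; `std_J` / `std_tg` carry the bootstrap standard
#'   deviations and `n_skipped` the number of dropped resamples.
#' @export
bootstrap_fit <- function(dataset, n_boot = 1000L, base = c("direct", "mle"),
                          seed = 1L, ...) {
  stopifnot(inherits(dataset, "nk_dataset"))
  base <- match.arg(base)
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  times <- dataset$times; M <- dataset$M; V <- dataset$volume
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  ests <- matrix(NA_real_, nrow = n_boot, ncol = 2L)
  for (b in seq_len(n_boot)) {
    draw <- times[sample.int(M, M, replace = TRUE)]
    if (length(unique(draw)) < 2L) next  # degenerate resample
    if (base == "mle") {
      e <- mle_raw(draw, V)
      if (!is.null(e)) ests[b, ] <- e
    } else {
      fit <- tryCatch(
        fit_direct(induction_dataset(dataset$config_id, draw, V), ...),
        error = function(e) NULL)
      if (!is.null(fit)) ests[b, ] <- c(fit$params$J, fit$params$tg)
    }
  }
  ok <- stats::complete.cases(ests)
  if (!any(ok))
    stop("all bootstrap resamples were degenerate or failed", call. = FALSE)
  ests <- ests[ok, , drop = FALSE]
  params <- distribution_params(mean(ests[, 1]), mean(ests[, 2]))
  conv <- list(...)$convention %||% "i_over_M"
  new_estimator_result(
    params,
    method = if (base == "mle") "mle_bootstrap" else "bootstrap",
    fit_rmse = fit_quality(dataset, params, conv),
    std_J = if (nrow(ests) > 1) sd(ests[, 1]) else 0,
    std_tg = if (nrow(ests) > 1) sd(ests[, 2]) else 0,
    n_boot = nrow(ests), n_skipped = n_boot - nrow(ests))
}

#' Fit an induction dataset by any supported method
#'
#' Dispatch wrapper over [fit_direct()], [fit_mle()] and [bootstrap_fit()].
#'
#' @param dataset An [induction_dataset()].
#' @param method One of `"direct"`, `"mle"`, `"bootstrap"`,
#'   `"mle_bootstrap"`.
#' @param ... Passed to the underlying estimator.
#' @return An `nk_fit`.
#' @export
fit_induction <- function(dataset,
                          method = c("mle", "direct", "bootstrap", "mle_bootstrap"),
                          ...) {
  method <- match.arg(method)
  switch(method,
         direct = fit_direct(dataset, ...),
         mle = fit_mle(dataset, ...),
         bootstrap = bootstrap_fit(dataset, base = "direct", ...),
         mle_bootstrap = bootstrap_fit(dataset, base = "mle", ...))
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
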