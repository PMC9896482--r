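#' Predict an induction-time distribution from hydrodynamic features
#'
#' Ensembles a nucleation-rate model and a growth-time model: the J model's
#' prediction is back-transformed from log10 space, the growth-time
#' prediction is floored at 0, and the pair is pushed through the Poisson
#' model CDF over a time grid. The returned curve is by construction a
#' valid induction-time distribution (nondecreasing, in `[0, 1]`, zero at
#' and below the implied growth time).
#'
#' @param model_J An `nk_model` trained for target `"J"` (predicts
#'   log10 J).
#' @param model_tg An `nk_model` trained for target `"tg"` (predicts
#'   seconds).
#' @param features_row One raw [feature_matrix()] row for the
#'   configuration to predict.
#' @param volume Solution volume, m^3.
#' @param time_grid Times (s) at which to evaluate the predicted
#'   cumulative probability.
#' @return An object of class `nk_curve`: list with `config_id`,
#'   `time_grid`, `probabilities`, `params` (the implied
#'   [distribution_params()]).
#' @export
ensemble_predict <- function(model_J, model_tg, features_row, volume,
                             time_grid) {
  stopifnot(inherits(model_J, "nk_model"), inherits(model_tg, "nk_model"))
  if (model_J$target != "J" || model_tg$target != "tg")
    stop("models must be trained for targets J and tg respectively", call. = FALSE)
  if (nrow(features_row) != 1L)
    stop("`features_row` must be a single configuration row", call. = FALSE)
  J_hat <- 10^predict(model_J, features_row)
  tg_hat <- max(predict(model_tg, features_row), 0)
  params <- distribution_params(J_hat, tg_hat)
  structure(
    list(config_id = features_row$config_id[1],
         time_grid = time_grid,
         probabilities = model_cdf(time_grid, params, volume),
         params = params),
    class = "nk_curve")
}

#' @export
print.nk_curve <- function(x, ...) {
  cat(sprintf("Predicted induction-time distribution for '%s': J = %.4g #/(m^3 s), t_g = %.5g s\n",
              x$config_id, x$params$J, x$params$tg))
  invisible(x)
}

#' Score predicted induction-time distributions against observations
#'
#' For each configuration the residuals are taken at the observed
#' induction times: observed cumulative probability ([empirical_cdf()])
#' minus the predicted curve's probability there (evaluated exactly from
#' the curve's implied parameters, so a perfect model scores zero
#' regardless of the curve's grid). Residuals are pooled across all
#' configurations before the square root for the aggregate RMSE, and the
#' aggregate R-squared is [r2_with_nan()] on the pooled pairs; per-config
#' RMSEs (and their mean) are also reported.
#'
#' @param curves List of `nk_curve`s, one per observed dataset.
#' @param observed List of [induction_dataset()]s, matched to `curves` by
#'   `config_id`.
#' @param convention Plotting-position convention for the empirical CDF.
#' @return A list of class `nk_ensemble_eval`: `rmse` (pooled), `r2`
#'   (pooled), `per_config` (tibble with per-config rmse and an
#'   `all_zero` flag raised when the predicted growth time exceeds every
#'   observed time so the curve predicts P = 0 throughout), `rmse_mean`
#'   (mean of per-config RMSEs), `pooled` (the residual table).
#' @export
evaluate_ensemble <- function(curves, observed,
                              convention = c("i_over_M", "i_over_M1")) {
  convention <- match.arg(convention)
  if (length(curves) != length(observed))
    stop("need one curve per observed dataset", call. = FALSE)
  curve_ids <- vapply(curves, function(cv) cv$config_id, character(1))
  obs_ids <- vapply(observed, function(d) d$config_id, character(1))
  if (!setequal(curve_ids, obs_ids))
    stop("configuration mismatch between curves and observations: ",
         paste(union(setdiff(curve_ids, obs_ids), setdiff(obs_ids, curve_ids)),
               collapse = ", "), call. = FALSE)
  pooled <- list()
  per <- list()
  for (cv in curves) {
    d <- observed[[match(cv$config_id, obs_ids)]]
    emp <- empirical_cdf(d, convention)
    pred <- model_cdf(emp$time, cv$params, d$volume)
    pooled[[cv$config_id]] <- tibble::tibble(
      config_id = cv$config_id, time = emp$time,
      observed = emp$prob, predicted = pred)
    per[[cv$config_id]] <- tibble::tibble(
      config_id = cv$config_id,
      rmse = sqrt(mean((emp$prob - pred)^2)),
      all_zero = all(pred == 0))
  }
  pooled <- dplyr::bind_rows(pooled)
  per <- dplyr::bind_rows(per)
  structure(
    list(rmse = sqrt(mean((pooled$observed - pooled$predicted)^2)),
         r2 = r2_with_nan(pooled$predicted, pooled$observed),
         rmse_mean = mean(per$rmse),
         per_config = per, pooled = pooled),
    class = "nk_ensemble_eval")
}

#' @export
print.nk_ensemble_eval <- function(x, ...) {
  cat(sprintf("Ensemble evaluation: pooled RMSE = %.3g, R^2 = %.3g (mean per-config RMSE %.3g)\n",
              x$rmse, x$r2, x$rmse_mean))
  if (any(x$per_config$all_zero))
    cat("  note: predicted growth time exceeds all observed times for: ",
        paste(x$per_config$config_id[x$per_config$all_zero], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# ---- Shapley attribution ----------------------------------------------------

linear_coefs <- function(model) {
  switch(model$type,
    linear = ,
    univariate = {
      cf <- coef(model$fit)
      cf <- cf[names(cf) != "(Intercept)"]
      # lm backtick-quotes non-syntactic names
      names(cf) <- gsub("`", "", names(cf))
      cf[is.na(cf)] <- 0
      cf
    },
    ridge = ,
    lasso = {
      cf <- as.matrix(coef(model$fit))[, 1]
      cf <- cf[names(cf) != "(Intercept)"]
      cf
    },
    NULL)
}

# Monte Carlo permutation Shapley (Strumbelj & Kononenko) for black-box
# regressors: per explained row, sample feature-orderings and background
# rows, and accumulate marginal contributions.
permutation_shapley <- function(pred_fun, X, background, n_perm, seed) {
  p <- ncol(X)
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  set.seed(as.integer(seed))
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    plus <- matrix(0, n_perm * p, p)
    minus <- matrix(0, n_perm * p, p)
    slot <- 1L
    order_of <- integer(n_perm * p)
    for (s in seq_len(n_perm)) {
      w <- background[sample.int(nrow(background), 1L), ]
      o <- sample.int(p)
      z <- w
      for (j in o) {
        minus[slot, ] <- z
        z[j] <- x[j]
        plus[slot, ] <- z
        order_of[slot] <- j
        slot <- slot + 1L
      }
    }
    colnames(plus) <- colnames(minus) <- colnames(X)
    contrib <- pred_fun(plus) - pred_fun(minus)
    for (j in seq_len(p))
      phi[r, j] <- mean(contrib[order_of == j])
  }
  phi
}

#' Shapley-value feature attributions for a trained model
#'
#' Computes per-row, per-feature attributions of the model's predictions:
#' exact closed-form Shapley values for linear models
#' (\eqn{\phi_{ij} = \beta_j (x_{ij} - \bar x_j)} over the training
#' background), exact TreeSHAP for gradient-boosting models (via the
#' booster's prediction contributions), and a seeded Monte-Carlo
#' permutation Shapley estimate for other model classes. Constant models
#' attribute zero everywhere. The report summarises, per feature, the mean
#' absolute attribution (global importance) and the signed high-value
#' direction: the mean attribution among rows with the feature above its
#' median minus the mean among rows below, positive when high feature
#' values push the prediction up.
#'
#' @param model A trained `nk_model`.
#' @param table Model-ready rows to explain (defaults to the model's
#'   training split). The training split is always the background set.
#' @param n_perm Permutation samples per row for the Monte-Carlo path.
#' @param seed Integer seed for the Monte-Carlo path.
#' @return An object of class `nk_attribution`: list with `summary` (a
#'   tibble `feature`, `mean_abs`, `direction`, `high_value_effect`),
#'   `phi` (the attribution matrix), `baseline` (mean training
#'   prediction) and `method`.
#' @export
feature_attribution <- function(model, table = NULL, n_perm = 64L, seed = 1L) {
  if (!inherits(model, "nk_model"))
    stop("`model` must be a trained nk_model", call. = FALSE)
  if (is.null(table)) table <- model$prep$train
  feats <- model$features
  if (model$type == "constant") {
    feats <- c("impeller_RC", "impeller_PBT")
  }
  X <- as.matrix(table[, feats, drop = FALSE])
  bg <- as.matrix(model$prep$train[, feats, drop = FALSE])
  by_group <- model$type == "constant" &&
    identical(model$fit$grouping, "by_impeller_type")
  pred_fun <- function(M) {
    if (by_group) {
      grp <- ifelse(M[, "impeller_RC"] == 1, "RC", "PBT")
      return(as.numeric(model$fit$means[grp]))
    }
    predict_one(model$type, model$fit, pad_single_column(M))
  }

  if (model$type == "constant" &&
      !identical(model$fit$grouping, "by_impeller_type")) {
    phi <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, colnames(X)))
    method <- "exact (constant model)"
  } else if (!is.null(cf <- linear_coefs(model))) {
    cf <- cf[colnames(X)]
    cf[is.na(cf)] <- 0
    phi <- sweep(X, 2, colMeans(bg)) %*% diag(cf, ncol(X))
    colnames(phi) <- colnames(X)
    method <- "exact (linear Shapley)"
  } else if (model$type == "gradient_boosting") {
    contrib <- predict(model$fit, pad_single_column(X), type = "contrib")
    phi <- contrib[, colnames(X), drop = FALSE]
    method <- "exact (TreeSHAP)"
  } else {
    phi <- permutation_shapley(pred_fun, X, bg, n_perm, seed)
    method <- sprintf("Monte-Carlo permutation Shapley (%d samples/row)", n_perm)
  }

  summary <- dplyr::bind_rows(lapply(colnames(phi), function(j) {
    xj <- X[, j]
    hi <- xj > median(xj)
    dir <- if (any(hi) && any(!hi)) mean(phi[hi, j]) - mean(phi[!hi, j]) else 0
    tibble::tibble(
      feature = j,
      mean_abs = mean(abs(phi[, j])),
      high_value_effect = dir,
      direction = if (dir > 0) "positive" else if (dir < 0) "negative" else "none")
  }))
  summary <- summary[order(-summary$mean_abs), ]
  baseline <- if (model$type == "constant") {
    if (identical(model$fit$grouping, "by_impeller_type")) {
      mean(as.numeric(model$fit$means[
        ifelse(bg[, "impeller_RC"] == 1, "RC", "PBT")]))
    } else model$fit$mean
  } else mean(predict_one(model$type, model$fit, pad_single_column(bg)))
  structure(list(summary = summary, phi = phi, baseline = baseline,
                 method = method, model = model$name),
            class = "nk_attribution")
}

#' @export
print.nk_attribution <- function(x, ...) {
  cat(sprintf("Feature attribution for model '%s' [%s]\n", x$model, x$method))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
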