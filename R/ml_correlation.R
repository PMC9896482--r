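#' Assemble the regression feature matrix
#'
#' Joins a hydrodynamic feature table (19 CFD columns plus the derived
#' `reynolds`, `tip_speed`, `specific_power` scalars) with the vessel
#' operating conditions, yielding one row per configuration with the 24
#' numeric features (volume, impeller speed, 19 CFD fields, 3 derived
#' scalars), the categorical `impeller_type`, and the train/test `split`
#' label carried as data.
#'
#' @param features Feature table from [augment_features()] or
#'   [load_cfd_features()] + [augment_features()].
#' @param configs Vessel-configuration table with `config_id`,
#'   `volume_ml`, `impeller_speed_rpm`, `impeller_type`, `split`.
#' @return A tibble: `config_id`, `split`, `impeller_type`, then numeric
#'   feature columns in canonical order.
#' @export
feature_matrix <- function(features, configs) {
  idx <- match(features$config_id, configs$config_id)
  if (anyNA(idx))
    stop("configs table lacks rows for config(s): ",
         paste(features$config_id[is.na(idx)], collapse = ", "), call. = FALSE)
  cfg <- configs[idx, ]
  out <- tibble::tibble(
    config_id = features$config_id,
    split = cfg$split,
    impeller_type = cfg$impeller_type,
    volume = cfg$volume_ml,
    impeller_speed = cfg$impeller_speed_rpm)
  out <- dplyr::bind_cols(
    out, features[, c(cfd_feature_names(), "reynolds", "tip_speed", "specific_power")])
  if (anyNA(out)) stop("feature matrix contains missing values", call. = FALSE)
  if (!all(out$impeller_type %in% c("RC", "PBT")))
    stop("impeller_type must be 'RC' or 'PBT'", call. = FALSE)
  out
}

# Canonical numeric feature order; reduction tie-breaks depend on it.
canonical_feature_order <- function() {
  c("volume", "impeller_speed", cfd_feature_names(),
    "reynolds", "tip_speed", "specific_power")
}

numeric_feature_cols <- function(df) {
  intersect(canonical_feature_order(), names(df))
}

#' Drop highly collinear features by Pearson correlation
#'
#' Iterates the numeric feature columns in canonical table order, keeping a
#' column only if its absolute Pearson correlation with every
#' already-kept column is at most `r_max`. When a pair exceeds the
#' threshold the later column in canonical order is dropped, making the
#' result deterministic. The categorical impeller type is never part of
#' the scan and always survives.
#'
#' @param features A [feature_matrix()] (or any tibble with a subset of the
#'   canonical numeric columns).
#' @param r_max Maximum tolerated absolute pairwise correlation (default
#'   0.95).
#' @return A list with `kept` and `dropped` column-name vectors and
#'   `features`, the input with dropped numeric columns removed.
#' @export
reduce_features <- function(features, r_max = 0.95) {
  cols <- numeric_feature_cols(features)
  if (length(cols) < 2L)
    stop("need at least 2 numeric feature columns", call. = FALSE)
  X <- as.matrix(features[, cols])
  kept <- character(0)
  dropped <- character(0)
  for (col in cols) {
    if (length(kept) == 0L) { kept <- col; next }
    r <- suppressWarnings(abs(cor(X[, col], X[, kept, drop = FALSE])))
    r[is.na(r)] <- 0  # constant columns cannot be collinear by this measure
    if (any(r > r_max)) dropped <- c(dropped, col) else kept <- c(kept, col)
  }
  list(kept = kept, dropped = dropped,
       features = features[, setdiff(names(features), dropped)])
}

#' Explained-variance spectrum of the standardized features
#'
#' Principal component analysis of the standardized numeric feature
#' columns; returns the fraction of total variance carried by each
#' component, a diagnostic for how many independent directions the feature
#' table actually spans.
#'
#' @param features A [feature_matrix()].
#' @return Numeric vector of nonnegative, nonincreasing fractions summing
#'   to 1.
#' @export
pca_variance <- function(features) {
  cols <- numeric_feature_cols(features)
  X <- as.matrix(features[, cols])
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ", paste(cols[sds == 0], collapse = ", "),
         call. = FALSE)
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  ev / sum(ev)
}

#' Preprocess features and targets for regression
#'
#' The nucleation rate spans orders of magnitude, so `J` is modelled as
#' log10(J); growth time is modelled on its natural scale. Numeric
#' features are standardized (mean 0, variance 1) using statistics from
#' the training split only, and the categorical impeller type is expanded
#' to binary indicator columns `impeller_RC` / `impeller_PBT`.
#'
#' @param features A [feature_matrix()] (must carry `split`).
#' @param target `"J"` or `"tg"`.
#' @param targets A data frame with `config_id` and columns `J` and/or
#'   `tg` holding the fitted kinetics per configuration.
#' @return An object of class `nk_prep`: list with `train` and `test`
#'   model-ready tibbles (`config_id`, `y`, predictors), `centers`,
#'   `scales`, `feature_cols`, `target`.
#' @export
preprocess <- function(features, target = c("J", "tg"), targets) {
  target <- match.arg(target)
  if (!"split" %in% names(features))
    stop("feature matrix must carry a `split` column", call. = FALSE)
  idx <- match(features$config_id, targets$config_id)
  if (anyNA(idx))
    stop("targets missing for config(s): ",
         paste(features$config_id[is.na(idx)], collapse = ", "), call. = FALSE)
  yraw <- targets[[target]][idx]
  if (target == "J") {
    if (any(yraw <= 0)) stop("J values must be > 0 to take log10", call. = FALSE)
    y <- log10(yraw)
  } else y <- yraw

  cols <- numeric_feature_cols(features)
  is_train <- features$split == "training_validation"
  if (sum(is_train) < 3L)
    stop("training split needs at least 3 rows", call. = FALSE)
  Xtr <- as.matrix(features[is_train, cols])
  centers <- colMeans(Xtr)
  scales <- apply(Xtr, 2, sd)
  if (any(scales == 0))
    stop("zero-variance training column(s): ",
         paste(cols[scales == 0], collapse = ", "), call. = FALSE)

  scale_rows <- function(rows) {
    X <- sweep(sweep(as.matrix(features[rows, cols]), 2, centers), 2, scales, "/")
    tb <- tibble::as_tibble(as.data.frame(X))
    tb$impeller_RC <- as.numeric(features$impeller_type[rows] == "RC")
    tb$impeller_PBT <- as.numeric(features$impeller_type[rows] == "PBT")
    dplyr::bind_cols(tibble::tibble(config_id = features$config_id[rows],
                                    y = y[rows]), tb)
  }
  structure(
    list(train = scale_rows(which(is_train)),
         test = scale_rows(which(!is_train)),
         centers = centers, scales = scales,
         feature_cols = c(cols, "impeller_RC", "impeller_PBT"),
         target = target),
    class = "nk_prep")
}

# Standardize a raw feature-matrix row set with a prep's training stats.
apply_prep <- function(prep, features) {
  cols <- names(prep$centers)
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0)
    stop("feature columns missing: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- sweep(sweep(as.matrix(features[, cols]), 2, prep$centers), 2,
             prep$scales, "/")
  tb <- tibble::as_tibble(as.data.frame(X))
  tb$impeller_RC <- as.numeric(features$impeller_type == "RC")
  tb$impeller_PBT <- as.numeric(features$impeller_type == "PBT")
  tb
}

#' Coefficient of determination with the NaN convention for poor fits
#'
#' Standard \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. Fits worse than predicting
#' the mean of the observations (raw \eqn{R^2 < 0}), and cases where the
#' observations have zero variance, are reported as `NaN`: such data are
#' better represented by their mean than by the model.
#'
#' @param predictions,actuals Numeric vectors of equal length (n >= 2).
#' @return A scalar in (0, 1] , 0, or `NaN`.
#' @export
r2_with_nan <- function(predictions, actuals) {
  if (length(predictions) != length(actuals))
    stop("length mismatch between predictions and actuals", call. = FALSE)
  if (length(actuals) < 2L) stop("need at least 2 points", call. = FALSE)
  ss_tot <- sum((actuals - mean(actuals))^2)
  if (ss_tot == 0) return(NaN)
  r2 <- 1 - sum((actuals - predictions)^2) / ss_tot
  if (r2 < 0) NaN else r2
}

# ---- model zoo --------------------------------------------------------------

default_grids <- function() {
  list(
    linear = list(list()),
    univariate = list(list()),
    ridge = lapply(10^seq(-3, 2, length.out = 6), function(l) list(lambda = l)),
    lasso = lapply(10^seq(-3, 2, length.out = 6), function(l) list(lambda = l)),
    random_forest = {
      g <- expand.grid(ntree = c(50, 200), nodesize = c(1, 3))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    gradient_boosting = {
      g <- expand.grid(max_depth = c(2, 3), nrounds = c(50, 200))
      lapply(seq_len(nrow(g)), function(i) c(as.list(g[i, ]), list(eta = 0.1)))
    },
    knn = lapply(c(2, 3, 5), function(k) list(k = k)),
    constant = list(list()))
}

fit_one <- function(type, X, y, hyper, seed) {
  switch(type,
    linear = ,
    univariate = {
      df <- as.data.frame(X); df$.y <- y
      lm(.y ~ ., data = df)
    },
    ridge = glmnet::glmnet(X, y, alpha = 0, lambda = hyper$lambda,
                           standardize = FALSE),
    lasso = glmnet::glmnet(X, y, alpha = 1, lambda = hyper$lambda,
                           standardize = FALSE),
    random_forest = {
      set.seed(seed)
      randomForest::randomForest(x = X, y = y, ntree = hyper$ntree,
                                 nodesize = hyper$nodesize)
    },
    gradient_boosting = {
      set.seed(seed)
      xgboost::xgboost(X, y, nrounds = hyper$nrounds,
                       max_depth = hyper$max_depth,
                       learning_rate = hyper$eta,
                       nthreads = 1, verbosity = 0,
                       objective = "reg:squarederror")
    },
    knn = caret::knnreg(as.data.frame(X), y, k = hyper$k),
    constant = list(mean = mean(y)),
    stop("unknown model type: ", type, call. = FALSE))
}

predict_one <- function(type, obj, X) {
  switch(type,
    linear = ,
    univariate = unname(predict(obj, newdata = as.data.frame(X))),
    ridge = ,
    lasso = as.numeric(predict(obj, newx = X)),
    random_forest = unname(predict(obj, newdata = X)),
    gradient_boosting = predict(obj, newdata = X),
    knn = unname(predict(obj, newdata = as.data.frame(X))),
    constant = rep(obj$mean, nrow(X)))
}

# Special handling: glmnet refuses single-column matrices.
pad_single_column <- function(X) {
  if (ncol(X) == 1L) cbind(X, `.pad` = 0) else X
}

loo_rmse_for <- function(type, X, y, hyper, seed) {
  n <- length(y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    obj <- fit_one(type, pad_single_column(X[-i, , drop = FALSE]), y[-i],
                   hyper, seed + i)
    preds[i] <- predict_one(type, obj, pad_single_column(X[i, , drop = FALSE]))
  }
  list(rmse = sqrt(mean((preds - y)^2)), preds = preds)
}

#' Train the regression model zoo with leave-one-out validation
#'
#' For each model specification, runs a grid search over the default
#' hyperparameter grids, scoring each candidate by leave-one-out RMSE on
#' the training split, keeps the best candidate's leave-one-out
#' predictions, and refits it on the full training split.
#'
#' @param prep An [preprocess()] object.
#' @param zoo A list of model specifications, each a list with `name`
#'   (label), `type` (one of linear, univariate, ridge, lasso,
#'   random_forest, gradient_boosting, knn, constant), `features` (a
#'   character vector of predictor columns, or `"reduced"` / `"all"`), and
#'   for `constant` models optionally `grouping` (`"all"` or
#'   `"by_impeller_type"`).
#' @param reduced_cols Columns to substitute for `features = "reduced"`.
#' @param grids Optional replacement for [the default grids][train_regressors].
#' @param seed Integer seed for stochastic learners.
#' @return A named list of `nk_model` objects.
#' @export
train_regressors <- function(prep, zoo, reduced_cols = NULL,
                             grids = default_grids(), seed = 1L) {
  stopifnot(inherits(prep, "nk_prep"))
  seed <- as.integer(seed)
  y <- prep$train$y
  out <- list()
  for (spec in zoo) {
    type <- spec$type
    if (!type %in% names(grids))
      stop("unknown model type: ", type, call. = FALSE)
    feats <- spec$features %||% "all"
    if (identical(feats, "all")) {
      feats <- prep$feature_cols
    } else if (identical(feats, "reduced")) {
      if (is.null(reduced_cols))
        stop("`reduced_cols` required for features = 'reduced'", call. = FALSE)
      feats <- c(reduced_cols, "impeller_RC", "impeller_PBT")
    }
    if (type == "constant" && identical(spec$grouping %||% "all",
                                        "by_impeller_type")) {
      out[[spec$name]] <- train_constant_by_group(prep, spec, seed)
      next
    }
    miss <- setdiff(feats, names(prep$train))
    if (length(miss) > 0)
      stop("unknown feature column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- as.matrix(prep$train[, feats, drop = FALSE])
    best <- NULL
    for (hyper in grids[[type]]) {
      cand <- loo_rmse_for(type, X, y, hyper, seed)
      if (is.null(best) || cand$rmse < best$rmse)
        best <- c(cand, list(hyper = hyper))
    }
    fit <- fit_one(type, pad_single_column(X), y, best$hyper, seed)
    # release stale booster handles promptly; avoids GC inside xgb.train
    if (type == "gradient_boosting") gc(FALSE)
    out[[spec$name]] <- structure(
      list(name = spec$name, type = type, features = feats, fit = fit,
           hyper = best$hyper, target = prep$target, prep = prep,
           loo = tibble::tibble(config_id = prep$train$config_id,
                                actual = y, pred = best$preds),
           loo_rmse = best$rmse),
      class = "nk_model")
  }
  out
}

# Constant-by-impeller-type model fitted inside the zoo: grid-free, LOO by
# leaving each row out of its group mean.
train_constant_by_group <- function(prep, spec, seed) {
  y <- prep$train$y
  grp <- ifelse(prep$train$impeller_RC == 1, "RC", "PBT")
  n <- length(y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(grp == grp[i])
    rest <- setdiff(same, i)
    if (length(rest) == 0L)
      stop("constant-by-group model: group '", grp[i],
           "' has a single training row", call. = FALSE)
    preds[i] <- mean(y[rest])
  }
  means <- tapply(y, grp, mean)
  structure(
    list(name = spec$name, type = "constant", features = character(0),
         fit = list(means = means, grouping = "by_impeller_type"),
         hyper = list(), target = prep$target, prep = prep,
         loo = tibble::tibble(config_id = prep$train$config_id,
                              actual = y, pred = preds),
         loo_rmse = sqrt(mean((preds - y)^2))),
    class = "nk_model")
}

#' Predict from a trained zoo model
#'
#' @param object An `nk_model`.
#' @param newdata Either a model-ready tibble (as in `prep$test`) or a raw
#'   [feature_matrix()] row set (detected by the absence of standardized
#'   columns and scaled with the model's training statistics).
#' @param ... Unused.
#' @return Predictions on the model scale (log10 J for J models, seconds
#'   for growth-time models).
#' @export
predict.nk_model <- function(object, newdata, ...) {
  if (!all(c("impeller_RC", "impeller_PBT") %in% names(newdata)))
    newdata <- apply_prep(object$prep, newdata)
  if (object$type == "constant") {
    if (identical(object$fit$grouping, "by_impeller_type")) {
      grp <- ifelse(newdata$impeller_RC == 1, "RC", "PBT")
      miss <- setdiff(unique(grp), names(object$fit$means))
      if (length(miss) > 0)
        stop("no training mean for group(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      return(as.numeric(object$fit$means[grp]))
    }
    return(rep(object$fit$mean, nrow(newdata)))
  }
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0)
    stop("feature column(s) missing from newdata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- pad_single_column(as.matrix(newdata[, object$features, drop = FALSE]))
  predict_one(object$type, object$fit, X)
}

#' @export
print.nk_model <- function(x, ...) {
  cat(sprintf("nk_model '%s' (%s) for %s: %d feature(s), LOO RMSE %.4g\n",
              x$name, x$type, if (x$target == "J") "log10(J)" else "t_g",
              length(x$features), x$loo_rmse))
  invisible(x)
}

#' Constant-value benchmark predictions
#'
#' The simplest benchmark for growth time: predict the training mean,
#' either one global mean (`grouping = "all"`) or the per-impeller-type
#' means (`grouping = "by_impeller_type"`).
#'
#' @param values Training target values.
#' @param groups Grouping labels per value (required for
#'   `by_impeller_type`).
#' @param grouping `"all"` or `"by_impeller_type"`.
#' @param new_groups Labels at which predictions are wanted (default: the
#'   training labels).
#' @return Numeric predictions aligned with `new_groups` (or a single
#'   value for `grouping = "all"` when `new_groups` is missing).
#' @export
constant_value_predictions <- function(values, groups = NULL,
                                       grouping = c("all", "by_impeller_type"),
                                       new_groups = groups) {
  grouping <- match.arg(grouping)
  if (length(values) == 0L) stop("empty training group", call. = FALSE)
  if (grouping == "all") {
    m <- mean(values)
    if (is.null(new_groups)) return(m)
    return(rep(m, length(new_groups)))
  }
  if (is.null(groups)) stop("`groups` required for by_impeller_type", call. = FALSE)
  means <- tapply(values, groups, mean)
  miss <- setdiff(unique(new_groups), names(means))
  if (length(miss) > 0)
    stop("empty group(s): ", paste(miss, collapse = ", "), call. = FALSE)
  as.numeric(means[new_groups])
}

#' Experimental-error bands from the estimator benchmark
#'
#' Converts an [estimator_benchmark()] result into the error bands used by
#' [error_band_metrics()]: the estimator's mean absolute error at M = 5
#' and M = 20 observations stands in for the experimental uncertainty of
#' the fitted kinetics. For `J` the band lives in log10 space (the scale
#' the models predict on), so the benchmark's mean absolute log10-error is
#' used; for `tg` the band is in seconds.
#'
#' @param benchmark An [estimator_benchmark()] tibble.
#' @param target `"J"` or `"tg"`.
#' @param method Which estimator's errors to use (default `"mle"`, the
#'   estimator used for the fitted kinetics).
#' @return A list of class `nk_band` with elements `m5`, `m20`, `target`.
#' @export
error_band_from_benchmark <- function(benchmark, target = c("J", "tg"),
                                      method = "mle") {
  target <- match.arg(target)
  b <- benchmark[benchmark$method == method, ]
  col <- if (target == "J") "mae_log10J" else "mae_tg"
  pick <- function(M) {
    row <- b[b$M == M, ]
    if (nrow(row) == 0)
      stop("benchmark lacks M = ", M, " for method ", method, call. = FALSE)
    row[[col]][1]
  }
  structure(list(m5 = pick(5), m20 = pick(20), target = target),
            class = "nk_band")
}

#' Error-band performance metrics for a model
#'
#' Alongside RMSE and the NaN-convention R-squared, reports the percentage
#' of predictions falling within the experimental error band of the
#' observations: |prediction - actual| <= MAE(M), where MAE(M) is the
#' estimator benchmark's mean absolute error at M = 5 (widest credible
#' band, fewest observations) and M = 20 observations. Predictions and
#' actuals must be on the scale the model predicts (log10 J for J models).
#'
#' @param predictions,actuals Numeric vectors of equal length.
#' @param band An [error_band_from_benchmark()] object.
#' @param split Label stored in the output (`"train"` or `"test"`).
#' @return A one-row tibble: `split`, `rmse`, `r2`, `pct_within_m5`,
#'   `pct_within_m20`.
#' @export
error_band_metrics <- function(predictions, actuals, band,
                               split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(inherits(band, "nk_band"))
  if (length(predictions) != length(actuals))
    stop("length mismatch between predictions and actuals", call. = FALSE)
  err <- abs(predictions - actuals)
  tibble::tibble(
    split = split,
    rmse = sqrt(mean((predictions - actuals)^2)),
    r2 = r2_with_nan(predictions, actuals),
    pct_within_m5 = 100 * mean(err <= band$m5),
    pct_within_m20 = 100 * mean(err <= band$m20))
}

#' Default model zoos for nucleation rate and growth time
#'
#' The standard model sets: for `J`, univariate benchmarks on the
#' classical scale-up parameters (Reynolds number, tip speed, specific
#' power) and the mean radial velocity, then ridge, LASSO, random forest,
#' kNN and gradient boosting on the reduced feature set. For `tg`,
#' constant-value benchmarks (global mean and per-impeller-type means),
#' univariate impeller-speed and tip-speed models, then the same
#' multivariate set.
#'
#' @return A list of model specifications for [train_regressors()].
#' @export
model_zoo_J <- function() {
  list(
    list(name = "J1", type = "univariate", features = "reynolds"),
    list(name = "J2", type = "univariate", features = "tip_speed"),
    list(name = "J3", type = "univariate", features = "specific_power"),
    list(name = "J4", type = "univariate", features = "radial_mean"),
    list(name = "J5", type = "ridge", features = "reduced"),
    list(name = "J6", type = "lasso", features = "reduced"),
    list(name = "J7", type = "random_forest", features = "reduced"),
    list(name = "J8", type = "knn", features = "reduced"),
    list(name = "J9", type = "gradient_boosting", features = "reduced"))
}

#' @rdname model_zoo_J
#' @export
model_zoo_tg <- function() {
  list(
    list(name = "T1", type = "constant", grouping = "all"),
    list(name = "T2", type = "constant", grouping = "by_impeller_type"),
    list(name = "T3", type = "univariate", features = "impeller_speed"),
    list(name = "T4", type = "univariate", features = "tip_speed"),
    list(name = "T5", type = "ridge", features = "reduced"),
    list(name = "T6", type = "lasso", features = "reduced"),
    list(name = "T7", type = "random_forest", features = "reduced"),
    list(name = "T8", type = "knn", features = "reduced"),
    list(name = "T9", type = "gradient_boosting", features = "reduced"))
}

#' Summarise a trained model zoo as a performance table
#'
#' One row per model with training (leave-one-out) and testing metrics:
#' RMSE, NaN-convention R-squared, and the error-band percentages on the
#' training split.
#'
#' @param models A named list of `nk_model`s from [train_regressors()].
#' @param band An [error_band_from_benchmark()] object on the models'
#'   prediction scale.
#' @return A tibble shaped like the study's model-performance tables.
#' @export
evaluate_zoo <- function(models, band) {
  rows <- lapply(models, function(m) {
    tr <- error_band_metrics(m$loo$pred, m$loo$actual, band, split = "train")
    te_pred <- predict(m, m$prep$test)
    te_act <- m$prep$test$y
    tibble::tibble(
      model = m$name, type = m$type,
      features = if (length(m$features) > 0)
        paste(setdiff(m$features, c("impeller_RC", "impeller_PBT")),
              collapse = "+") else m$fit$grouping %||% "none",
      train_rmse = tr$rmse, train_r2 = tr$r2,
      pct_within_m5 = tr$pct_within_m5, pct_within_m20 = tr$pct_within_m20,
      test_rmse = sqrt(mean((te_pred - te_act)^2)),
      test_r2 = if (length(te_act) >= 2) r2_with_nan(te_pred, te_act) else NaN)
  })
  dplyr::bind_rows(rows)
}
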