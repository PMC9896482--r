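fixture_checksums <- c(
  vessel_geometry.csv = "d92efe987e5bcff66a7c5183b3fd63b6",
  induction_kinetics.csv = "c1f349f98e19ec2b3914fbab94f01fb4")

#' Load the packaged study fixtures
#'
#' Returns the vessel/impeller geometry table and the per-configuration
#' induction-time kinetics table (fitted nucleation rate `J`, growth time
#' `tg_s`, number of observations `n_obs`, fit RMSE and train/test split
#' label), plus their join: one `configs` row per studied configuration
#' with geometry, operating conditions and split. Fixture files are
#' checksummed on load.
#'
#' @return A list with tibbles `geometry` (5 vessel/impeller rows),
#'   `kinetics` (17 configuration rows) and `configs` (kinetics joined
#'   with geometry, keyed by `config_id`).
#' @examples
#' fx <- load_fixtures()
#' sum(fx$kinetics$n_obs)  # 131 induction-time observations in total
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "nucleokin")
  for (f in names(fixture_checksums)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing packaged fixture: ", f, call. = FALSE)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(fixture_checksums[[f]])))
      stop("checksum mismatch for packaged fixture ", f, call. = FALSE)
  }
  geometry <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "vessel_geometry.csv"),
                    stringsAsFactors = FALSE))
  kinetics <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "induction_kinetics.csv"),
                    stringsAsFactors = FALSE))
  idx <- match(paste(kinetics$vessel, kinetics$impeller_type),
               paste(geometry$vessel, geometry$impeller_type))
  if (anyNA(idx)) stop("kinetics row without matching geometry", call. = FALSE)
  configs <- dplyr::bind_cols(
    kinetics,
    geometry[idx, c("vessel_diameter_mm", "liquid_height_mm",
                    "impeller_diameter_mm")])
  configs$config_id <- sprintf("%s_%s_%drpm", configs$vessel,
                               configs$impeller_type,
                               configs$impeller_speed_rpm)
  stopifnot(all(configs$impeller_diameter_mm < configs$vessel_diameter_mm))
  list(geometry = geometry, kinetics = kinetics, configs = configs)
}

#' Build a pipeline run configuration
#'
#' A nested list of every setting consumed by [run_pipeline()], with
#' defaults mirroring the study protocol: MLE estimation of the kinetics,
#' 1000 bootstrap resamples when bootstrapping, direct-fit bounds
#' J in [0.01, 20] #/(m^3 s) and t_g in [3000, 30000] s, benchmark at
#' J = 0.1 #/(m^3 s), V = 0.01 m^3, t_g = 10,000 s over M in
#' {5, 10, 20, 40, 80} with 1000 datasets per M, and a 0.95 Pearson
#' reduction threshold. Every stochastic stage derives its seed
#' deterministically from the root `seed`. The configuration round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed Root integer seed.
#' @param out_dir Directory for run artifacts.
#' @param ... Named overrides for any top-level section (`estimator`,
#'   `benchmark`, `study`, `ml`, `ensemble`), each a list merged over the
#'   defaults.
#' @return A list of class `nk_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("nucleokin_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    estimator = list(method = "mle", n_boot = 1000L,
                     bounds_J = c(0.01, 20), bounds_tg = c(3000, 30000),
                     convention = "i_over_M"),
    benchmark = list(true_J = 0.1, true_tg = 10000, volume = 0.01,
                     M_list = c(5, 10, 20, 40, 80), n_datasets = 1000L,
                     methods = c("direct", "mle")),
    study = list(n_configs = 17L, M = 10L,
                 noise = list(logJ_sd = 0, tg_sd = 0)),
    ml = list(r_max = 0.95),
    ensemble = list(model_J = "best_loo", model_tg = "best_loo"),
    inputs = list())
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "nk_config")
}

#' @rdname run_config
#' @param config An `nk_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  miss <- setdiff(names(base), names(cfg))
  if (length(miss) > 0)
    stop("config file lacks section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "nk_config")
}

write_stage_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-12s done in %.1f s", name,
              proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full scale-up analysis pipeline
#'
#' Executes the study's analysis scheme end to end on a synthetic study:
#' generate (or load) induction-time data and hydrodynamic features,
#' estimate the per-configuration kinetics, benchmark the estimators to
#' obtain experimental error bands, reduce the features, train the J and
#' t_g model zoos with leave-one-out validation, ensemble the chosen
#' models into predicted induction-time distributions for the test
#' configurations, score them against the held-out observations (against
#' a tip-speed + constant-value benchmark ensemble), and compute Shapley
#' feature attributions. Every intermediate table is written as CSV under
#' `config$out_dir` together with a `manifest.yaml` recording the seeds
#' used per stage.
#'
#' @param config An [run_config()] object.
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `nk_run` with the study, estimated kinetics,
#'   benchmark, reduction, trained zoos, zoo evaluation tables, ensemble
#'   evaluations, attributions and the manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "nk_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(msg) if (!quiet) message("[nucleokin] ", msg)
  seed <- config$seed
  seeds <- list(study = seed, benchmark = seed + 1000L,
                training = seed + 2000L, attribution = seed + 3000L)

  # -- stage 1: data (synthetic study, or user-supplied tables)
  study <- run_stage("data", log, {
    if (length(config$inputs) > 0) {
      for (p in unlist(config$inputs))
        if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
      stop("external-input mode expects induction, feature and config CSVs; ",
           "not configured", call. = FALSE)
    }
    generate_study(n_configs = config$study$n_configs, M = config$study$M,
                   noise = config$study$noise, seed = seeds$study)
  })
  write_stage_csv(study$configs, config$out_dir, "configs.csv")
  write_stage_csv(study$features, config$out_dir, "features.csv")
  write_stage_csv(study$truth, config$out_dir, "true_kinetics.csv")
  write_induction_csv(study$datasets, file.path(config$out_dir, "induction_times.csv"))

  # -- stage 2: kinetics estimation per configuration
  est <- config$estimator
  kinetics <- run_stage("estimate", log, {
    dplyr::bind_rows(lapply(study$datasets, function(d) {
      fit <- switch(est$method,
        mle = fit_mle(d, convention = est$convention),
        direct = fit_direct(d, bounds_J = est$bounds_J,
                            bounds_tg = est$bounds_tg,
                            convention = est$convention),
        bootstrap = ,
        mle_bootstrap = bootstrap_fit(
          d, n_boot = est$n_boot,
          base = if (est$method == "mle_bootstrap") "mle" else "direct",
          seed = seed + 10L, convention = est$convention),
        stop("unknown estimator method: ", est$method, call. = FALSE))
      tibble::tibble(config_id = d$config_id, J = fit$params$J,
                     tg = fit$params$tg, fit_rmse = fit$fit_rmse,
                     method = fit$method, M = d$M)
    }))
  })
  write_stage_csv(kinetics, config$out_dir, "estimated_kinetics.csv")

  # -- stage 3: estimator benchmark -> experimental error bands
  bm <- config$benchmark
  benchmark <- run_stage("benchmark", log, {
    estimator_benchmark(
      true_params = distribution_params(bm$true_J, bm$true_tg),
      volume = bm$volume, M_list = bm$M_list,
      n_datasets = bm$n_datasets, methods = bm$methods,
      seed = seeds$benchmark,
      bounds_J = est$bounds_J, bounds_tg = est$bounds_tg,
      convention = est$convention)
  })
  write_stage_csv(benchmark, config$out_dir, "estimator_benchmark.csv")
  band_method <- if (est$method %in% benchmark$method) est$method else benchmark$method[1]
  band_J <- error_band_from_benchmark(benchmark, "J", method = band_method)
  band_tg <- error_band_from_benchmark(benchmark, "tg", method = band_method)

  # -- stage 4: feature matrix, reduction, model training
  fm <- feature_matrix(study$features, study$configs)
  red <- run_stage("reduce", log,
                   reduce_features(fm[fm$split == "training_validation", ],
                                   r_max = config$ml$r_max))
  models <- run_stage("train", log, {
    prep_J <- preprocess(fm, "J", kinetics)
    prep_tg <- preprocess(fm, "tg", kinetics)
    list(
      J = train_regressors(prep_J, model_zoo_J(), reduced_cols = red$kept,
                           seed = seeds$training),
      tg = train_regressors(prep_tg, model_zoo_tg(), reduced_cols = red$kept,
                            seed = seeds$training))
  })
  eval_J <- evaluate_zoo(models$J, band_J)
  eval_tg <- evaluate_zoo(models$tg, band_tg)
  write_stage_csv(eval_J, config$out_dir, "model_table_J.csv")
  write_stage_csv(eval_tg, config$out_dir, "model_table_tg.csv")

  # -- stage 5: ensembles on the test configurations
  pick <- function(zoo, choice) {
    if (identical(choice, "best_loo")) {
      zoo[[which.min(vapply(zoo, function(m) m$loo_rmse, numeric(1)))]]
    } else zoo[[choice]]
  }
  ens <- run_stage("ensemble", log, {
    model_J <- pick(models$J, config$ensemble$model_J)
    model_tg <- pick(models$tg, config$ensemble$model_tg)
    test_ids <- study$configs$config_id[study$configs$split == "testing"]
    observed <- study$datasets[test_ids]
    curves_for <- function(mJ, mt) {
      lapply(test_ids, function(id) {
        row <- fm[fm$config_id == id, ]
        d <- observed[[id]]
        grid <- seq(0, max(d$times) * 1.2, length.out = 200)
        ensemble_predict(mJ, mt, row, d$volume, grid)
      })
    }
    curves <- curves_for(model_J, model_tg)
    # no-CFD/no-ML benchmark: tip-speed univariate J + per-impeller mean t_g
    bench_curves <- curves_for(models$J[["J2"]], models$tg[["T2"]])
    list(model_J = model_J$name, model_tg = model_tg$name,
         curves = curves,
         chosen = evaluate_ensemble(curves, unname(observed),
                                    convention = est$convention),
         benchmark = evaluate_ensemble(bench_curves, unname(observed),
                                       convention = est$convention))
  })
  curves_df <- dplyr::bind_rows(lapply(ens$curves, function(cv) {
    tibble::tibble(config_id = cv$config_id, time_s = cv$time_grid,
                   prob = cv$probabilities)
  }))
  write_stage_csv(curves_df, config$out_dir, "predicted_curves.csv")
  ens_summary <- tibble::tibble(
    ensemble = c(sprintf("%s + %s", ens$model_J, ens$model_tg),
                 "J2 + T2 (no-CFD/no-ML benchmark)"),
    rmse = c(ens$chosen$rmse, ens$benchmark$rmse),
    r2 = c(ens$chosen$r2, ens$benchmark$r2),
    rmse_mean_config = c(ens$chosen$rmse_mean, ens$benchmark$rmse_mean))
  write_stage_csv(ens_summary, config$out_dir, "ensemble_summary.csv")

  # -- stage 6: feature attribution for the chosen models
  attribution <- run_stage("explain", log, {
    list(J = feature_attribution(models$J[[ens$model_J]],
                                 seed = seeds$attribution),
         tg = feature_attribution(models$tg[[ens$model_tg]],
                                  seed = seeds$attribution))
  })
  write_stage_csv(attribution$J$summary, config$out_dir, "attribution_J.csv")
  write_stage_csv(attribution$tg$summary, config$out_dir, "attribution_tg.csv")

  manifest <- list(seed = seed, stage_seeds = seeds,
                   estimator = est$method,
                   ensemble = sprintf("%s + %s", ens$model_J, ens$model_tg),
                   r_max = config$ml$r_max,
                   n_configs = nrow(study$configs))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  structure(
    list(config = config, study = study, kinetics = kinetics,
         benchmark = benchmark, bands = list(J = band_J, tg = band_tg),
         reduction = red, models = models,
         evaluation = list(J = eval_J, tg = eval_tg),
         ensemble = ens, ensemble_summary = ens_summary,
         attribution = attribution, manifest = manifest),
    class = "nk_run")
}

#' @export
print.nk_run <- function(x, ...) {
  cat(sprintf("nucleokin pipeline run (seed %d): %d configurations\n",
              x$manifest$seed, x$manifest$n_configs))
  cat(sprintf("  kinetics estimator: %s; reduced features: %s\n",
              x$manifest$estimator, paste(x$reduction$kept, collapse = ", ")))
  cat(sprintf("  ensemble %s: pooled RMSE %.3g (benchmark %.3g)\n",
              x$manifest$ensemble, x$ensemble$chosen$rmse,
              x$ensemble$benchmark$rmse))
  invisible(x)
}
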