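#' Generate synthetic induction times from the Poisson model
#'
#' Draws `M` uniform probabilities on `[0, 1)` and maps them through the
#' model quantile function [invert_cdf()], producing induction times
#' distributed exactly as the shifted-exponential induction-time model.
#' `u = 1` cannot be drawn, keeping all times finite.
#'
#' @param params True [distribution_params()].
#' @param volume Solution volume, m^3.
#' @param M Number of observations.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param config_id Label for the resulting dataset.
#' @return An [induction_dataset()].
#' @examples
#' generate_induction_times(distribution_params(0.1, 10000), 0.01, M = 10, seed = 1)
#' @export
generate_induction_times <- function(params, volume, M, seed,
                                     config_id = "synthetic") {
  stopifnot(inherits(params, "nk_params"), M >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  u <- stats::runif(M)  # in [0, 1); u = 1 has probability zero and is excluded
  induction_dataset(config_id, invert_cdf(u, params, volume), volume)
}

# Draw one M-vector of induction times from the current RNG stream.
draw_times <- function(params, volume, M) {
  invert_cdf(stats::runif(M), params, volume)
}

# Vectorised MLE-with-bootstrap over a single dataset: resample matrix,
# closed-form MLE per row, degenerate rows dropped.
mle_bootstrap_raw <- function(times, volume, n_boot) {
  M <- length(times)
  idx <- matrix(sample.int(M, M * n_boot, replace = TRUE), nrow = n_boot)
  tmat <- matrix(times[idx], nrow = n_boot)
  mins <- do.call(pmin, as.data.frame(tmat))
  ssum <- rowSums(tmat) - M * mins
  ok <- ssum > 0
  if (!any(ok)) return(NULL)
  J <- (M / ssum[ok]) / volume
  c(mean(J), mean(mins[ok]))
}

#' Benchmark the distribution-parameter estimators on synthetic data
#'
#' Generates `n_datasets` synthetic induction-time datasets for each
#' dataset size in `M_list`, fits each requested estimator to every
#' dataset, and reports the mean absolute error of the fitted `J` and `tg`
#' against the generating values. Datasets on which an estimator fails (or
#' is degenerate) are excluded from that estimator's average and counted.
#'
#' Defaults reproduce the study conditions of the estimator comparison:
#' J = 0.1 #/(m^3 s), V = 0.01 m^3, t_g = 10,000 s, M in {5, 10, 20, 40,
#' 80}, 1000 datasets per M. Note the bootstrap-based methods refit their
#' base estimator `n_boot` times per dataset, which for the direct-fit base
#' is computationally heavy at the full default scale.
#'
#' @param true_params Generating [distribution_params()].
#' @param volume Solution volume, m^3.
#' @param M_list Dataset sizes to benchmark.
#' @param n_datasets Datasets per size.
#' @param methods Subset of `c("direct", "mle", "bootstrap",
#'   "mle_bootstrap")`.
#' @param seed Integer root seed.
#' @param n_boot Resamples for the bootstrap-based methods.
#' @param bounds_J,bounds_tg Box constraints for the direct fit.
#' @param convention Plotting-position convention for the direct fit.
#' @return A tibble of class `nk_benchmark` with one row per (method, M):
#'   columns `method`, `M`, `mae_J`, `mae_tg`, `mae_log10J`, `n_datasets`,
#'   `n_failed`, `true_J`, `true_tg`, `true_volume`. `mae_log10J` is the
#'   mean absolute error of log10(J), the error measure used for
#'   model-performance bands on the log scale.
#' @export
estimator_benchmark <- function(true_params = distribution_params(0.1, 10000),
                                volume = 0.01,
                                M_list = c(5, 10, 20, 40, 80),
                                n_datasets = 1000L,
                                methods = c("direct", "mle"),
                                seed = 1L,
                                n_boot = 1000L,
                                bounds_J = c(0.01, 20),
                                bounds_tg = c(3000, 30000),
                                convention = "i_over_M") {
  allowed <- c("direct", "mle", "bootstrap", "mle_bootstrap")
  if (!all(methods %in% allowed))
    stop("unknown method(s): ", paste(setdiff(methods, allowed), collapse = ", "),
         call. = FALSE)
  stopifnot(n_datasets >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  rows <- list()
  for (M in M_list) {
    est <- array(NA_real_, dim = c(n_datasets, length(methods), 2L),
                 dimnames = list(NULL, methods, c("J", "tg")))
    for (d in seq_len(n_datasets)) {
      times <- draw_times(true_params, volume, M)
      for (m in methods) {
        val <- switch(m,
          mle = mle_raw(times, volume),
          direct = {
            fit <- tryCatch(
              fit_direct(induction_dataset("bench", times, volume),
                         bounds_J = bounds_J, bounds_tg = bounds_tg,
                         convention = convention),
              error = function(e) NULL)
            if (is.null(fit)) NULL else c(fit$params$J, fit$params$tg)
          },
          bootstrap = {
            fit <- tryCatch(
              bootstrap_fit(induction_dataset("bench", times, volume),
                            n_boot = n_boot, base = "direct",
                            seed = sample.int(.Machine$integer.max, 1L),
                            bounds_J = bounds_J, bounds_tg = bounds_tg,
                            convention = convention),
              error = function(e) NULL)
            if (is.null(fit)) NULL else c(fit$params$J, fit$params$tg)
          },
          mle_bootstrap = mle_bootstrap_raw(times, volume, n_boot))
        if (!is.null(val)) est[d, m, ] <- val
      }
    }
    for (m in methods) {
      ok <- stats::complete.cases(est[, m, , drop = FALSE][, 1, ])
      nf <- sum(!ok)
      J_hat <- est[ok, m, "J"]; tg_hat <- est[ok, m, "tg"]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, M = M,
        mae_J = mean(abs(J_hat - true_params$J)),
        mae_tg = mean(abs(tg_hat - true_params$tg)),
        mae_log10J = mean(abs(log10(J_hat) - log10(true_params$J))),
        n_datasets = sum(ok), n_failed = nf,
        true_J = true_params$J, true_tg = true_params$tg,
        true_volume = volume)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nk_benchmark", class(out))
  out
}

# ---- synthetic hydrodynamic feature fabrication -----------------------------

# Fixed multipliers turning each family mean into its 25/50/75% quantiles.
quantile_ratios <- function() c(q25 = 0.55, q50 = 0.8, q75 = 1.15)

#' Fabricate CFD-like hydrodynamic feature tables
#'
#' Builds, for each vessel configuration, a synthetic row with the 19
#' canonical CFD feature columns. The fabrication recipe is a fixture
#' generator, not a physics model: each feature family is a base scalar
#' derived from classical mixing quantities (tip speed, Reynolds number,
#' specific power) scaled by a fixed family coefficient and a per-row
#' lognormal jitter (sigma = 0.1); the quantile columns are fixed multiples
#' (0.55, 0.8, 1.15) of the jittered family mean. This forces the strong
#' inter-feature collinearity seen in real CFD summaries (quantiles of one
#' field move together), so downstream correlation-based feature reduction
#' has realistic work to do.
#'
#' @param configs Vessel-configuration table with columns `config_id`,
#'   `impeller_type`, `impeller_speed_rpm`, `impeller_diameter_mm`,
#'   `vessel_diameter_mm`, `volume_ml`.
#' @param fluid An [fluid_properties()] object.
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Lognormal sigma of the per-row family jitter.
#' @return A validated feature tibble (`config_id` + 19 columns).
#' @export
generate_hydrodynamic_features <- function(configs, fluid = default_fluid(),
                                           seed = 1L, jitter_sd = 0.1) {
  stopifnot(inherits(fluid, "nk_fluid"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  N <- rpm_to_hz(configs$impeller_speed_rpm)
  D <- configs$impeller_diameter_mm / 1000
  Tv <- configs$vessel_diameter_mm / 1000
  V <- configs$volume_ml / 1e6
  Np <- power_number_for(configs$impeller_type)
  utip <- tip_speed(N, D)
  eps_bar <- specific_power(Np, fluid, N, D, V)     # W/m^3
  n <- nrow(configs)
  jit <- function() exp(stats::rnorm(n, 0, jitter_sd))

  # Family base scalars, with classical scalings so features move
  # monotonically with impeller speed for fixed geometry.
  sr_base <- 11 * N * (D / Tv)            # 1/s, Metzner-Otto-like mean shear
  ep_base <- eps_bar / fluid$density      # m^2/s^3, mass-specific dissipation
  k_base <- 0.1 * utip^2                  # m^2/s^2
  U_base <- 0.3 * utip                    # m/s

  fam <- function(base, prefix) {
    m <- base * jit()
    r <- quantile_ratios()
    out <- tibble::tibble(m, m * r[["q25"]], m * r[["q50"]], m * r[["q75"]])
    names(out) <- paste0(prefix, c("_mean", "_q25", "_q50", "_q75"))
    out
  }

  out <- dplyr::bind_cols(
    tibble::tibble(config_id = configs$config_id),
    fam(sr_base, "sr"), fam(ep_base, "ep"), fam(k_base, "k"), fam(U_base, "U"),
    tibble::tibble(
      axial_mean = U_base * ifelse(configs$impeller_type == "PBT", 0.45, 0.12) * jit(),
      radial_mean = U_base * ifelse(configs$impeller_type == "RC", 0.40, 0.18) * jit(),
      power_draw = eps_bar * jit()))
  validate_cfd_features(out)
  out
}

#' Default ground-truth mapping from hydrodynamic features to kinetics
#'
#' The linear mapping, in standardized feature space, used by
#' [generate_study()] to give fabricated configurations known nucleation
#' kinetics: \eqn{\log_{10} J = a_0 + a_1 \log_{10} V + a_2 z(sr\_mean) +
#' a_3 z(ep\_mean)} and \eqn{t_g = b_0 - b_1 z(rpm) - b_2 z(ep\_mean)}
#' (clipped at `tg_floor`). Coefficients default to magnitudes matching the
#' small-scale observation that J V is roughly constant (a0, a1) and to
#' positive shear/dissipation effects on J, negative speed/dissipation
#' effects on t_g.
#'
#' @param a0,a1,a2,a3 Coefficients for log10(J).
#' @param b0,b1,b2 Coefficients for tg (s).
#' @param tg_floor Lower clip for tg, s.
#' @return A list of class `nk_mapping`.
#' @export
default_mapping <- function(a0 = -3.9, a1 = -1, a2 = 0.15, a3 = 0.20,
                            b0 = 11000, b1 = 3000, b2 = 2000,
                            tg_floor = 600) {
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3,
                 b0 = b0, b1 = b1, b2 = b2, tg_floor = tg_floor),
            class = "nk_mapping")
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) stop("cannot standardize a zero-variance vector", call. = FALSE)
  (x - mean(x)) / s
}

# Apply an nk_mapping to a feature table + configs, returning per-config
# true (J, tg) before sampling noise.
apply_mapping <- function(mapping, features, configs) {
  V <- configs$volume_ml / 1e6
  z_sr <- zscore(features$sr_mean)
  z_ep <- zscore(features$ep_mean)
  z_rpm <- zscore(configs$impeller_speed_rpm)
  log10J <- mapping$a0 + mapping$a1 * log10(V) + mapping$a2 * z_sr +
    mapping$a3 * z_ep
  tg <- pmax(mapping$b0 - mapping$b1 * z_rpm - mapping$b2 * z_ep,
             mapping$tg_floor)
  tibble::tibble(config_id = configs$config_id, J = 10^log10J, tg = tg)
}

#' Construct a set of synthetic vessel configurations
#'
#' For `n_configs = 17` this is the packaged study layout (the fixture
#' vessel/impeller/speed combinations). For other sizes, configurations are
#' built by cycling through the packaged vessel geometries and drawing
#' impeller speeds uniformly within each vessel's studied range.
#'
#' @param n_configs Number of configurations (>= 4).
#' @param seed Integer seed (used only when speeds are drawn).
#' @return A config tibble with a `config_id` column, geometry, speed,
#'   volume and a `split` column (last ~18% of rows labelled `testing`).
#' @export
synthetic_vessel_configs <- function(n_configs = 17L, seed = 1L) {
  stopifnot(n_configs >= 4)
  fx <- load_fixtures()
  if (n_configs == 17L) return(fx$configs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  geo <- fx$geometry
  rows <- lapply(seq_len(n_configs), function(i) {
    g <- geo[((i - 1L) %% nrow(geo)) + 1L, ]
    rpm <- round(stats::runif(1, 150, 450))
    vol <- c(EasyMax = 85, OptiMax = 630, Miniplant = 9300)[[g$vessel]]
    tibble::tibble(
      vessel = g$vessel, volume_ml = vol, impeller_type = g$impeller_type,
      impeller_speed_rpm = rpm,
      vessel_diameter_mm = g$vessel_diameter_mm,
      liquid_height_mm = g$liquid_height_mm,
      impeller_diameter_mm = g$impeller_diameter_mm,
      config_id = sprintf("%s_%s_%drpm_%02d", g$vessel, g$impeller_type, rpm, i))
  })
  out <- dplyr::bind_rows(rows)
  n_test <- max(1L, round(0.18 * n_configs))
  out$split <- c(rep("training_validation", n_configs - n_test),
                 rep("testing", n_test))
  out
}

#' Generate a complete synthetic scale-up study
#'
#' End-to-end fixture for the pipeline: vessel configurations, fabricated
#' hydrodynamic features, a known linear mapping from features to the true
#' kinetics (J, t_g), and induction-time datasets sampled from those
#' kinetics. Because the generating mapping is recorded, downstream model
#' training and attribution can be tested against known coefficient signs.
#'
#' @param n_configs Number of configurations (>= 4; 17 reproduces the
#'   packaged study layout).
#' @param M Observations per configuration: a scalar or a vector of length
#'   `n_configs`.
#' @param noise List with elements `logJ_sd` and `tg_sd`: the standard
#'   deviations of Gaussian perturbations added to log10(J) and tg (s)
#'   before sampling, representing config-level deviations from the
#'   mapping. Defaults to zero noise.
#' @param mapping An [default_mapping()] object.
#' @param fluid An [fluid_properties()] object.
#' @param seed Integer root seed; every stage draws from seeds derived
#'   deterministically from it.
#' @return An object of class `nk_study`: a list with `configs`,
#'   `features` (19 CFD columns + derived scalars), `truth` (per-config
#'   J, tg actually used), `mapping`, `datasets` (named list of
#'   [induction_dataset()]), and `seed`.
#' @export
generate_study <- function(n_configs = 17L, M = 10L,
                           noise = list(logJ_sd = 0, tg_sd = 0),
                           mapping = default_mapping(),
                           fluid = default_fluid(), seed = 1L) {
  stopifnot(inherits(mapping, "nk_mapping"))
  seed <- as.integer(seed)
  configs <- synthetic_vessel_configs(n_configs, seed = seed)
  n <- nrow(configs)
  M <- rep_len(as.integer(M), n)

  features <- generate_hydrodynamic_features(configs, fluid, seed = seed + 1L)
  truth <- apply_mapping(mapping, features, configs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 2L)
  logJ_sd <- noise$logJ_sd %||% 0
  tg_sd <- noise$tg_sd %||% 0
  truth$J <- 10^(log10(truth$J) + stats::rnorm(n, 0, logJ_sd))
  truth$tg <- pmax(truth$tg + stats::rnorm(n, 0, tg_sd), mapping$tg_floor)

  datasets <- lapply(seq_len(n), function(i) {
    generate_induction_times(
      distribution_params(truth$J[i], truth$tg[i]),
      volume = configs$volume_ml[i] / 1e6, M = M[i],
      seed = seed + 100L + i, config_id = configs$config_id[i])
  })
  names(datasets) <- configs$config_id

  features <- augment_features(features, configs, fluid)
  structure(
    list(configs = configs, features = features, truth = truth,
         mapping = mapping, datasets = datasets, seed = seed),
    class = "nk_study")
}

#' @export
print.nk_study <- function(x, ...) {
  cat(sprintf("Synthetic scale-up study: %d configurations, seed %d\n",
              nrow(x$configs), x$seed))
  cat(sprintf("  J range [%.3g, %.3g] #/(m^3 s); t_g range [%.4g, %.4g] s\n",
              min(x$truth$J), max(x$truth$J), min(x$truth$tg), max(x$truth$tg)))
  invisible(x)
}
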