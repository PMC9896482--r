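#' Study conditions for an isothermal induction-time experiment
#'
#' Bundles the temperature, solute concentration and solubility that define a
#' constant-supersaturation induction-time study, and checks that the stored
#' supersaturation ratio is consistent with \eqn{S = c/c^*}.
#'
#' @param temperature Solution temperature, degrees C.
#' @param concentration Solute concentration \eqn{c}, g solute / kg solvent.
#' @param solubility Equilibrium solubility \eqn{c^*} at `temperature`,
#'   g solute / kg solvent.
#' @param supersaturation Optional stored supersaturation ratio \eqn{S}. If
#'   supplied it must agree with `concentration / solubility` to within 0.5%;
#'   if omitted it is computed from the ratio.
#'
#' @return An object of class `nk_conditions`: a list with fields
#'   `temperature`, `concentration`, `solubility`, `supersaturation`.
#' @examples
#' study_conditions(15, concentration = 155.81, solubility = 97.38)
#' @export
study_conditions <- function(temperature, concentration, solubility,
                             supersaturation = NULL) {
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            is.numeric(solubility), length(solubility) == 1L)
  if (!is.finite(concentration) || concentration <= 0)
    stop("`concentration` must be a positive finite number", call. = FALSE)
  if (!is.finite(solubility) || solubility <= 0)
    stop("`solubility` must be a positive finite number", call. = FALSE)
  ratio <- concentration / solubility
  if (is.null(supersaturation)) {
    supersaturation <- ratio
  } else if (abs(supersaturation / ratio - 1) > 0.005) {
    stop(sprintf(
      "stored supersaturation %.4g inconsistent with c/c* = %.4g (> 0.5%%)",
      supersaturation, ratio), call. = FALSE)
  }
  structure(
    list(temperature = temperature, concentration = concentration,
         solubility = solubility, supersaturation = supersaturation),
    class = "nk_conditions")
}

#' Induction-time distribution parameters
#'
#' The parameter pair of the Poisson induction-time model: the primary
#' nucleation rate `J` (#/(m^3 s)) and the growth time `tg` (s), the lag
#' between the nucleation event and the crystal population reaching the
#' detection threshold.
#'
#' @param J Nucleation rate per unit volume, #/(m^3 s). Must be > 0.
#' @param tg Growth time, s. Must be >= 0.
#' @return An object of class `nk_params`.
#' @examples
#' distribution_params(J = 0.1, tg = 10000)
#' @export
distribution_params <- function(J, tg) {
  stopifnot(is.numeric(J), length(J) == 1L, is.numeric(tg), length(tg) == 1L)
  if (!is.finite(J) || J <= 0) stop("`J` must be > 0 and finite", call. = FALSE)
  if (!is.finite(tg) || tg < 0) stop("`tg` must be >= 0 and finite", call. = FALSE)
  structure(list(J = J, tg = tg), class = "nk_params")
}

#' @export
print.nk_params <- function(x, ...) {
  cat(sprintf("Induction-time distribution parameters: J = %.4g #/(m^3 s), t_g = %.6g s\n",
              x$J, x$tg))
  invisible(x)
}

#' One configuration's induction-time observations
#'
#' Stores a series of measured induction times together with the solution
#' volume in which they were observed. Times are kept in ascending order.
#'
#' @param config_id Text label for the vessel/impeller/speed configuration.
#' @param times Induction times \eqn{t_i}, s. All must be strictly positive
#'   and finite; censored (non-nucleated) runs are not representable and must
#'   be excluded upstream.
#' @param volume Solution volume \eqn{V}, m^3.
#' @return An object of class `nk_dataset` with fields `config_id`, `times`
#'   (sorted ascending), `volume` and `M` (the number of observations).
#' @examples
#' induction_dataset("demo", times = c(12000, 10500, 15000), volume = 0.01)
#' @export
induction_dataset <- function(config_id, times, volume) {
  stopifnot(is.character(config_id), length(config_id) == 1L)
  times <- as.numeric(times)
  if (length(times) < 1L) stop("at least one induction time is required", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("induction times must be finite and non-missing", call. = FALSE)
  if (any(times <= 0))
    stop("induction times must be strictly positive (censored runs are not modelled)",
         call. = FALSE)
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0)
    stop("`volume` must be a positive finite scalar (m^3)", call. = FALSE)
  structure(
    list(config_id = config_id, times = sort(times), volume = volume,
         M = length(times)),
    class = "nk_dataset")
}

#' @export
print.nk_dataset <- function(x, ...) {
  cat(sprintf("Induction-time dataset '%s': M = %d observations, V = %.4g m^3\n",
              x$config_id, x$M, x$volume))
  cat(sprintf("  times [s]: min %.5g, median %.5g, max %.5g\n",
              min(x$times), stats::median(x$times), max(x$times)))
  invisible(x)
}

#' Cumulative probability of nucleation under the Poisson model
#'
#' Evaluates the induction-time cumulative distribution
#' \deqn{P(t) = 1 - \exp(-J V (t - t_g)), \quad t \ge t_g,}
#' and 0 for \eqn{t < t_g}: under the single nucleus mechanism, nucleation
#' events in a stirred volume \eqn{V} at rate \eqn{J} form a stationary
#' Poisson process, and detection lags the nucleation event by the growth
#' time \eqn{t_g}.
#'
#' @param t Time(s), s. Vectorised.
#' @param params An [distribution_params()] object.
#' @param volume Solution volume, m^3.
#' @return Probabilities in `[0, 1]`, nondecreasing in `t`.
#' @examples
#' p <- distribution_params(0.1, 10000)
#' model_cdf(c(10000, 10693.1), p, volume = 0.01)
#' @export
model_cdf <- function(t, params, volume) {
  stopifnot(inherits(params, "nk_params"))
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("`volume` must be a positive scalar (m^3)", call. = FALSE)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric time(s) in seconds", call. = FALSE)
  # -expm1 keeps precision for small J*V*(t - tg)
  ifelse(t <= params$tg, 0, -expm1(-params$J * volume * (t - params$tg)))
}

#' Quantile function of the Poisson induction-time model
#'
#' Inverts [model_cdf()]:
#' \eqn{t(P) = t_g - \ln(1 - P)/(J V)} for \eqn{P \in [0, 1)}.
#'
#' @inheritParams model_cdf
#' @param p Probabilities in `[0, 1)`. `p = 1` is rejected (the model's
#'   support is unbounded).
#' @return Times in s, all `>= tg`.
#' @export
invert_cdf <- function(p, params, volume) {
  stopifnot(inherits(params, "nk_params"))
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("`volume` must be a positive scalar (m^3)", call. = FALSE)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p >= 1))
    stop("`p` must lie in [0, 1); the quantile is unbounded at p = 1", call. = FALSE)
  params$tg - log1p(-p) / (params$J * volume)
}

#' Empirical cumulative probability of observed induction times
#'
#' For times sorted ascending the observed cumulative probability at the
#' i-th observation is \eqn{P_i = i/M} (default) or \eqn{P_i = i/(M+1)}.
#' Tied times all carry the probability of the largest rank among them, so
#' that \eqn{P(t)} equals the fraction of observations at or below \eqn{t}.
#'
#' @param dataset An [induction_dataset()].
#' @param convention Plotting-position convention, `"i_over_M"` (default) or
#'   `"i_over_M1"` for \eqn{i/(M+1)}.
#' @return A tibble with columns `time` (ascending) and `prob`, one row per
#'   observation.
#' @export
empirical_cdf <- function(dataset, convention = c("i_over_M", "i_over_M1")) {
  stopifnot(inherits(dataset, "nk_dataset"))
  convention <- match.arg(convention)
  t <- dataset$times
  M <- dataset$M
  counts <- vapply(t, function(x) sum(t <= x), integer(1))
  denom <- if (convention == "i_over_M") M else M + 1L
  tibble::tibble(time = t, prob = counts / denom)
}

#' Mean and median induction time
#'
#' The arithmetic mean of the observed induction times, and the sample
#' median. When observation windows are finite the mean is biased by
#' unobserved long induction times, so the median is the more robust
#' location summary; both are reported.
#'
#' @param dataset An [induction_dataset()].
#' @return A tibble with columns `config_id`, `n`, `mean_s`, `median_s`.
#' @export
induction_summary <- function(dataset) {
  stopifnot(inherits(dataset, "nk_dataset"))
  tibble::tibble(config_id = dataset$config_id, n = dataset$M,
                 mean_s = mean(dataset$times),
                 median_s = stats::median(dataset$times))
}

#' Read and write induction-time tables
#'
#' The on-disk form is a long CSV with columns `config_id` and `time_s`.
#' Volumes are not part of the long table (they are a property of the vessel
#' configuration), so the reader takes a named vector of volumes in m^3.
#'
#' @param path CSV path.
#' @param volumes Named numeric vector mapping `config_id` to solution
#'   volume, m^3.
#' @return `read_induction_csv()`: a named list of [induction_dataset()]
#'   objects; `write_induction_csv()`: `path`, invisibly.
#' @export
read_induction_csv <- function(path, volumes) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("config_id", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("induction CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(df$time_s))
    stop("induction CSV contains missing times", call. = FALSE)
  ids <- unique(df$config_id)
  if (!all(ids %in% names(volumes)))
    stop("no volume supplied for config(s): ",
         paste(setdiff(ids, names(volumes)), collapse = ", "), call. = FALSE)
  out <- lapply(ids, function(id) {
    induction_dataset(id, df$time_s[df$config_id == id], volumes[[id]])
  })
  stats::setNames(out, ids)
}

#' @rdname read_induction_csv
#' @param datasets A list of [induction_dataset()] objects.
#' @export
write_induction_csv <- function(datasets, path) {
  if (inherits(datasets, "nk_dataset")) datasets <- list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(config_id = d$config_id, time_s = d$times)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
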