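#' Fluid properties of the crystallizing solution
#'
#' @param density Fluid density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return An object of class `nk_fluid`.
#' @examples
#' fluid_properties(820, 2.3e-3)
#' @export
fluid_properties <- function(density, viscosity) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0)
    stop("`density` must be a positive finite scalar (kg/m^3)", call. = FALSE)
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be a positive finite scalar (Pa s)", call. = FALSE)
  structure(list(density = density, viscosity = viscosity), class = "nk_fluid")
}

#' Default fluid preset: paracetamol-isopropanol solution near 15 degrees C
#'
#' A convenience preset (density 820 kg/m^3, viscosity 2.3e-3 Pa s)
#' representative of a concentrated paracetamol solution in isopropanol at
#' the study temperature. Density and viscosity remain explicit inputs to
#' every calculation; the preset only supplies typical values.
#'
#' @return An `nk_fluid`.
#' @export
default_fluid <- function() fluid_properties(density = 820, viscosity = 2.3e-3)

#' Convert impeller speed from rpm to revolutions per second
#'
#' All hydrodynamic formulas in the package take SI units; vessel tables
#' print rpm, so the conversion is centralised here.
#'
#' @param rpm Impeller speed in revolutions per minute.
#' @return Speed in 1/s.
#' @export
rpm_to_hz <- function(rpm) rpm / 60

#' Impeller Reynolds number
#'
#' \eqn{Re = \rho N D^2 / \mu}, the ratio of inertial to viscous forces for
#' a rotating impeller.
#'
#' @param fluid An [fluid_properties()] object.
#' @param speed_N Impeller speed, 1/s (use [rpm_to_hz()] at the boundary).
#' @param impeller_D Impeller diameter, m.
#' @return Dimensionless Reynolds number. Vectorised over `speed_N` and
#'   `impeller_D`.
#' @export
reynolds <- function(fluid, speed_N, impeller_D) {
  stopifnot(inherits(fluid, "nk_fluid"))
  if (any(speed_N < 0) || any(impeller_D < 0))
    stop("speed and diameter must be nonnegative", call. = FALSE)
  fluid$density * speed_N * impeller_D^2 / fluid$viscosity
}

#' Impeller tip speed
#'
#' \eqn{u_{tip} = \pi N D}, the linear velocity of the blade tip.
#'
#' @inheritParams reynolds
#' @return Tip speed, m/s.
#' @export
tip_speed <- function(speed_N, impeller_D) {
  if (any(speed_N < 0) || any(impeller_D < 0))
    stop("speed and diameter must be nonnegative", call. = FALSE)
  pi * speed_N * impeller_D
}

#' Specific power input of a stirred vessel
#'
#' \eqn{\bar\varepsilon = N_p \rho N^3 D^5 / V}, the impeller power draw per
#' unit working liquid volume.
#'
#' @inheritParams reynolds
#' @param power_number Dimensionless impeller power number \eqn{N_p}; see
#'   [power_number_for()] for the defaults by impeller type.
#' @param volume Working liquid volume, m^3.
#' @return Specific power input, W/m^3.
#' @export
specific_power <- function(power_number, fluid, speed_N, impeller_D, volume) {
  stopifnot(inherits(fluid, "nk_fluid"))
  if (any(volume <= 0)) stop("`volume` must be > 0 (m^3)", call. = FALSE)
  if (any(power_number <= 0)) stop("`power_number` must be > 0", call. = FALSE)
  if (any(speed_N < 0) || any(impeller_D < 0))
    stop("speed and diameter must be nonnegative", call. = FALSE)
  power_number * fluid$density * speed_N^3 * impeller_D^5 / volume
}

#' Power number defaults by impeller type
#'
#' 1.07 for a three-blade retreat curve (RC) impeller and 1.3 for a
#' four-blade 45-degree pitched blade turbine (PBT).
#'
#' @param impeller_type Character vector of `"RC"` / `"PBT"`.
#' @return Numeric power numbers.
#' @export
power_number_for <- function(impeller_type) {
  if (!all(impeller_type %in% c("RC", "PBT")))
    stop("`impeller_type` must be 'RC' or 'PBT'", call. = FALSE)
  ifelse(impeller_type == "RC", 1.07, 1.3)
}

# The 19 CFD feature columns, in canonical table order, with the quantile
# families used for ordering validation.
cfd_feature_names <- function() {
  c("sr_mean", "sr_q25", "sr_q50", "sr_q75",
    "ep_mean", "ep_q25", "ep_q50", "ep_q75",
    "k_mean", "k_q25", "k_q50", "k_q75",
    "U_mean", "U_q25", "U_q50", "U_q75",
    "axial_mean", "radial_mean", "power_draw")
}

cfd_quantile_families <- function() c("sr", "ep", "k", "U")

# Columns allowed to be negative (signed mean velocities).
cfd_signed_columns <- function() c("axial_mean", "radial_mean")

validate_cfd_features <- function(df) {
  miss <- setdiff(c("config_id", cfd_feature_names()), names(df))
  if (length(miss) > 0)
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unsigned <- setdiff(cfd_feature_names(), cfd_signed_columns())
  for (col in unsigned) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0)
      stop(sprintf("negative value in column '%s' (row %d: config '%s')",
                   col, bad[1], df$config_id[bad[1]]), call. = FALSE)
  }
  for (fam in cfd_quantile_families()) {
    q25 <- df[[paste0(fam, "_q25")]]
    q50 <- df[[paste0(fam, "_q50")]]
    q75 <- df[[paste0(fam, "_q75")]]
    bad <- which(q25 > q50 | q50 > q75)
    if (length(bad) > 0)
      stop(sprintf(
        "quantile ordering violated for family '%s' in row %d (config '%s'): need q25 <= q50 <= q75",
        fam, bad[1], df$config_id[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

#' Load a CFD hydrodynamic feature table
#'
#' Reads a comma-separated table holding, per vessel configuration, the 19
#' CFD-derived hydrodynamic summaries (mean and 25/50/75% quantiles of
#' shear rate, turbulent dissipation rate and turbulent kinetic energy;
#' mean and quantiles of velocity magnitude; mean axial and radial
#' velocity; power draw). Column names must match the canonical terms
#' (`sr_mean`, ..., `power_draw`) exactly. Validation enforces positivity
#' of all magnitudes (the signed mean velocities excepted) and the
#' q25 <= q50 <= q75 ordering within each quantile family.
#'
#' @param path CSV path with a `config_id` column plus the 19 feature
#'   columns.
#' @return A tibble, validated, one row per configuration.
#' @export
load_cfd_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cfd_features(df)
  tibble::as_tibble(df)
}

#' @rdname load_cfd_features
#' @param features A validated feature table (tibble or data.frame).
#' @export
write_cfd_features <- function(features, path) {
  validate_cfd_features(as.data.frame(features))
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Append classical scale-up scalars to a feature table
#'
#' Computes the impeller Reynolds number, tip speed and specific power
#' input from vessel geometry and operating conditions and appends them as
#' columns `reynolds`, `tip_speed` and `specific_power`. CFD columns are
#' never overwritten; in particular the CFD `power_draw` and the
#' geometric `specific_power` are kept as distinct fields.
#'
#' @param features Feature table with a `config_id` column.
#' @param configs A vessel-configuration table (see [load_fixtures()]) with
#'   columns `config_id`, `impeller_type`, `impeller_speed_rpm`,
#'   `impeller_diameter_mm`, `volume_ml`.
#' @param fluid An [fluid_properties()] object.
#' @return `features` with the three scalar columns appended.
#' @export
augment_features <- function(features, configs, fluid = default_fluid()) {
  stopifnot(inherits(fluid, "nk_fluid"))
  if (any(c("reynolds", "tip_speed", "specific_power") %in% names(features)))
    stop("feature table already carries derived scalar columns", call. = FALSE)
  idx <- match(features$config_id, configs$config_id)
  if (anyNA(idx))
    stop("configs table lacks rows for config(s): ",
         paste(features$config_id[is.na(idx)], collapse = ", "), call. = FALSE)
  cfg <- configs[idx, ]
  N <- rpm_to_hz(cfg$impeller_speed_rpm)
  D <- cfg$impeller_diameter_mm / 1000
  V <- cfg$volume_ml / 1e6
  features$reynolds <- reynolds(fluid, N, D)
  features$tip_speed <- tip_speed(N, D)
  features$specific_power <- specific_power(power_number_for(cfg$impeller_type),
                                            fluid, N, D, V)
  features
}
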