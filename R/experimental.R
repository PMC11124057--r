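#' Fit a UV calibration curve with LOD and LOQ
#'
#' Ordinary least squares of absorbance on concentration. Limits of detection
#' and quantification follow the 3.3/10 sigma convention: `LOD = 3.3 s /
#' slope` and `LOQ = 10 s / slope` with `s` the residual standard deviation of
#' the fit, so `LOQ / LOD = 10 / 3.3` by construction.
#'
#' @param levels Tibble with columns `conc_mg_mL` and `absorbance`, at least
#'   3 levels spanning a non-zero concentration range.
#' @return A `calibration_curve`: slope (absorbance per mg/mL), intercept,
#'   `r2`, residual SD `s`, `lod` and `loq` (mg/mL), `n_levels`, and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' lv <- gen_calibration_series(27.268, 0.001, noise = 0)
#' fit_calibration(lv)$slope
fit_calibration <- function(levels) {
  stopifnot(all(c("conc_mg_mL", "absorbance") %in% names(levels)))
  if (nrow(levels) < 3L) stop("need at least 3 calibration levels", call. = FALSE)
  if (stats::sd(levels$conc_mg_mL) == 0) {
    stop("calibration levels must span a non-zero concentration range",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ conc_mg_mL, data = levels)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  # suppressWarnings: summary.lm warns on exactly collinear (noise-free) data
  sm <- suppressWarnings(summary(fit))
  s <- sm$sigma
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r2 = sm$r.squared, s = s,
         lod = 3.3 * s / slope, loq = 10 * s / slope,
         n_levels = nrow(levels), model = fit),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.4f x C + %.4f (R2 = %.4f)\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  LOD %.5f, LOQ %.5f mg/mL (%d levels)\n",
              x$lod, x$loq, x$n_levels))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 s = x$s, lod = x$lod, loq = x$loq, n_levels = x$n_levels)
}

#' Invert a calibration curve
#'
#' @param A Absorbance reading(s).
#' @param curve A [fit_calibration()] result.
#' @param dilution Dilution factor applied before measurement.
#' @return Concentration(s) in mg/mL of the undiluted sample.
#' @export
absorbance_to_concentration <- function(A, curve, dilution = 1) {
  if (any(A < curve$intercept)) {
    stop("absorbance below the calibration intercept implies a negative ",
         "concentration", call. = FALSE)
  }
  dilution * (A - curve$intercept) / curve$slope
}

#' Convert an absorbance reading to a saturation mole fraction
#'
#' Reduces one spectrophotometric measurement of a saturated, diluted sample
#' to the solute mole fraction: the calibration curve gives the saturated
#' concentration `C` (mg per mL of saturated solution), the measured density
#' gives the total mass of 1 mL, the solvent mass is apportioned among the
#' system's components by their solute-free mole fractions, and the mole
#' fraction is `n_solute / (n_solute + n_solvent)`.
#'
#' @param A Absorbance of the diluted sample.
#' @param curve A [fit_calibration()] result.
#' @param dilution Dilution factor (>= 1).
#' @param density_g_mL Measured density of the saturated solution, g/mL.
#' @param system Solvent-system component tibble ([des_system()] /
#'   [solvent_mixture()]).
#' @param solute Solute compound id (molar mass from `registry`).
#' @param registry Compound registry with `compound_id` and `mw` columns.
#' @return A one-row tibble: `x` (mole fraction), `conc_mg_mL` (saturated
#'   concentration), `below_lod` (whether the measured concentration fell
#'   below the curve's LOD).
#' @export
absorbance_to_mole_fraction <- function(A, curve, dilution = 1, density_g_mL,
                                        system, solute,
                                        registry = compound_registry()) {
  stopifnot(length(A) == 1L, density_g_mL > 0, dilution >= 1)
  conc <- absorbance_to_concentration(A, curve, dilution)
  measured <- conc / dilution
  mw_solute <- lookup_mw(solute, registry)
  n_solute <- conc / mw_solute # mmol per mL of saturated solution
  solvent_mass <- 1000 * density_g_mL - conc # mg
  if (solvent_mass <= 0) {
    stop("solute concentration exceeds the sample mass implied by the ",
         "density; inconsistent measurement", call. = FALSE)
  }
  frac <- system$fraction / sum(system$fraction)
  mbar <- sum(frac * lookup_mw(system$component, registry))
  n_solvent <- solvent_mass / mbar
  tibble::tibble(x = n_solute / (n_solute + n_solvent),
                 conc_mg_mL = conc,
                 below_lod = measured < curve$lod)
}

#' Mean and standard deviation of replicate measurements
#'
#' @param values Numeric vector (>= 1 value).
#' @return A one-row tibble: `mean`, `sd` (sample SD, 0 for a single value),
#'   `n`.
#' @export
#' @examples
#' aggregate_replicates(c(1, 2, 3))
aggregate_replicates <- function(values) {
  if (length(values) < 1L) stop("need at least one replicate", call. = FALSE)
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) == 1L) 0 else stats::sd(values),
                 n = length(values))
}

#' Reduce raw spectrophotometric measurements to solubility records
#'
#' Converts each replicate absorbance to a mole fraction with
#' [absorbance_to_mole_fraction()] and aggregates replicates per
#' (system, temperature) into the solubility-record schema.
#'
#' @param raw Tibble with columns `sample_id`, `system_id`, `T_K`,
#'   `absorbance`, `dilution`, `density_g_mL`.
#' @param curve A [fit_calibration()] result for the solute.
#' @param systems Solvent-system component tibble covering every `system_id`.
#' @param solute Solute compound id.
#' @param registry Compound registry.
#' @return A record tibble: `record_id`, `solute`, `system_id`, `is_DES`,
#'   `T_K`, `x_exp`, `sd`, `n_replicates`.
#' @export
process_measurements <- function(raw, curve, systems, solute,
                                 registry = compound_registry()) {
  per_rep <- purrr::pmap_dfr(
    raw[, c("system_id", "T_K", "absorbance", "dilution", "density_g_mL")],
    function(system_id, T_K, absorbance, dilution, density_g_mL) {
      sys <- systems[systems$system_id == system_id, , drop = FALSE]
      if (nrow(sys) == 0L) stop("unknown system_id: ", system_id, call. = FALSE)
      res <- absorbance_to_mole_fraction(absorbance, curve, dilution,
                                         density_g_mL, sys, solute, registry)
      tibble::tibble(system_id = system_id, T_K = T_K, x = res$x,
                     is_DES = sys$is_des[1])
    })
  per_rep |>
    dplyr::group_by(.data$system_id, .data$T_K, .data$is_DES) |>
    dplyr::summarise(agg = list(aggregate_replicates(.data$x)),
                     .groups = "drop") |>
    tidyr::unnest("agg") |>
    dplyr::transmute(
      record_id = sprintf("%s_%s_%gK", solute, .data$system_id, .data$T_K),
      solute = solute, system_id = .data$system_id, is_DES = .data$is_DES,
      T_K = .data$T_K, x_exp = .data$mean, sd = .data$sd,
      n_replicates = .data$n)
}

#' Locate the optimal DES-water composition on a cosolvency curve
#'
#' The optimal composition is the measured grid point with the highest
#' solubility (no interpolation); the curve shows \emph{apparent cosolvency}
#' when that maximum strictly exceeds the neat-DES (`x_star_des = 1`) value.
#' Ties are broken toward the neat DES, so a flat series classifies as
#' `"none"` with the optimum at `x_star_des = 1`.
#'
#' @param series Tibble with columns `x_star_des` and `x_exp`, at least 3
#'   distinct compositions including the neat DES point (`x_star_des = 1`).
#' @return A one-row tibble: `x_star_opt`, `classification`
#'   (`"apparent cosolvency"` or `"none"`), `x_max`, `x_neat`.
#' @export
#' @examples
#' cosolvency_analysis(gen_cosolvency_curve(peak = 0.9, amplitude = 0.05))
cosolvency_analysis <- function(series) {
  stopifnot(all(c("x_star_des", "x_exp") %in% names(series)))
  if (anyDuplicated(series$x_star_des)) {
    stop("duplicate compositions in the cosolvency series", call. = FALSE)
  }
  if (nrow(series) < 3L) stop("need at least 3 compositions", call. = FALSE)
  if (!any(abs(series$x_star_des - 1) < 1e-12)) {
    stop("the series must include the neat DES point (x_star_des = 1)",
         call. = FALSE)
  }
  ord <- order(series$x_exp, series$x_star_des, decreasing = TRUE)
  top <- series[ord[1], ]
  neat <- series$x_exp[abs(series$x_star_des - 1) < 1e-12]
  tibble::tibble(
    x_star_opt = top$x_star_des,
    classification = if (top$x_exp > neat) "apparent cosolvency" else "none",
    x_max = top$x_exp, x_neat = neat)
}
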