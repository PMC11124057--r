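#' Fusion data constructor and reader
#'
#' Fusion (melting) data drive the ideal-solubility term of the SLE model:
#' melting temperature `Tm_K`, enthalpy of fusion `dHm_kJ_mol` and optionally
#' the heat-capacity change upon melting `dCp_kJ_molK`.
#'
#' @param compound_id Identifier.
#' @param Tm_K Melting temperature, K (> 0).
#' @param dHm_kJ_mol Enthalpy of fusion, kJ/mol (> 0).
#' @param dCp_kJ_molK Optional heat-capacity change upon melting, kJ/(mol K).
#' @return A tibble with one row per compound.
#' @export
#' @examples
#' fusion_data("IP", 348.64, 26.69)
fusion_data <- function(compound_id, Tm_K, dHm_kJ_mol, dCp_kJ_molK = NA_real_) {
  stopifnot(all(Tm_K > 0), all(dHm_kJ_mol > 0))
  tibble::tibble(compound_id = compound_id, Tm_K = Tm_K,
                 dHm_kJ_mol = dHm_kJ_mol, dCp_kJ_molK = dCp_kJ_molK)
}

#' @rdname fusion_data
#' @param path CSV with columns `compound_id,Tm_K,dHm_kJ_mol` and optionally
#'   `dCp_kJ_molK`. The package ships the literature means for ibuprofen /
#'   dexibuprofen, ketoprofen and flurbiprofen in
#'   `system.file("extdata", "fusion.csv", package = "desolv")`.
#' @export
read_fusion <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("compound_id", "Tm_K", "dHm_kJ_mol")
  if (!all(req %in% names(d))) {
    stop("fusion CSV must have columns ", paste(req, collapse = ","),
         call. = FALSE)
  }
  if (!"dCp_kJ_molK" %in% names(d)) d$dCp_kJ_molK <- NA_real_
  fusion_data(d$compound_id, d$Tm_K, d$dHm_kJ_mol, d$dCp_kJ_molK)
}

lookup_fusion <- function(fusion, compound_id) {
  row <- fusion[fusion$compound_id == compound_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("no fusion data available for solute: ", compound_id,
         " (solubility computation requires melting temperature and ",
         "enthalpy of fusion)", call. = FALSE)
  }
  row[1, ]
}

#' Ideal solubility from fusion data
#'
#' Schroeder-van Laar ideal saturation mole fraction
#' \deqn{\ln x_{id} = -\frac{\Delta H_m}{R}\Big(\frac1T - \frac1{T_m}\Big)
#'   + \frac{\Delta C_p}{R}\Big(\frac{T_m}{T} - 1 - \ln\frac{T_m}{T}\Big)}
#' with the heat-capacity term included only when `dCp_kJ_molK` is supplied.
#' Above the melting point the ideal solubility is 1.
#'
#' @param fusion One-row fusion tibble (or several rows, vectorised with `T`).
#' @param T Temperature in K (> 0).
#' @return Ideal saturation mole fraction in (0, 1].
#' @export
#' @examples
#' ideal_solubility(fusion_data("IP", 348.64, 26.69), 298.15) # ~0.21
ideal_solubility <- function(fusion, T) {
  if (any(T <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  lnx <- -(fusion$dHm_kJ_mol * 1000 / GAS_CONSTANT) * (1 / T - 1 / fusion$Tm_K)
  dcp <- fusion$dCp_kJ_molK
  has_cp <- !is.na(dcp)
  if (any(has_cp)) {
    corr <- (dcp * 1000 / GAS_CONSTANT) *
      (fusion$Tm_K / T - 1 - log(fusion$Tm_K / T))
    lnx[has_cp] <- lnx[has_cp] + corr[has_cp]
  }
  pmin(exp(lnx), 1)
}

#' Activity-coefficient models for SLE solving
#'
#' `activity_ideal()` returns the ideal model (gamma = 1); `activity_constant()`
#' a composition-independent coefficient; `activity_cosmors()` the COSMO-RS
#' style model in which the solute's activity coefficient at mole fraction `x`
#' is obtained from the residual (sigma-potential) chemical potential of the
#' solute in the saturated mixture relative to the pure solute liquid:
#' \eqn{\ln\gamma = [\mu^{mix}_{solute} - \mu^{pure}_{solute}] / RT}
#' with per-area potentials integrated over the solute's sigma-profile (the
#' combinatorial contribution is neglected).
#'
#' All three return a function `gamma(x, T)` suitable for [solve_sle()].
#'
#' @param value Constant activity coefficient (> 0).
#' @param solute_id Solute compound id.
#' @param system Solvent-system component tibble ([des_system()] /
#'   [solvent_mixture()]).
#' @param profiles Long sigma-profile tibble covering solute and components.
#' @param constants A [cosmo_constants()] list.
#' @return A function `(x, T) -> gamma`.
#' @export
activity_ideal <- function() function(x, T) rep(1, length(x))

#' @rdname activity_ideal
#' @export
activity_constant <- function(value) {
  stopifnot(value > 0)
  function(x, T) rep(value, length(x))
}

#' @rdname activity_ideal
#' @export
activity_cosmors <- function(solute_id, system, profiles,
                             constants = cosmo_constants()) {
  a_solute <- profile_areas(profiles, solute_id)
  comp_ids <- system$component
  frac <- system$fraction / sum(system$fraction)
  sub <- profiles[profiles$compound_id %in% c(solute_id, comp_ids), ]
  pure_cache <- new.env(parent = emptyenv())

  function(x, T) {
    key <- format(T, digits = 12)
    if (is.null(pure_cache[[key]])) {
      pure <- sigma_potential(profiles[profiles$compound_id == solute_id, ],
                              T = T, constants = constants)
      pure_cache[[key]] <- sum(a_solute * pure$mu)
    }
    mu_pure <- pure_cache[[key]]
    RT <- GAS_CONSTANT * T / 1000
    vapply(x, function(xi) {
      w <- c(xi, (1 - xi) * frac)
      names(w) <- c(solute_id, comp_ids)
      # merge duplicated ids (solute also a solvent component)
      w <- tapply(w, names(w), sum)
      mix <- sigma_potential(sub, mole_fractions = w / sum(w), T = T,
                             constants = constants)
      exp((sum(a_solute * mix$mu) - mu_pure) / RT)
    }, numeric(1))
  }
}

#' Solve the solid-liquid equilibrium for the saturation mole fraction
#'
#' Finds the saturation mole fraction `x_sat` satisfying
#' \eqn{\ln(x\,\gamma(x, T)) = \ln x_{id}(T)} by a bracketed root solve in
#' `ln x` on (0, 1] — a full solve rather than successive substitution, which
#' oscillates or diverges for highly soluble cases.
#'
#' @param fusion One-row fusion tibble for the solute.
#' @param activity A `gamma(x, T)` function (see [activity_ideal()]).
#' @param T Temperature in K.
#' @param tol Absolute tolerance on the root in `ln x`.
#' @return A one-row tibble: `x_sat`, `gamma_at_sat`, `converged`, `residual`.
#'   When the SLE residual has no sign change on the bracket the result is
#'   flagged `converged = FALSE` with diagnostic residual.
#' @export
#' @examples
#' fu <- fusion_data("IP", 348.64, 26.69)
#' solve_sle(fu, activity_constant(2), 298.15)$x_sat
solve_sle <- function(fusion, activity, T, tol = 1e-12) {
  x_id <- ideal_solubility(fusion, T)
  f <- function(lx) lx + log(activity(exp(lx), T)) - log(x_id)
  lo <- log(1e-12)
  hi <- 0
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi)) {
    stop("activity model returned non-finite gamma on (0, 1]", call. = FALSE)
  }
  if (abs(fhi) < 1e-12) {
    return(tibble::tibble(x_sat = 1, gamma_at_sat = activity(1, T),
                          converged = TRUE, residual = fhi))
  }
  if (flo * fhi > 0) {
    return(tibble::tibble(x_sat = NA_real_, gamma_at_sat = NA_real_,
                          converged = FALSE, residual = min(abs(flo), abs(fhi))))
  }
  root <- stats::uniroot(f, c(lo, hi), tol = tol)
  x_sat <- exp(root$root)
  tibble::tibble(x_sat = x_sat, gamma_at_sat = activity(x_sat, T),
                 converged = TRUE, residual = f(root$root))
}
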