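dmu_colnames <- function(grid = sigma_grid()) sprintf("dmu_%0.3f", grid)

#' Relative sigma-potentials for a set of solubility records
#'
#' Computes, for every distinct (solute, system, temperature) combination in
#' `records`, the relative sigma-potential (pure-solute potential minus
#' solute-free-mole-fraction-weighted solvent potential) on the canonical
#' grid.
#'
#' @param records Solubility record tibble with columns `solute`, `system_id`,
#'   `T_K` (other columns are ignored).
#' @param systems Solvent-system component tibble covering every `system_id`.
#' @param profiles Long sigma-profile tibble covering solutes and components.
#' @param constants A [cosmo_constants()] list.
#' @param mixture_method Passed to [mixture_potential()].
#' @return A wide tibble keyed by `solute`, `system_id`, `T_K` with one
#'   `dmu_*` column per grid point (kJ/(mol A^2)).
#' @export
compute_relative_potentials <- function(records, systems, profiles,
                                        constants = cosmo_constants(),
                                        mixture_method = "potential") {
  combos <- dplyr::distinct(records, .data$solute, .data$system_id, .data$T_K)
  pure_cache <- new.env(parent = emptyenv())
  mix_cache <- new.env(parent = emptyenv())

  pure_pot <- function(id, T) {
    key <- paste(id, format(T, digits = 12))
    if (is.null(pure_cache[[key]])) {
      pure_cache[[key]] <- sigma_potential(
        profiles[profiles$compound_id == id, ], T = T, constants = constants)
    }
    pure_cache[[key]]
  }
  mix_pot <- function(sid, T) {
    key <- paste(sid, format(T, digits = 12))
    if (is.null(mix_cache[[key]])) {
      sys <- systems[systems$system_id == sid, , drop = FALSE]
      if (nrow(sys) == 0L) stop("unknown system_id: ", sid, call. = FALSE)
      mix_cache[[key]] <- mixture_potential(sys, profiles, T = T,
                                            constants = constants,
                                            method = mixture_method)
    }
    mix_cache[[key]]
  }

  dmu <- purrr::pmap(combos, function(solute, system_id, T_K) {
    rel <- relative_potential(pure_pot(solute, T_K), mix_pot(system_id, T_K))
    stats::setNames(rel$delta_mu, dmu_colnames())
  })
  dplyr::bind_cols(combos, dplyr::bind_rows(dmu))
}

#' Per-sigma R-squared profile of solubility against relative potentials
#'
#' For every grid point, the coefficient of determination of a univariate
#' ordinary-least-squares regression of decadal-log experimental solubility on
#' the relative sigma-potential at that point, within one subset (DES or
#' non-DES systems).
#'
#' @param records Record tibble with `solute`, `system_id`, `T_K`, `is_DES`
#'   (logical) and `x_exp` (> 0).
#' @param relpots Relative-potential store from
#'   [compute_relative_potentials()].
#' @param subset `"DES"` or `"nonDES"`.
#' @param log10_response Regress on `log10(x_exp)` (default) or on the linear
#'   scale.
#' @return A tibble with columns `sigma` and `r2`; a constant predictor at a
#'   sigma point yields `r2 = 0`.
#' @export
r2_profile <- function(records, relpots, subset = c("nonDES", "DES"),
                       log10_response = TRUE) {
  subset <- match.arg(subset)
  rec <- records[records$is_DES == (subset == "DES"), , drop = FALSE]
  if (nrow(rec) < 3L) {
    stop("need at least 3 records in the ", subset, " subset", call. = FALSE)
  }
  dat <- dplyr::inner_join(rec, relpots, by = c("solute", "system_id", "T_K"))
  if (nrow(dat) != nrow(rec)) {
    stop("relative potentials missing for some records", call. = FALSE)
  }
  y <- if (log10_response) log10(dat$x_exp) else dat$x_exp
  if (any(!is.finite(y))) stop("x_exp must be positive and finite", call. = FALSE)
  X <- as.matrix(dat[, dmu_colnames(), drop = FALSE])
  r2 <- apply(X, 2, function(x) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)^2
  })
  tibble::tibble(sigma = sigma_grid(), r2 = unname(r2))
}

#' Select informative sigma points by the two-subset R-squared rule
#'
#' A grid point is retained when its R-squared with experimental solubility
#' strictly exceeds the threshold in \emph{either} the non-DES or the DES
#' subset.
#'
#' @param r2_nondes,r2_des R-squared profiles from [r2_profile()].
#' @param threshold Selection threshold (default 0.4, strict inequality).
#' @return An object of class `sigma_selection`: a list with the per-sigma
#'   report tibble (`sigma`, `r2_nonDES`, `r2_DES`, `selected`), the
#'   `threshold` and the `selected_indices` (grid positions).
#' @export
select_sigma_points <- function(r2_nondes, r2_des, threshold = 0.4) {
  stopifnot(nrow(r2_nondes) == 61L, nrow(r2_des) == 61L)
  report <- tibble::tibble(
    sigma = sigma_grid(),
    r2_nonDES = r2_nondes$r2,
    r2_DES = r2_des$r2,
    selected = r2_nondes$r2 > threshold | r2_des$r2 > threshold
  )
  structure(
    list(report = report, threshold = threshold,
         selected_indices = which(report$selected)),
    class = "sigma_selection"
  )
}

#' @export
print.sigma_selection <- function(x, ...) {
  cat("<sigma_selection> threshold R2 >", x$threshold, "\n")
  cat("  ", length(x$selected_indices), "of 61 sigma points selected\n")
  if (length(x$selected_indices) > 0) {
    sel <- x$report$sigma[x$selected_indices]
    cat("  sigma range:", min(sel), "to", max(sel), "e/A^2\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sigma_selection <- function(x, ...) x$report

#' @export
glance.sigma_selection <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 n_selected = length(x$selected_indices),
                 max_r2_nonDES = max(x$report$r2_nonDES),
                 max_r2_DES = max(x$report$r2_DES))
}

#' Write / read a selection report as CSV
#'
#' @param selection A `sigma_selection` object.
#' @param path CSV path (`sigma,r2_nonDES,r2_DES,selected`).
#' @return `write_selection()` returns `path` invisibly; `read_selection()`
#'   the reconstructed `sigma_selection`.
#' @export
write_selection <- function(selection, path) {
  readr::write_csv(selection$report, path)
  invisible(path)
}

#' @rdname write_selection
#' @param threshold Threshold recorded with the reloaded report.
#' @export
read_selection <- function(path, threshold = 0.4) {
  rep <- readr::read_csv(path, show_col_types = FALSE)
  structure(list(report = rep, threshold = threshold,
                 selected_indices = which(rep$selected)),
            class = "sigma_selection")
}

#' Assemble the per-record descriptor table
#'
#' One row per solubility record: the decadal log of the SLE-computed
#' solubility as the first descriptor, the relative sigma-potential values at
#' the selected grid points, and the temperature.
#'
#' @param records Record tibble (`record_id`, `solute`, `system_id`, `T_K`,
#'   ...).
#' @param systems Solvent-system component tibble.
#' @param profiles Long sigma-profile tibble.
#' @param fusion Fusion tibble covering every solute (error names the solute
#'   otherwise).
#' @param selection A `sigma_selection`; `NULL` keeps no sigma features.
#' @param activity_model `"cosmors"` or `"ideal"` activity for the SLE solve.
#' @param constants A [cosmo_constants()] list.
#' @param relpots Optional precomputed store from
#'   [compute_relative_potentials()] (computed when `NULL`).
#' @param mixture_method Passed to [compute_relative_potentials()].
#' @return A tibble: `record_id`, `log10_x_computed`, selected `dmu_*`
#'   columns in grid order, `T_K`.
#' @export
build_feature_table <- function(records, systems, profiles, fusion,
                                selection = NULL,
                                activity_model = c("cosmors", "ideal"),
                                constants = cosmo_constants(),
                                relpots = NULL,
                                mixture_method = "potential") {
  activity_model <- match.arg(activity_model)
  for (s in unique(records$solute)) lookup_fusion(fusion, s)
  if (is.null(relpots)) {
    relpots <- compute_relative_potentials(records, systems, profiles,
                                           constants, mixture_method)
  }

  combos <- dplyr::distinct(records, .data$solute, .data$system_id, .data$T_K)
  combos$log10_x_computed <- purrr::pmap_dbl(
    combos,
    function(solute, system_id, T_K) {
      fu <- lookup_fusion(fusion, solute)
      act <- if (activity_model == "ideal") {
        activity_ideal()
      } else {
        sys <- systems[systems$system_id == system_id, , drop = FALSE]
        activity_cosmors(solute, sys, profiles, constants)
      }
      res <- solve_sle(fu, act, T_K)
      if (!res$converged) {
        stop("SLE solve failed for solute ", solute, " in system ", system_id,
             " at ", T_K, " K", call. = FALSE)
      }
      log10(res$x_sat)
    })

  sel_cols <- if (is.null(selection)) character(0) else
    dmu_colnames()[selection$selected_indices]
  keep <- c("solute", "system_id", "T_K", sel_cols)
  feat <- dplyr::inner_join(combos, relpots[, keep, drop = FALSE],
                            by = c("solute", "system_id", "T_K"))
  out <- dplyr::inner_join(
    records[, c("record_id", "solute", "system_id", "T_K")],
    feat, by = c("solute", "system_id", "T_K"))
  out <- out[, c("record_id", "log10_x_computed", sel_cols, "T_K")]
  stopifnot(!anyNA(out))
  out
}
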