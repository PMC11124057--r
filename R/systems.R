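parse_ratio <- function(ratio) {
  if (is.numeric(ratio)) return(as.numeric(ratio))
  parts <- strsplit(as.character(ratio), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("ratio must look like '1:2'", call. = FALSE)
  a <- as.numeric(parts[1]); b <- as.numeric(parts[2])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("ratio components must be positive", call. = FALSE)
  }
  b / a
}

#' Build a DES(-water) solvent system
#'
#' A deep eutectic solvent is an HBA (choline chloride or betaine, treated as
#' one component) combined with a polyol HBD at a molar ratio `1:k`; within
#' the DES the components have mole fractions `1/(1+k)` and `k/(1+k)`. Water
#' enters through the solute-free DES mole fraction `x_star_des` of the
#' aqueous mixture; all solute-free component fractions are renormalised to
#' sum to 1.
#'
#' @param hba,hbd Component identifiers (must have sigma-profiles and molar
#'   masses available for downstream use).
#' @param ratio HBA:HBD molar ratio as a string (`"1:2"`) or the numeric `k`.
#' @param x_star_des Solute-free DES mole fraction in the aqueous mixture,
#'   in (0, 1]; 1 means neat DES.
#' @param system_id Identifier; a descriptive one is generated by default.
#' @return A tibble with one row per component: `system_id`, `component`,
#'   `fraction` (solute-free mole fraction), `is_des`, `x_star_des`.
#' @export
#' @examples
#' des_system("ChCl", "TEG", "1:2", x_star_des = 0.9)
des_system <- function(hba, hbd, ratio = "1:2", x_star_des = 1,
                       system_id = NULL) {
  k <- parse_ratio(ratio)
  stopifnot(x_star_des > 0, x_star_des <= 1)
  if (is.null(system_id)) {
    system_id <- sprintf("%s-%s_1to%g_x%0.2f", hba, hbd, k, x_star_des)
  }
  comp <- c(hba, hbd)
  frac <- c(1 / (1 + k), k / (1 + k)) * x_star_des
  if (x_star_des < 1) {
    comp <- c(comp, "water")
    frac <- c(frac, 1 - x_star_des)
  }
  frac <- frac / sum(frac)
  tibble::tibble(system_id = system_id, component = comp, fraction = frac,
                 is_des = TRUE, x_star_des = x_star_des)
}

#' Build a conventional (non-DES) solvent system
#'
#' Neat solvents and binary mixtures of conventional solvents are non-DES
#' systems.
#'
#' @param components Character vector of component identifiers.
#' @param fractions Solute-free mole fractions (renormalised to sum to 1).
#' @param system_id Identifier; defaults to the component ids joined by `+`.
#' @return A component tibble in the same schema as [des_system()]
#'   (`x_star_des` is `NA` for non-DES systems).
#' @export
#' @examples
#' solvent_mixture("water")
#' solvent_mixture(c("water", "methanol"), c(0.5, 0.5))
solvent_mixture <- function(components, fractions = rep(1, length(components)),
                            system_id = NULL) {
  stopifnot(length(components) == length(fractions), all(fractions > 0))
  if (is.null(system_id)) system_id <- paste(components, collapse = "+")
  tibble::tibble(system_id = system_id, component = components,
                 fraction = fractions / sum(fractions),
                 is_des = FALSE, x_star_des = NA_real_)
}

#' Enumerate the DES screening grid
#'
#' Full Cartesian product of HBAs, HBDs and molar ratios (deduplicated); the
#' study grid of 2 acceptors x 6 donors x 3 ratios gives 36 systems.
#'
#' @param hba,hbd Character vectors of acceptor / donor identifiers.
#' @param ratios Character or numeric vector of HBA:HBD ratios.
#' @return A tibble with columns `hba`, `hbd`, `ratio`, `system_id`, one row
#'   per distinct system.
#' @export
#' @examples
#' nrow(enumerate_des_grid())
enumerate_des_grid <- function(hba = c("ChCl", "BI"),
                               hbd = c("ETG", "DEG", "TEG", "GLY", "P2D", "B3D"),
                               ratios = c("1:1", "1:2", "1:4")) {
  stopifnot(length(hba) > 0, length(hbd) > 0, length(ratios) > 0)
  grid <- tidyr::expand_grid(hba = unique(hba), hbd = unique(hbd),
                             ratio = unique(as.character(ratios)))
  dplyr::mutate(grid,
                system_id = sprintf("%s-%s_%s", .data$hba, .data$hbd,
                                    gsub(":", "to", .data$ratio)))
}
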