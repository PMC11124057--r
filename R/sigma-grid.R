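#' The canonical sigma grid
#'
#' Screening-charge-density grid on which all sigma-profiles and
#' sigma-potentials are defined: 61 points for sigma between -0.03 and
#' +0.03 e/A^2 with a 0.001 step.
#'
#' @return Numeric vector of 61 strictly increasing sigma values (e/A^2).
#' @export
#' @examples
#' length(sigma_grid())
#' range(sigma_grid())
sigma_grid <- function() {
  round(seq(-0.030, 0.030, by = 0.001), 3)
}

SIGMA_STEP <- 0.001

#' Construct a sigma-profile
#'
#' A sigma-profile is the histogram of a molecule's COSMO screening-charge
#' density over its surface: surface area (A^2) per sigma bin on the
#' canonical grid.
#'
#' @param compound_id Identifier of the compound.
#' @param areas Numeric vector of per-bin surface areas (A^2), one per grid
#'   point, all non-negative.
#' @param grid Sigma grid the areas are defined on; must equal [sigma_grid()].
#' @return A tibble with columns `compound_id`, `sigma`, `area`.
#' @export
#' @examples
#' pr <- sigma_profile("toy", dnorm(sigma_grid(), 0, 0.005))
#' sum(pr$area)
sigma_profile <- function(compound_id, areas, grid = sigma_grid()) {
  check_grid(grid)
  if (length(areas) != length(grid)) {
    stop("`areas` must have one value per grid point (",
         length(grid), "), got ", length(areas), call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("sigma-profile areas must be finite and non-negative", call. = FALSE)
  }
  if (sum(areas) <= 0) {
    stop("sigma-profile has zero total surface area", call. = FALSE)
  }
  tibble::tibble(compound_id = compound_id, sigma = grid, area = as.numeric(areas))
}

check_grid <- function(grid, tol = 1e-9) {
  ref <- round(seq(-0.030, 0.030, by = 0.001), 3)
  if (length(grid) != length(ref) || any(abs(grid - ref) > tol)) {
    stop("sigma grid must be the canonical 61-point grid from -0.03 to +0.03 ",
         "at step 0.001 e/A^2", call. = FALSE)
  }
  invisible(grid)
}

# Extract the area vector of one compound from a long profile table,
# aligned to the canonical grid.
profile_areas <- function(profiles, compound_id) {
  sub <- profiles[profiles$compound_id == compound_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no sigma-profile found for compound: ", compound_id, call. = FALSE)
  }
  sub <- sub[order(sub$sigma), , drop = FALSE]
  check_grid(sub$sigma)
  sub$area
}

#' Read sigma-profiles from CSV files
#'
#' Each file holds one compound's profile with columns `sigma` (e/A^2) and
#' `area` (A^2); the grid is validated against the canonical 61-point grid on
#' load. The compound id is taken from the file name (without extension)
#' unless the file has a `compound_id` column.
#'
#' @param paths Character vector of CSV paths, or a single directory whose
#'   `*.csv` files are all read.
#' @return A long tibble with columns `compound_id`, `sigma`, `area`.
#' @export
read_sigma_profiles <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no sigma-profile CSV files found", call. = FALSE)
  purrr::map_dfr(paths, function(p) {
    d <- readr::read_csv(p, show_col_types = FALSE)
    if (!all(c("sigma", "area") %in% names(d))) {
      stop("sigma-profile file ", p, " must have columns sigma,area", call. = FALSE)
    }
    id <- if ("compound_id" %in% names(d)) d$compound_id[1] else
      tools::file_path_sans_ext(basename(p))
    sigma_profile(id, d$area[order(d$sigma)])
  })
}

#' Write sigma-profiles to per-compound CSV files
#'
#' @param profiles Long profile tibble (`compound_id`, `sigma`, `area`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sigma_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(profiles$compound_id)
  paths <- vapply(ids, function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    sub <- profiles[profiles$compound_id == id, c("sigma", "area")]
    readr::write_csv(sub, p)
    p
  }, character(1))
  invisible(paths)
}
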