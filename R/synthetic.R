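#' Synthetic-data generator configuration
#'
#' Controls the emulation of the study's (on-request) dataset: sigma-profiles
#' of apolar solutes, HBA salts, polyol donors and water; fusion data; DES and
#' conventional solvent-system grids; a ground-truth solubility surface that
#' is a known function of the relative sigma-potential descriptors plus ideal
#' solubility; and heteroscedastic measurement noise.
#'
#' @param seed Master integer seed; every generator is a pure function of it.
#' @param n_solutes Number of synthetic solutes.
#' @param n_solvents Number of DES constituents (2 HBAs plus polyol HBDs);
#'   three conventional solvents and water are always added.
#' @param n_records Number of solubility records drawn from the full
#'   (solute, system, temperature) grid.
#' @param noise_sd_dex Measurement noise SD on decadal-log solubility (0.1 dex
#'   is typical inter-laboratory scatter).
#' @param planted_sigma_indices Grid indices (1--61) carrying true signal.
#' @param effect_sizes Effect, in dex per SD of the relative potential, of
#'   each planted index.
#' @param quad_effect Coefficient of the mild quadratic term in the first
#'   planted index (dex per SD^2).
#' @param cosolvency_peak Default peak composition for
#'   [gen_cosolvency_curve()].
#' @param calib_noise_sd Default absorbance noise for
#'   [gen_calibration_series()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1, n_solutes = 6, n_solvents = 6,
                             n_records = 600, noise_sd_dex = 0.1,
                             planted_sigma_indices = c(16L, 31L, 46L),
                             effect_sizes = c(0.7, 0.5, 0.4),
                             quad_effect = 0.15,
                             cosolvency_peak = 0.9,
                             calib_noise_sd = 0.005) {
  stopifnot(noise_sd_dex >= 0, calib_noise_sd >= 0,
            all(planted_sigma_indices >= 1), all(planted_sigma_indices <= 61),
            length(effect_sizes) == length(planted_sigma_indices),
            n_solutes >= 2, n_solvents >= 4)
  structure(list(seed = as.integer(seed), n_solutes = n_solutes,
                 n_solvents = n_solvents, n_records = n_records,
                 noise_sd_dex = noise_sd_dex,
                 planted_sigma_indices = as.integer(planted_sigma_indices),
                 effect_sizes = effect_sizes, quad_effect = quad_effect,
                 cosolvency_peak = cosolvency_peak,
                 calib_noise_sd = calib_noise_sd),
            class = "generator_config")
}

gaussian_mix_profile <- function(centers, widths, weights, total_area) {
  grid <- sigma_grid()
  dens <- Reduce(`+`, Map(function(c, s, w) w * stats::dnorm(grid, c, s),
                          centers, widths, weights))
  total_area * dens / sum(dens)
}

#' Generate synthetic sigma-profiles
#'
#' Mixture-of-Gaussians surface-area distributions on the canonical grid,
#' with archetypes for apolar drug-like solutes (most area near sigma = 0),
#' HBA salts (strong positive-sigma anion surface), polyol donors (donor
#' hydrogens at negative sigma plus acceptor oxygens at positive sigma),
#' moderately polar conventional solvents, and water. Total areas fall in a
#' realistic 100--400 A^2 range.
#'
#' @param config A [generator_config()].
#' @return A long profile tibble (`compound_id`, `sigma`, `area`) with
#'   solutes `sol01..`, acceptors `hbaA`/`hbaB`, donors `hbd01..`,
#'   conventional solvents `conv1..conv3` and `water`.
#' @export
gen_sigma_profiles <- function(config = generator_config()) {
  n_hbd <- max(2L, config$n_solvents - 2L)
  withr::with_seed(config$seed + 1L, {
    out <- list()
    for (i in seq_len(config$n_solutes)) {
      shoulder <- stats::runif(1, 0.04, 0.09)
      out[[length(out) + 1L]] <- sigma_profile(
        sprintf("sol%02d", i),
        gaussian_mix_profile(
          centers = c(stats::rnorm(1, 0, 0.0006), -0.013, 0.014),
          widths = c(stats::runif(1, 0.0015, 0.0022), 0.002, 0.002),
          weights = c(1 - 2 * shoulder, shoulder, shoulder),
          total_area = stats::runif(1, 250, 350)))
    }
    for (id in c("hbaA", "hbaB")) {
      out[[length(out) + 1L]] <- sigma_profile(
        id,
        gaussian_mix_profile(
          centers = c(0, stats::runif(1, 0.014, 0.018), -0.010),
          widths = c(0.003, 0.0025, 0.002),
          weights = c(0.5, stats::runif(1, 0.25, 0.35), 0.15),
          total_area = stats::runif(1, 180, 280)))
    }
    for (i in seq_len(n_hbd)) {
      out[[length(out) + 1L]] <- sigma_profile(
        sprintf("hbd%02d", i),
        gaussian_mix_profile(
          centers = c(0, stats::runif(1, -0.016, -0.012),
                      stats::runif(1, 0.010, 0.014)),
          widths = c(0.0025, 0.002, 0.002),
          weights = c(0.5, stats::runif(1, 0.25, 0.35), 0.2),
          total_area = stats::runif(1, 150, 250)))
    }
    for (i in 1:3) {
      out[[length(out) + 1L]] <- sigma_profile(
        sprintf("conv%d", i),
        gaussian_mix_profile(
          centers = c(stats::rnorm(1, 0, 0.001), -0.012, 0.012),
          widths = c(0.002, 0.002, 0.002),
          weights = c(0.7, stats::runif(1, 0.1, 0.2), stats::runif(1, 0.1, 0.2)),
          total_area = stats::runif(1, 120, 200)))
    }
    out[[length(out) + 1L]] <- sigma_profile(
      "water",
      gaussian_mix_profile(centers = c(0, -0.015, 0.015),
                           widths = c(0.003, 0.0022, 0.0022),
                           weights = c(0.35, 0.32, 0.33),
                           total_area = 110))
    dplyr::bind_rows(out)
  })
}

#' Generate synthetic fusion data
#'
#' @param config A [generator_config()].
#' @return A fusion tibble for the synthetic solutes, with melting points in
#'   330--430 K and fusion enthalpies in 18--32 kJ/mol.
#' @export
gen_fusion <- function(config = generator_config()) {
  withr::with_seed(config$seed + 2L, {
    fusion_data(sprintf("sol%02d", seq_len(config$n_solutes)),
                Tm_K = stats::runif(config$n_solutes, 330, 430),
                dHm_kJ_mol = stats::runif(config$n_solutes, 18, 32))
  })
}

#' Generate the synthetic solvent-system grid
#'
#' DES systems (HBA x HBD at ratio 1:2 across a DES-water composition sweep
#' including the neat DES) plus non-DES systems: neat conventional solvents,
#' neat water and water/conventional binary mixtures.
#'
#' @param config A [generator_config()].
#' @return A solvent-system component tibble covering all systems.
#' @export
gen_systems <- function(config = generator_config()) {
  n_hbd <- max(2L, config$n_solvents - 2L)
  des <- tidyr::expand_grid(
    hba = c("hbaA", "hbaB"),
    hbd = sprintf("hbd%02d", seq_len(n_hbd)),
    x_star = c(1, 0.9, 0.8, 0.6, 0.4, 0.2))
  des_tbl <- purrr::pmap_dfr(des, function(hba, hbd, x_star) {
    des_system(hba, hbd, "1:2", x_star_des = x_star)
  })
  non_des <- dplyr::bind_rows(
    purrr::map_dfr(sprintf("conv%d", 1:3), solvent_mixture),
    solvent_mixture("water"),
    purrr::map_dfr(sprintf("conv%d", 1:3), function(cv) {
      purrr::map_dfr(c(0.25, 0.5, 0.75), function(f) {
        solvent_mixture(c("water", cv), c(1 - f, f),
                        system_id = sprintf("water+%s_f%0.2f", cv, f))
      })
    }))
  dplyr::bind_rows(des_tbl, non_des)
}

#' Generate a synthetic solubility dataset with known ground truth
#'
#' Draws records from the (solute, system, temperature) grid and builds
#' decadal-log solubility as ideal solubility plus planted linear effects of
#' the relative sigma-potential at the configured grid indices, a mild
#' quadratic term in the first planted index, and Gaussian noise:
#' \deqn{\log_{10} x = \log_{10} x_{id} + \sum_i \beta_i z_i + q (z_1^2 - 1)
#'   + \varepsilon}
#' where `z_i` are the planted relative potentials standardised over the
#' dataset. With all effects zero the surface reduces to the ideal
#' solubility.
#'
#' @param config A [generator_config()].
#' @param profiles,fusion Optional pre-generated inputs (regenerated from
#'   `config` when `NULL`).
#' @return A list: `records` (record tibble with `x_exp`), `truth`
#'   (per-record noiseless `log10_x_true` and components), `relpots`,
#'   `profiles`, `fusion`, `systems`.
#' @export
gen_solubility_dataset <- function(config = generator_config(),
                                   profiles = NULL, fusion = NULL) {
  if (is.null(profiles)) profiles <- gen_sigma_profiles(config)
  if (is.null(fusion)) fusion <- gen_fusion(config)
  systems <- gen_systems(config)

  grid <- tidyr::expand_grid(
    solute = fusion$compound_id,
    system_id = unique(systems$system_id),
    T_K = c(298.15, 308.15, 318.15))
  n <- min(config$n_records, nrow(grid))
  rows <- withr::with_seed(config$seed + 3L, sample.int(nrow(grid), n))
  rec <- grid[sort(rows), ]

  relpots <- compute_relative_potentials(rec, systems, profiles)
  rec <- dplyr::left_join(
    rec,
    dplyr::distinct(systems[, c("system_id", "is_des")]) |>
      dplyr::rename(is_DES = "is_des"),
    by = "system_id")

  log10_x_ideal <- purrr::pmap_dbl(rec[, c("solute", "T_K")],
    function(solute, T_K) {
      log10(ideal_solubility(lookup_fusion(fusion, solute), T_K))
    })

  dm <- dplyr::inner_join(rec, relpots, by = c("solute", "system_id", "T_K"))
  Z <- as.matrix(dm[, dmu_colnames()[config$planted_sigma_indices],
                    drop = FALSE])
  Z <- scale(Z)
  signal <- as.vector(Z %*% config$effect_sizes) +
    config$quad_effect * (Z[, 1]^2 - 1)
  truth <- log10_x_ideal + signal
  shift <- max(0, max(truth) + 0.05)
  truth <- truth - shift

  eps <- withr::with_seed(config$seed + 4L,
                          stats::rnorm(n, 0, config$noise_sd_dex))
  log10_x_obs <- pmin(truth + eps, 0)
  x_exp <- 10^log10_x_obs

  records <- tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    solute = rec$solute, system_id = rec$system_id, is_DES = rec$is_DES,
    T_K = rec$T_K, x_exp = x_exp,
    sd = x_exp * log(10) * config$noise_sd_dex, n_replicates = 3L)
  truth_tbl <- tibble::tibble(
    record_id = records$record_id, log10_x_true = truth,
    log10_x_ideal = log10_x_ideal, signal = signal, shift = shift)
  list(records = records, truth = truth_tbl, relpots = relpots,
       profiles = profiles, fusion = fusion, systems = systems)
}

#' Generate an independent-noise fixture for sigma-point selection
#'
#' Builds a relative-potential store whose non-planted grid points are pure
#' independent noise while the planted points share a latent component with
#' the response, giving each planted point a marginal R-squared near
#' `effect_r2` in both the DES and non-DES subsets — the setting in which
#' exact recovery of the planted indices is a well-posed property.
#'
#' @param n Number of records (half DES, half non-DES).
#' @param planted Grid indices carrying signal.
#' @param effect_r2 Target marginal R-squared of each planted point.
#' @param seed Integer seed.
#' @param scale SD of the relative-potential values (kJ/(mol A^2)).
#' @return A list: `records`, `relpots`, `planted`.
#' @export
gen_selection_fixture <- function(n = 200, planted = c(16L, 31L, 46L),
                                  effect_r2 = 0.8, seed = 1, scale = 0.05) {
  stopifnot(n >= 10, effect_r2 > 0, effect_r2 < 1)
  withr::with_seed(seed, {
    delta2 <- 0.05
    tau2 <- 1 / (effect_r2 * (1 + delta2)) - 1
    u <- stats::rnorm(n)
    y_std <- u + sqrt(tau2) * stats::rnorm(n)
    M <- matrix(stats::rnorm(n * 61, 0, scale), n, 61,
                dimnames = list(NULL, dmu_colnames()))
    for (j in planted) {
      M[, j] <- scale * (u + sqrt(delta2) * stats::rnorm(n)) / sqrt(1 + delta2)
    }
    log10_x <- pmin(-2.5 + 0.6 * y_std, -0.01)
    records <- tibble::tibble(
      record_id = sprintf("f%04d", seq_len(n)),
      solute = sprintf("s%04d", seq_len(n)),
      system_id = sprintf("sys%04d", seq_len(n)),
      is_DES = seq_len(n) <= n / 2,
      T_K = 298.15, x_exp = 10^log10_x, sd = 0, n_replicates = 1L)
    relpots <- dplyr::bind_cols(
      records[, c("solute", "system_id", "T_K")],
      tibble::as_tibble(M))
    list(records = records, relpots = relpots, planted = as.integer(planted))
  })
}

#' Generate a synthetic UV calibration series
#'
#' Concentrations spanning a stated range with absorbances from a straight
#' line plus Gaussian noise (defaults mirror the ibuprofen curve: 11 levels
#' from 0.0126 to 0.0504 mg/mL).
#'
#' @param slope,intercept Line parameters (absorbance per mg/mL; absorbance).
#' @param noise Gaussian absorbance noise SD.
#' @param n_levels Number of concentration levels (>= 3).
#' @param conc_range Concentration range, mg/mL.
#' @param seed Integer seed.
#' @return A tibble: `conc_mg_mL`, `absorbance`.
#' @export
gen_calibration_series <- function(slope = 27.268, intercept = 0.001,
                                   noise = 0, n_levels = 11,
                                   conc_range = c(0.0126, 0.0504), seed = 1) {
  stopifnot(n_levels >= 3)
  conc <- seq(conc_range[1], conc_range[2], length.out = n_levels)
  eps <- withr::with_seed(seed, stats::rnorm(n_levels, 0, noise))
  tibble::tibble(conc_mg_mL = conc, absorbance = slope * conc + intercept + eps)
}

#' Generate a synthetic cosolvency curve
#'
#' A unimodal DES-water solubility series whose maximum sits at the requested
#' grid point and exceeds the neat-DES value by `amplitude` (for `peak < 1`);
#' `amplitude = 0` gives a flat (or monotone, for `peak = 1`) curve with no
#' apparent cosolvency.
#'
#' @param peak Composition of the maximum; must be a grid point.
#' @param amplitude Excess of the peak solubility over the neat-DES value.
#' @param base Neat-DES solubility (mole fraction).
#' @param grid Measured composition grid (must include 1).
#' @return A tibble: `x_star_des`, `x_exp`.
#' @export
gen_cosolvency_curve <- function(peak = 0.9, amplitude = 0.05, base = 0.3,
                                 grid = c(0.2, 0.4, 0.6, 0.8, 0.9, 1)) {
  stopifnot(peak %in% grid, 1 %in% grid, base > 0, amplitude >= 0)
  x <- sort(grid)
  if (peak < 1) {
    v <- base + amplitude - amplitude * ((x - peak) / (1 - peak))^2
  } else {
    v <- base + amplitude - amplitude * (1 - x) / max(1 - min(x), 1e-12)
  }
  tibble::tibble(x_star_des = x, x_exp = v)
}
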