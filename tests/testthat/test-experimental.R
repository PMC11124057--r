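ip_line <- list(slope = 27.268, intercept = 0.001)

test_that("a noiseless calibration series is fit exactly with zero LOD/LOQ", {
  lv <- gen_calibration_series(ip_line$slope, ip_line$intercept, noise = 0)
  cal <- fit_calibration(lv)
  expect_equal(cal$slope, 27.268, tolerance = 1e-10)
  expect_equal(cal$intercept, 0.001, tolerance = 1e-10)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_equal(cal$lod, 0, tolerance = 1e-12)
  expect_equal(cal$loq, 0, tolerance = 1e-12)
  expect_equal(cal$n_levels, 11L)
})

test_that("LOQ/LOD is 10/3.3 by construction for any noisy fit", {
  for (s in 1:5) {
    cal <- fit_calibration(gen_calibration_series(noise = 0.01, seed = s))
    expect_equal(cal$loq / cal$lod, 10 / 3.3, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo LOD matches the residual-SD oracle at the reported noise level", {
  # with absorbance noise SD 0.0192 the expected LOD is 3.3 * E[s] / slope;
  # E[s] = c4 * sigma with c4 for 9 residual degrees of freedom
  sigma <- 0.0192
  c4 <- sqrt(2 / 9) * gamma(5) / gamma(4.5)
  expected <- 3.3 * c4 * sigma / 27.268
  lods <- vapply(1:400, function(s) {
    fit_calibration(gen_calibration_series(noise = sigma, seed = s))$lod
  }, 0)
  expect_equal(mean(lods), expected, tolerance = 0.05)
  # consistent with the certificate-level LOD near 0.0023 mg/mL
  expect_equal(mean(lods), 0.0023, tolerance = 0.08)
})

test_that("calibration requires variation and at least three levels", {
  expect_error(fit_calibration(tibble::tibble(conc_mg_mL = c(1, 2),
                                              absorbance = c(1, 2))),
               "at least 3")
  expect_error(fit_calibration(tibble::tibble(conc_mg_mL = rep(1, 5),
                                              absorbance = rnorm(5))),
               "non-zero concentration range")
})

test_that("absorbance inversion reproduces the worked example and round-trips", {
  lv <- gen_calibration_series(ip_line$slope, ip_line$intercept, noise = 0)
  cal <- fit_calibration(lv)
  expect_equal(absorbance_to_concentration(0.27368, cal), 0.0100,
               tolerance = 1e-6)
  conc <- c(0.015, 0.03, 0.05)
  A <- cal$slope * conc + cal$intercept
  expect_equal(absorbance_to_concentration(A, cal), conc, tolerance = 1e-12)
  expect_error(absorbance_to_concentration(cal$intercept - 0.01, cal),
               "negative")
})

test_that("mole-fraction conversion matches the hand-worked aqueous ibuprofen case", {
  # identity curve: A equals concentration in mg/mL
  cal <- fit_calibration(tibble::tibble(conc_mg_mL = c(0, 100, 200, 300),
                                        absorbance = c(0, 100, 200, 300)))
  water <- solvent_mixture("water")
  res <- absorbance_to_mole_fraction(206.28, cal, dilution = 1,
                                     density_g_mL = 1.03128,
                                     system = water, solute = "IP")
  # 1 mmol IP against 825 mg water (45.79 mmol)
  expect_equal(res$conc_mg_mL, 206.28, tolerance = 1e-9)
  expect_equal(res$x, 1 / (1 + 825 / 18.015), tolerance = 1e-4)
  expect_equal(res$x, 0.0214, tolerance = 2e-3)
  expect_false(res$below_lod)
})

test_that("mole balance is conserved and inconsistent densities are rejected", {
  cal <- fit_calibration(tibble::tibble(conc_mg_mL = c(0, 10, 20, 30),
                                        absorbance = c(0, 10, 20, 30)))
  sys <- des_system("ChCl", "TEG", "1:2", x_star_des = 0.9)
  res <- absorbance_to_mole_fraction(25, cal, dilution = 1,
                                     density_g_mL = 1.1, system = sys,
                                     solute = "IP")
  reg <- compound_registry()
  mw_ip <- reg$mw[reg$compound_id == "IP"]
  mbar <- sum(sys$fraction * reg$mw[match(sys$component, reg$compound_id)])
  n_solute <- res$conc_mg_mL / mw_ip
  n_solvent <- (1100 - res$conc_mg_mL) / mbar
  expect_equal(res$x, n_solute / (n_solute + n_solvent), tolerance = 1e-12)
  expect_equal(n_solute * mw_ip + n_solvent * mbar, 1100, tolerance = 1e-9)
  expect_true(res$x >= 0 && res$x <= 1)
  expect_error(
    absorbance_to_mole_fraction(25, cal, dilution = 100, density_g_mL = 1.0,
                                system = sys, solute = "IP"),
    "density")
})

test_that("an absorbance at the intercept maps to the zero boundary, flagged below LOD", {
  cal <- fit_calibration(gen_calibration_series(noise = 0.005, seed = 1))
  res <- absorbance_to_mole_fraction(cal$intercept, cal, dilution = 1,
                                     density_g_mL = 1.0,
                                     system = solvent_mixture("water"),
                                     solute = "IP")
  expect_equal(res$x, 0)
  expect_true(res$below_lod)
})

test_that("replicate aggregation gives the arithmetic mean and sample SD", {
  expect_equal(aggregate_replicates(c(0.35, 0.35, 0.35)),
               tibble::tibble(mean = 0.35, sd = 0, n = 3L))
  expect_equal(aggregate_replicates(c(1, 2, 3)),
               tibble::tibble(mean = 2, sd = 1, n = 3L))
  expect_equal(aggregate_replicates(0.42),
               tibble::tibble(mean = 0.42, sd = 0, n = 1L))
  expect_error(aggregate_replicates(numeric(0)), "at least one")
})

test_that("raw measurement reduction produces the record schema with triplicate SDs", {
  cal <- fit_calibration(tibble::tibble(conc_mg_mL = c(0, 10, 20, 30),
                                        absorbance = c(0, 10, 20, 30)))
  sys <- dplyr::bind_rows(des_system("ChCl", "TEG", "1:2", 0.9),
                          solvent_mixture("water"))
  raw <- tidyr::expand_grid(system_id = unique(sys$system_id),
                            T_K = c(298.15, 308.15), rep = 1:3) |>
    dplyr::mutate(sample_id = dplyr::row_number(),
                  absorbance = 20 + rep, dilution = 1, density_g_mL = 1.05)
  rec <- process_measurements(raw, cal, sys, "IP")
  expect_equal(nrow(rec), 4L)
  expect_setequal(names(rec), c("record_id", "solute", "system_id", "is_DES",
                                "T_K", "x_exp", "sd", "n_replicates"))
  expect_true(all(rec$n_replicates == 3L))
  expect_true(all(rec$sd > 0))
  expect_setequal(unique(rec$is_DES), c(TRUE, FALSE))
})

test_that("cosolvency analysis finds the grid argmax and classifies strictly", {
  peaked <- gen_cosolvency_curve(peak = 0.9, amplitude = 0.05)
  res <- cosolvency_analysis(peaked)
  expect_equal(res$x_star_opt, 0.9)
  expect_equal(res$classification, "apparent cosolvency")
  # order invariance
  res2 <- cosolvency_analysis(peaked[sample.int(nrow(peaked)), ])
  expect_equal(res, res2)
  # monotone series peaking at the neat DES: no apparent cosolvency
  mono <- tibble::tibble(x_star_des = c(0.2, 0.5, 0.8, 1),
                         x_exp = c(0.1, 0.2, 0.25, 0.3))
  expect_equal(cosolvency_analysis(mono)$classification, "none")
  # flat series: tie broken toward the neat DES
  flat <- tibble::tibble(x_star_des = c(0.5, 0.8, 1), x_exp = rep(0.2, 3))
  resf <- cosolvency_analysis(flat)
  expect_equal(resf$x_star_opt, 1)
  expect_equal(resf$classification, "none")
  expect_error(cosolvency_analysis(flat[c(1, 1, 2, 3), ]), "duplicate")
  expect_error(cosolvency_analysis(flat[1:2, ]), "at least 3")
  expect_error(cosolvency_analysis(tibble::tibble(x_star_des = c(0.2, 0.5, 0.8),
                                                  x_exp = 1:3)),
               "neat DES")
})

test_that("the DES screening grid enumerates the Cartesian product without duplicates", {
  grid <- enumerate_des_grid()
  expect_equal(nrow(grid), 36L)
  expect_equal(nrow(enumerate_des_grid("ChCl", "TEG", "1:2")), 1L)
  expect_equal(nrow(enumerate_des_grid(c("ChCl", "ChCl"),
                                       c("TEG", "TEG", "GLY"),
                                       c("1:1", "1:2"))), 4L)
  expect_equal(anyDuplicated(grid$system_id), 0L)
})
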