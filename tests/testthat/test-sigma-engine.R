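test_that("the canonical grid has 61 uniformly spaced points on [-0.03, 0.03]", {
  g <- sigma_grid()
  expect_length(g, 61L)
  expect_equal(g[1], -0.030)
  expect_equal(g[61], 0.030)
  expect_equal(unique(round(diff(g), 12)), 0.001)
  expect_true(all(diff(g) > 0))
})

test_that("sigma-profile construction validates areas and the grid", {
  pr <- sigma_profile("toy", toy_areas(31, 100))
  expect_equal(sum(pr$area), 100)
  expect_error(sigma_profile("bad", rep(1, 60)), "one value per grid point")
  expect_error(sigma_profile("bad", c(rep(1, 60), -1)), "non-negative")
  expect_error(sigma_profile("bad", numeric(61)), "zero total")
  expect_error(desolv:::check_grid(seq(-0.02, 0.04, by = 0.001)), "canonical")
})

test_that("a neutral profile gives an even potential with its minimum at sigma = 0", {
  pr <- sigma_profile("neutral", toy_areas(31, 120))
  pot <- sigma_potential(pr, T = 298.15)
  expect_equal(pot$sigma[which.min(pot$mu)], 0)
  expect_equal(pot$mu, rev(pot$mu), tolerance = 1e-12)
  expect_equal(pot$source, rep("pure-compound", 61))
  expect_equal(unique(pot$temperature), 298.15)
})

test_that("a mixture of a compound with itself equals the pure compound", {
  a <- toy_areas(c(25, 31, 40), c(30, 80, 25))
  profs <- dplyr::bind_rows(sigma_profile("a", a), sigma_profile("b", a))
  pure <- sigma_potential(sigma_profile("a", a), T = 310)
  mix <- sigma_potential(profs, mole_fractions = c(a = 0.5, b = 0.5), T = 310)
  expect_equal(mix$mu, pure$mu, tolerance = 1e-10)
})

test_that("the damped fixed point reproduces the brute-force oracle on toy profiles", {
  cases <- list(
    toy_areas(c(21, 31, 41), c(40, 120, 40)),
    toy_areas(c(20, 31, 44), c(35, 90, 30)),
    toy_areas(c(15, 28, 31, 35, 48), c(20, 40, 80, 35, 25))
  )
  for (a in cases) {
    pot <- sigma_potential(sigma_profile("t", a), T = 298.15)
    mu_oracle <- oracle_sigma_potential(a, 298.15)
    expect_lt(max(abs(pot$mu - mu_oracle)), 1e-8)
  }
})

test_that("non-convergence and empty profiles raise informative errors", {
  const <- cosmo_constants(max_iter = 2)
  pr <- sigma_profile("t", toy_areas(c(10, 52), c(50, 50)))
  expect_error(sigma_potential(pr, T = 298.15, constants = const),
               "did not converge.*residual")
  expect_error(sigma_potential(pr[0, ], T = 298.15), "empty")
})

test_that("mixture potentials are linear in component weights and permutation invariant", {
  profs <- dplyr::bind_rows(
    sigma_profile("p", toy_areas(c(26, 31), c(50, 70))),
    sigma_profile("q", toy_areas(c(31, 38), c(90, 40))))
  sysA <- solvent_mixture(c("p", "q"), c(0.3, 0.7), system_id = "s")
  sysB <- solvent_mixture(c("q", "p"), c(0.7, 0.3), system_id = "s")
  mpA <- mixture_potential(sysA, profs, T = 298.15)
  mpB <- mixture_potential(sysB, profs, T = 298.15)
  expect_equal(mpA$mu, mpB$mu, tolerance = 1e-12)
  pp <- sigma_potential(profs[profs$compound_id == "p", ], T = 298.15)
  qq <- sigma_potential(profs[profs$compound_id == "q", ], T = 298.15)
  expect_equal(mpA$mu, 0.3 * pp$mu + 0.7 * qq$mu, tolerance = 1e-12)
  one <- mixture_potential(solvent_mixture("p"), profs, T = 298.15)
  expect_equal(one$mu, pp$mu, tolerance = 1e-12)
})

test_that("missing component profiles are reported by name", {
  profs <- sigma_profile("p", toy_areas(31, 100))
  sys <- solvent_mixture(c("p", "ghost"), c(0.5, 0.5))
  expect_error(mixture_potential(sys, profs, T = 298.15), "ghost")
})

test_that("relative potentials are pointwise differences with strict temperature checks", {
  profs <- dplyr::bind_rows(
    sigma_profile("u", toy_areas(c(28, 34), c(60, 60))),
    sigma_profile("v", toy_areas(c(31, 41), c(80, 30))))
  pu <- sigma_potential(profs[profs$compound_id == "u", ], T = 298.15)
  pv <- sigma_potential(profs[profs$compound_id == "v", ], T = 298.15)
  expect_equal(relative_potential(pu, pu)$delta_mu, rep(0, 61))
  expect_equal(relative_potential(pu, pv)$delta_mu,
               -relative_potential(pv, pu)$delta_mu)
  expect_equal(relative_potential(pu, pv)$delta_mu, pu$mu - pv$mu)
  pv2 <- sigma_potential(profs[profs$compound_id == "v", ], T = 308.15)
  expect_error(relative_potential(pu, pv2), "temperature")
})

test_that("DES composition convention yields renormalised solute-free fractions", {
  sys <- des_system("ChCl", "TEG", "1:2", x_star_des = 0.9)
  expect_equal(sys$component, c("ChCl", "TEG", "water"))
  expect_equal(sum(sys$fraction), 1)
  expect_equal(sys$fraction, c(0.3, 0.6, 0.1))
  expect_equal(sys$fraction[2] / sys$fraction[1], 2)
  neat <- des_system("BI", "GLY", "1:4")
  expect_equal(neat$fraction, c(0.2, 0.8))
  expect_false("water" %in% neat$component)
})

test_that("profile CSV round trip preserves the data and validates the grid", {
  dir <- withr::local_tempdir()
  profs <- dplyr::bind_rows(
    sigma_profile("a", toy_areas(c(20, 31), c(40, 60))),
    sigma_profile("b", toy_areas(c(31, 42), c(70, 30))))
  write_sigma_profiles(profs, dir)
  back <- read_sigma_profiles(dir)
  expect_equal(dplyr::arrange(back, compound_id, sigma),
               dplyr::arrange(profs, compound_id, sigma))
  bad <- file.path(dir, "c.csv")
  readr::write_csv(tibble::tibble(sigma = seq_len(10), area = 1), bad)
  expect_error(read_sigma_profiles(bad), "one value per grid point")
})
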