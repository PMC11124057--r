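make_toy_records <- function(n, dmu_fun, y_fun, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n * 61, 0, 0.05), n, 61,
                dimnames = list(NULL, desolv:::dmu_colnames()))
    M <- dmu_fun(M)
    y <- y_fun(M)
    records <- tibble::tibble(
      record_id = sprintf("t%03d", seq_len(n)),
      solute = sprintf("s%03d", seq_len(n)),
      system_id = sprintf("y%03d", seq_len(n)),
      is_DES = rep(c(TRUE, FALSE), length.out = n),
      T_K = 298.15, x_exp = 10^pmin(y, -0.01), sd = 0)
    relpots <- dplyr::bind_cols(records[, c("solute", "system_id", "T_K")],
                                tibble::as_tibble(M))
    list(records = records, relpots = relpots)
  })
}

test_that("a perfect linear relation at one sigma point gives R-squared 1 there", {
  # log solubility = 2 * dmu(sigma = 0.005), i.e. grid index 36
  toy <- make_toy_records(
    40, function(M) M,
    function(M) -2 + 2 * M[, 36])
  for (sub in c("DES", "nonDES")) {
    r2 <- r2_profile(toy$records, toy$relpots, sub)
    expect_equal(r2$r2[36], 1, tolerance = 1e-10)
    expect_equal(r2$sigma[36], 0.005)
  }
})

test_that("independent noise predictors give near-zero R-squared", {
  toy <- make_toy_records(
    400, function(M) M,
    function(M) withr::with_seed(99, rnorm(nrow(M), -2, 0.5)))
  r2 <- r2_profile(toy$records, toy$relpots, "DES")
  expect_lt(max(r2$r2), 0.05)
})

test_that("R-squared profiles are invariant to record duplication and zero for constant predictors", {
  toy <- make_toy_records(
    30, function(M) { M[, 10] <- 0.02; M },
    function(M) -2 + M[, 31])
  r2 <- r2_profile(toy$records, toy$relpots, "DES")
  doubled <- list(
    records = dplyr::bind_rows(
      toy$records,
      dplyr::mutate(toy$records, record_id = paste0(record_id, "b"))))
  r2d <- r2_profile(doubled$records, toy$relpots, "DES")
  expect_equal(r2$r2, r2d$r2, tolerance = 1e-12)
  expect_identical(r2$r2[10], 0)
})

test_that("selection applies a strict threshold in either subset", {
  r2a <- tibble::tibble(sigma = sigma_grid(), r2 = rep(0, 61))
  r2b <- r2a
  r2a$r2[5] <- 1
  r2a$r2[12] <- 0.4 # exactly at the threshold: excluded
  r2b$r2[20] <- 0.41
  sel <- select_sigma_points(r2a, r2b, threshold = 0.4)
  expect_identical(sel$selected_indices, c(5L, 20L))
  expect_false(sel$report$selected[12])
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(glance(sel)$n_selected, 2L)
})

test_that("selection is monotone in the threshold", {
  withr::with_seed(7, {
    r2a <- tibble::tibble(sigma = sigma_grid(), r2 = runif(61))
    r2b <- tibble::tibble(sigma = sigma_grid(), r2 = runif(61))
  })
  prev <- select_sigma_points(r2a, r2b, 0)$selected_indices
  for (thr in c(0.2, 0.4, 0.6, 0.9)) {
    cur <- select_sigma_points(r2a, r2b, thr)$selected_indices
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted informative sigma points are recovered exactly on the independent-noise fixture", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    fx <- gen_selection_fixture(n = 200, planted = c(16L, 31L, 46L),
                                effect_r2 = 0.8, seed = s)
    sel <- select_sigma_points(
      r2_profile(fx$records, fx$relpots, "nonDES"),
      r2_profile(fx$records, fx$relpots, "DES"))
    if (identical(sel$selected_indices, fx$planted)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("the feature table has the contracted shape and deterministic content", {
  ds <- small_dataset()
  rec <- ds$records[1:10, ]
  sel <- select_sigma_points(
    r2_profile(ds$records, ds$relpots, "nonDES"),
    r2_profile(ds$records, ds$relpots, "DES"))
  ft <- build_feature_table(rec, ds$systems, ds$profiles, ds$fusion, sel,
                            activity_model = "ideal", relpots = ds$relpots)
  expect_equal(nrow(ft), 10L)
  expect_equal(ncol(ft), 1L + 2L + length(sel$selected_indices))
  expect_equal(names(ft)[2], "log10_x_computed")
  expect_equal(names(ft)[ncol(ft)], "T_K")
  expect_false(anyNA(ft))
  ft2 <- build_feature_table(rec, ds$systems, ds$profiles, ds$fusion, sel,
                             activity_model = "ideal", relpots = ds$relpots)
  expect_identical(ft, ft2)
})

test_that("an empty selection keeps only the computed-solubility and temperature columns", {
  ds <- small_dataset()
  rec <- ds$records[1:5, ]
  zero <- tibble::tibble(sigma = sigma_grid(), r2 = rep(0, 61))
  sel <- select_sigma_points(zero, zero)
  ft <- build_feature_table(rec, ds$systems, ds$profiles, ds$fusion, sel,
                            activity_model = "ideal", relpots = ds$relpots)
  expect_equal(names(ft), c("record_id", "log10_x_computed", "T_K"))
})

test_that("a record whose solute is its own solvent has all-zero sigma features", {
  profs <- sigma_profile("self", toy_areas(c(28, 31, 34), c(40, 90, 40)))
  fus <- fusion_data("self", 380, 25)
  rec <- tibble::tibble(record_id = "r1", solute = "self",
                        system_id = "self", is_DES = FALSE,
                        T_K = 298.15, x_exp = 0.1, sd = 0)
  sys <- solvent_mixture("self")
  all_sel <- select_sigma_points(
    tibble::tibble(sigma = sigma_grid(), r2 = rep(1, 61)),
    tibble::tibble(sigma = sigma_grid(), r2 = rep(1, 61)))
  ft <- build_feature_table(rec, sys, profs, fus, all_sel,
                            activity_model = "ideal")
  expect_equal(unname(unlist(ft[1, desolv:::dmu_colnames()])), rep(0, 61))
})

test_that("missing fusion data is reported with the solute name", {
  ds <- small_dataset()
  rec <- ds$records[1:3, ]
  rec$solute <- "mystery"
  expect_error(
    build_feature_table(rec, ds$systems, ds$profiles, ds$fusion, NULL,
                        activity_model = "ideal", relpots = ds$relpots),
    "mystery")
})

test_that("selection reports round-trip through CSV", {
  fx <- gen_selection_fixture(n = 100, seed = 5)
  sel <- select_sigma_points(
    r2_profile(fx$records, fx$relpots, "nonDES"),
    r2_profile(fx$records, fx$relpots, "DES"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_equal(back$selected_indices, sel$selected_indices)
  expect_equal(back$report$r2_DES, sel$report$r2_DES, tolerance = 1e-12)
})
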