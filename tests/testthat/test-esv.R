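test_that("build_coefficients scales equivalent factors by the unit value", {
  V <- matrix(0, 11, 6)
  expect_true(all(build_coefficients(V, E_a = 1031.93) == 0))
  V[1, 1] <- 877.14 / 1031.93
  vc <- build_coefficients(V, E_a = 1031.93)
  expect_equal(vc["FP", "AL"], 877.14)
  # derived unit value: one seventh of grain value per hectare
  vc2 <- build_coefficients(V, Q = 7000, F_price = 2.1)
  expect_equal(attr(vc2, "E_a"), 2100)
  expect_error(build_coefficients(V), "exactly one")
  expect_error(build_coefficients(V, E_a = 1, Q = 1, F_price = 1), "exactly one")
})

test_that("the shipped coefficient table matches the published per-type totals", {
  co <- shanxi_esv_coefficients()
  expect_equal(unname(coefficient_totals(co)),
               c(4138.03, 23827.26, 20318.70, 129620.72, 0.00, 206.39),
               tolerance = 1e-9)
  expect_true(all(unclass(co)[, "CL"] == 0))
})

test_that("NDVI correction normalizes to unit mean", {
  expect_true(all(ndvi_correction(matrix(0.4, 3, 3))$F_k == 1))
  two <- ndvi_correction(matrix(c(0.2, 0.6), 1, 2))
  expect_equal(as.numeric(two$F_k), c(0.5, 1.5))
  s <- gen_scene(scene_config(n_rows = 32, n_cols = 32, seed = 8))
  expect_equal(mean(ndvi_correction(s$ndvi)$F_k), 1, tolerance = 1e-9)
  expect_error(ndvi_correction(matrix(NA_real_, 2, 2)), "valid")
})

test_that("compute_esv reproduces per-type totals and is linear in the correction", {
  co <- shanxi_esv_coefficients()
  one_al <- land_grid(matrix(1L, 1, 1), cell_area = 1)
  expect_equal(compute_esv(one_al, co)$total, 4138.03)
  all_cl <- land_grid(matrix(5L, 4, 4))
  expect_equal(compute_esv(all_cl, co)$total, 0)
  s <- gen_scene(scene_config(n_rows = 24, n_cols = 24, seed = 9))
  corr <- ndvi_correction(s$ndvi)
  r1 <- compute_esv(s$landuse, co, corr)
  doubled <- corr; doubled$F_k <- corr$F_k * 2
  expect_equal(compute_esv(s$landuse, co, doubled)$total, 2 * r1$total)
  # static model equals dynamic model under uniform NDVI
  expect_equal(compute_esv(s$landuse, co)$total,
               compute_esv(s$landuse, co,
                           ndvi_correction(matrix(0.7, 24, 24)))$total)
  expect_equal(sum(r1$per_service), r1$total, tolerance = 1e-9)
})

test_that("tiling a grid and summing tile values equals the whole-grid value", {
  co <- shanxi_esv_coefficients()
  s <- gen_scene(scene_config(n_rows = 32, n_cols = 32, seed = 10))
  corr <- ndvi_correction(s$ndvi)
  whole <- compute_esv(s$landuse, co, corr)$total
  tiles <- 0
  for (rs in list(1:16, 17:32)) for (cs in list(1:16, 17:32)) {
    sub_corr <- list(F_k = corr$F_k[rs, cs], ndvi_mean = corr$ndvi_mean)
    class(sub_corr) <- "ndvi_correction"
    tiles <- tiles + compute_esv(
      land_grid(unclass(s$landuse)[rs, cs]), co, sub_corr)$total
  }
  expect_equal(tiles, whole, tolerance = 1e-9)
})

test_that("transition contributions reconcile with the valuation difference", {
  co <- shanxi_esv_coefficients()
  g0 <- land_grid(matrix(1L, 1, 1))
  expect_equal(transition_contribution(g0, g0, co)$desv_total, 0)
  g1 <- land_grid(matrix(5L, 1, 1))
  cc <- transition_contribution(g0, g1, co)
  expect_equal(cc$desv_total, -4138.03)
  # arable-to-water gains exceed arable-to-grass gains per unit area
  gain_wa <- transition_contribution(g0, land_grid(matrix(4L, 1, 1)), co)$desv_total
  gain_gl <- transition_contribution(g0, land_grid(matrix(3L, 1, 1)), co)$desv_total
  expect_equal(gain_wa, 129620.72 - 4138.03)
  expect_gt(gain_wa, gain_gl)
  # with a shared correction, sum of contributions = ESV(t1) - ESV(t0)
  s <- gen_scene(scene_config(n_rows = 24, n_cols = 24, seed = 12))
  corr <- ndvi_correction(s$ndvi)
  t1 <- evolve_scene(s, shanxi_transition_matrix("NDS"), seed = 13)
  cc2 <- transition_contribution(s$landuse, t1, co, corr)
  expect_equal(cc2$desv_total,
               compute_esv(t1, co, corr)$total -
                 compute_esv(s$landuse, co, corr)$total,
               tolerance = 1e-9)
  # the three normalizations are internally consistent
  tab <- cc2$table
  expect_equal(sum(tab$pct_net), 100, tolerance = 1e-6)
  expect_equal(sum(tab$pct_gain, na.rm = TRUE), 100, tolerance = 1e-6)
  expect_equal(sum(tab$pct_loss, na.rm = TRUE), 100, tolerance = 1e-6)
})

test_that("percent change bookkeeping matches the published area and value figures", {
  a <- shanxi_landuse_areas()
  pc <- percent_change(a$area_1980, a$area_2020)
  expect_equal(round(pc[a$class == "AL"], 2), -5.82)
  expect_equal(round(pc[a$class == "CL"], 2), 131.74)
  expect_equal(round(percent_change(251.054, 245.899), 2), -2.05)
  expect_equal(round(percent_change(254.064, 245.899), 2), -3.21)
})
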