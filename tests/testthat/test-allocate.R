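uniform_suitability <- function(nr, nc) {
  lapply(seq_len(6), function(i) matrix(0.5, nr, nc))
}

test_that("allocation with demand equal to current areas changes nothing", {
  s <- gen_scene(scene_config(n_rows = 24, n_cols = 24, seed = 30))
  g <- s$landuse
  w <- neighborhood_weights(rep(1, 6))
  cfg <- allocation_config(uniform_suitability(24, 24), seed = 31)
  out <- allocate(class_areas(g), g, shanxi_transition_matrix("NDS"), w, cfg)
  expect_identical(matrix(as.integer(out), nrow(out)),
                   matrix(as.integer(g), nrow(g)))
  expect_true(attr(out, "converged"))
})

test_that("restricted water cells never convert and shortfalls are flagged", {
  g <- land_grid(matrix(rep(c(1L, 4L), each = 128), 16, 16))
  w <- neighborhood_weights(rep(1, 6))
  demand <- class_areas(g)
  demand["AL"] <- demand["AL"] + 60
  demand["WA"] <- demand["WA"] - 60
  cfg <- allocation_config(uniform_suitability(16, 16), restricted_from = 4L,
                           max_iters = 30, seed = 32)
  out <- allocate(demand, g, shanxi_transition_matrix("NDS"), w, cfg)
  expect_equal(unname(class_areas(out)["WA"]), unname(class_areas(g)["WA"]))
  expect_false(attr(out, "converged"))
  expect_gt(abs(attr(out, "shortfall")[["AL"]]), 0)
})

test_that("allocation meets projected demand within tolerance, deterministically", {
  s <- gen_scene(scene_config(n_rows = 48, n_cols = 48, seed = 33))
  g <- s$landuse
  m <- shanxi_transition_matrix("NDS")
  demand <- project_demand(class_areas(g), m, 1)
  w <- neighborhood_weights(pmax(demand - class_areas(g), 1))
  cfg <- allocation_config(uniform_suitability(48, 48), tolerance = 0.01,
                           seed = 34)
  out <- allocate(demand, g, m, w, cfg)
  total <- sum(class_areas(g))
  expect_true(all(abs(class_areas(out) - demand) <= 0.01 * total))
  out2 <- allocate(demand, g, m, w, cfg)
  expect_identical(unclass(out), unclass(out2))   # same seed, same map
  expect_error(allocate(demand * 2, g, m, w, cfg), "0.1%")
})

test_that("suitability learning returns probability surfaces per class", {
  s <- gen_scene(scene_config(n_rows = 24, n_cols = 24, seed = 35))
  g2 <- evolve_scene(s, shanxi_transition_matrix("NDS"), seed = 36)
  suit <- learn_suitability(s$landuse, g2, s$drivers)
  expect_length(suit, 6)
  for (m in suit) {
    expect_identical(dim(m), dim(unclass(s$landuse)))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("agreement metrics match closed-form kappa arithmetic", {
  g <- land_grid(matrix(sample(1:6, 400, TRUE), 20, 20))
  perfect <- agreement_metrics(g, g, initial = land_grid(matrix(1L, 20, 20)))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$fom, 1)
  # 2-class toy confusion [[40,10],[10,40]]: accuracy 0.8, kappa 0.6
  sim <- land_grid(matrix(rep(c(1L, 2L), each = 50), 10, 10))
  obs <- unclass(sim)
  obs[1:10] <- 2L          # 10 of the 50 class-1 cells observed as 2
  obs[51:60] <- 1L
  r <- agreement_metrics(sim, land_grid(obs))
  expect_equal(r$overall_accuracy, 0.8)
  expect_equal(r$kappa, 0.6)
  expect_true(is.na(r$fom))
})

test_that("kappa agrees with an independent implementation and has a null near zero", {
  skip_if_not_installed("e1071")
  set.seed(37)
  a <- land_grid(matrix(sample(1:6, 2500, TRUE), 50, 50))
  b <- land_grid(matrix(sample(1:6, 2500, TRUE, prob = c(3, 2, 2, 1, 1, 1)), 50, 50))
  r <- agreement_metrics(a, b)
  ca <- e1071::classAgreement(table(factor(a, 1:6), factor(b, 1:6)))
  expect_equal(r$kappa, ca$kappa, tolerance = 1e-12)
  expect_equal(r$overall_accuracy, ca$diag, tolerance = 1e-12)
  # independent random maps: kappa within 3 permutation SDs of zero
  perm <- replicate(100, {
    p <- land_grid(matrix(sample(unclass(b)), 50, 50))
    agreement_metrics(a, p)$kappa
  })
  expect_lt(abs(r$kappa - mean(perm)), 3 * sd(perm) + 1e-12)
})
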