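test_that("wcss is the exact sum of squared distances to own centroids", {
  x <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(wcss(x, c(1, 2), x), 0)                     # singleton clusters
  expect_equal(wcss(x, c(1, 1), matrix(c(1, 0), 1)), 2)    # hand example
  y <- matrix(rnorm(40), 20)
  expect_equal(wcss(y, rep(1, 20), matrix(colMeans(y), 1)),
               sum(scale(y, scale = FALSE)^2))              # one cluster = TSS
  expect_error(wcss(x, c(1, 3), x), "without a centroid")
})

test_that("the elbow rule finds planted blob counts and flags linear curves", {
  b3 <- make_blobs(60, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 1, seed = 5)
  e3 <- elbow_select(b3$x, k_max = 7, seed = 6)
  expect_equal(e3$k_opt, 3L)
  expect_false(e3$flat)
  expect_true(all(diff(e3$wcss_curve) <= 1e-9))   # non-increasing curve
  b2 <- make_blobs(60, rbind(c(0, 0), c(12, 0)), sd = 1, seed = 7)
  expect_equal(elbow_select(b2$x, k_max = 6, seed = 8)$k_opt, 2L)
  lin <- elbow_point(seq(100, 10, length.out = 8))
  expect_true(lin$flat)
  expect_error(elbow_select(matrix(1, 10, 2), k_max = 3), "distinct")
})

test_that("k = 1 bundling returns one bundle at the feature mean", {
  set.seed(9)
  st <- array(rnorm(8 * 8 * 3), c(8, 8, 3),
              dimnames = list(NULL, NULL, c("A", "B", "C")))
  m <- kmeans_bundles(list(d1 = st), k = 1, units = 2)
  expect_true(all(m$assignments$d1 == 1))
  expect_equal(unname(m$centroids[1, ]), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(bundle_shares(m)$share, 100)
})

test_that("bundling recovers planted archetypes and names them by dominant services", {
  skip_if_not_installed("mclust")
  arch <- make_archetype_landscape(nr = 48, nc = 48, units = 4, seed = 14)
  co <- shanxi_esv_coefficients()
  stack <- compute_esv(arch$grid, co)$per_cell
  m <- kmeans_bundles(list(d1 = stack), k = 3, units = 4, seed = 15)
  ari <- mclust::adjustedRandIndex(as.numeric(m$assignments$d1),
                                   as.numeric(arch$truth_units))
  expect_gt(ari, 0.9)
  # match bundles to truth bands by majority and inspect dominant services
  lab_of <- function(band) {
    b <- as.numeric(names(which.max(table(
      m$assignments$d1[arch$truth_units == band]))))
    m$labels[b]
  }
  expect_match(lab_of(1), "FP")                 # crop band: food production
  expect_match(lab_of(2), "CR|GR|SR|BM")        # mountain band: regulation
  expect_match(lab_of(3), "WR|WS")              # water band: hydrologic
})

test_that("assignments are invariant to per-service affine rescaling", {
  set.seed(16)
  st <- array(rnorm(12 * 12 * 4), c(12, 12, 4),
              dimnames = list(NULL, NULL, c("A", "B", "C", "D")))
  st2 <- st
  st2[, , 2] <- st[, , 2] * 1000 + 5
  m1 <- kmeans_bundles(list(d1 = st), k = 3, units = 2, seed = 17)
  m2 <- kmeans_bundles(list(d1 = st2), k = 3, units = 2, seed = 17)
  expect_identical(m1$assignments, m2$assignments)
})

test_that("bundle shares sum to 100 per date and track a planted trend", {
  # four dates in which the second archetype's footprint grows steadily
  mk <- function(frac2, seed) {
    set.seed(seed)
    n <- 100
    lab <- rep(1L, n); lab[seq_len(round(frac2 * n))] <- 2L
    st <- array(0, c(10, 10, 2), dimnames = list(NULL, NULL, c("A", "B")))
    st[, , 1] <- matrix(ifelse(lab == 1, 10, 0) + rnorm(n, sd = 0.5), 10)
    st[, , 2] <- matrix(ifelse(lab == 2, 10, 0) + rnorm(n, sd = 0.5), 10)
    st
  }
  stacks <- list(d1 = mk(0.2, 18), d2 = mk(0.35, 19),
                 d3 = mk(0.5, 20), d4 = mk(0.65, 21))
  m <- kmeans_bundles(stacks, k = 2, units = 1, seed = 22)
  sh <- bundle_shares(m)
  for (d in names(stacks))
    expect_equal(sum(sh$share[sh$date == d]), 100, tolerance = 1e-9)
  # identify the B-dominant bundle and check its share rises date over date
  b2 <- which(m$centroids[, "B"] > 0.5)
  tr <- sh$share[sh$bundle == b2][order(unique(sh$date))]
  expect_true(all(diff(tr) > 0))
})
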