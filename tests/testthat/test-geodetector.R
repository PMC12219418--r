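test_that("discretization produces monotone bins of the requested kind", {
  expect_error(discretize(rep(1, 50), "quantile", 5), "distinct")
  q5 <- discretize(1:100, "quantile", 5)
  expect_equal(as.integer(table(q5$strata)), rep(20L, 5))
  e4 <- discretize(1:100, "equal", 4)
  expect_equal(e4$breaks[2:4], c(25.75, 50.5, 75.25))
  # monotone: stratum label never decreases with the value
  expect_true(all(diff(q5$strata[order(1:100)]) >= 0))
})

test_that("factor_q matches the variance-decomposition hand example and bounds", {
  q <- factor_q(c(1, 2, 3, 4), c(1, 1, 2, 2))
  expect_equal(q$q, 0.8)
  expect_equal(q$sigma2, 1.25)
  expect_equal(unname(q$sigma2_h), c(0.25, 0.25))
  # internally constant strata explain everything
  expect_equal(factor_q(c(1, 1, 5, 5, 9, 9), c(1, 1, 2, 2, 3, 3))$q, 1)
  expect_error(factor_q(rep(2, 10), rep(1:2, 5)), "zero variance")
})

test_that("factor_q equals 1 - SSW/SST from an independent groupby oracle", {
  set.seed(25)
  for (i in 1:5) {
    n <- 1000
    y <- rnorm(n, mean = rep(seq_len(5), each = n / 5))
    s <- sample(rep(1:8, length.out = n))
    sst <- sum((y - mean(y))^2)
    ssw <- sum(unlist(lapply(split(y, s), function(g) sum((g - mean(g))^2))))
    expect_equal(factor_q(y, s)$q, 1 - ssw / sst, tolerance = 1e-12)
  }
})

test_that("random strata give q near the permutation null", {
  set.seed(26)
  n <- 10000
  y <- rnorm(n)
  s <- sample(rep(1:5, n / 5))
  q_obs <- factor_q(y, s)$q
  q_null <- replicate(100, factor_q(y, sample(s))$q)
  expect_lt(abs(q_obs - mean(q_null)), 3 * sd(q_null) + 1e-12)
})

test_that("q never decreases when a partition is refined", {
  set.seed(27)
  for (i in 1:10) {
    n <- 400
    y <- rnorm(n) + rep(rnorm(4, sd = 2), each = n / 4)
    coarse <- sample(1:4, n, TRUE)
    refined <- paste(coarse, sample(1:3, n, TRUE))
    expect_gte(factor_q(y, refined)$q + 1e-12, factor_q(y, coarse)$q)
  }
})

test_that("interaction detection classifies constructed designs correctly", {
  # XOR layout: neither factor explains y alone, the overlay explains it fully
  a <- rep(c(1, 1, 2, 2), 25)
  b <- rep(c(1, 2, 1, 2), 25)
  y <- as.numeric(a != b)
  r <- interaction_detect(y, a, b)
  expect_equal(r$q1, 0, tolerance = 1e-12)
  expect_equal(r$q2, 0, tolerance = 1e-12)
  expect_equal(r$q12, 1)
  expect_equal(r$type, "nonlinear enhancement")
  # self-overlay: q12 equals the factor's own q, reported as a boundary tie
  set.seed(28)
  y2 <- rnorm(100) + rep(c(0, 3), each = 50)
  s <- rep(1:2, each = 50)
  r2 <- interaction_detect(y2, s, s)
  expect_equal(r2$q12, r2$q1, tolerance = 1e-12)
  expect_equal(r2$type, "equals max")
  # y depends only on A; B refines the overlay without explaining anything:
  # q12 = q1 = q1 + q2 exactly, the independence identity
  y3 <- rep(c(0, 10), each = 60)
  a3 <- rep(1:2, each = 60)
  b3 <- rep(rep(1:2, each = 30), 2)
  r3 <- interaction_detect(y3, a3, b3)
  expect_equal(r3$q2, 0, tolerance = 1e-12)
  expect_equal(r3$q12, r3$q1, tolerance = 1e-12)
  expect_equal(r3$type, "independence")
})

test_that("VIF screening flags collinearity and passes orthogonal designs", {
  # exactly orthogonal contrasts: all VIF = 1
  X <- cbind(a = rep(c(1, -1), 4), b = rep(c(1, 1, -1, -1), 2),
             c = rep(c(1, -1, -1, 1), 2))
  expect_equal(unname(vif(X)), rep(1, 3))
  set.seed(29)
  x1 <- rnorm(100)
  expect_true(is.infinite(vif(cbind(x1 = x1, x2 = x1, x3 = rnorm(100)))[["x2"]]))
  # mild planted correlation across 9 factors stays under the screening rule
  Z <- matrix(rnorm(900), 100, 9)
  Z <- Z + 0.5 * Z[, 1]   # common mild dependence
  colnames(Z) <- paste0("X", 1:9)
  expect_true(all(vif(Z) < 5))
})
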