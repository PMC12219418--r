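#' Discretize a continuous factor into strata
#'
#' Monotone binning of a driver surface for the factor detector. The
#' quantile method yields near-equal stratum counts; the equal-interval
#' method splits the value range evenly. Empty strata are pruned and
#' labels renumbered 1..L.
#'
#' @param x Numeric vector or matrix of factor values.
#' @param method "quantile" or "equal".
#' @param L Number of strata (2..12).
#' @return A `strata_partition` list: `strata` (integer labels, NA where
#'   `x` is NA), `L`, `method`, `breaks`.
#' @export
discretize <- function(x, method = c("quantile", "equal"), L = 5L) {
  method <- match.arg(method)
  v <- as.numeric(x)
  L <- as.integer(L)
  if (L < 2L || L > 12L) stop("`L` must be in 2..12", call. = FALSE)
  if (length(unique(v[!is.na(v)])) < L)
    stop("fewer distinct values than strata", call. = FALSE)
  breaks <- if (method == "quantile")
    unique(stats::quantile(v, probs = seq(0, 1, length.out = L + 1L),
                           na.rm = TRUE, names = FALSE))
  else seq(min(v, na.rm = TRUE), max(v, na.rm = TRUE), length.out = L + 1L)
  s <- cut(v, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  lev <- sort(unique(s[!is.na(s)]))
  s <- match(s, lev)
  structure(list(strata = s, L = length(lev), method = method,
                 breaks = breaks), class = "strata_partition")
}

as_strata <- function(s) {
  if (inherits(s, "strata_partition")) s$strata else as.integer(as.factor(s))
}

#' Factor-detector q statistic
#'
#' The explanatory power of a stratification for a response:
#' `q = 1 - sum_h(N_h * sigma2_h) / (N * sigma2)`, with population
#' variances (denominator N, not N-1) throughout; identical to
#' 1 - SSW/SST. Also returns the noncentral-F p-value of the q test.
#'
#' @param y Numeric response, one value per unit.
#' @param strata A [discretize()] result or any vector of stratum labels.
#' @return A `q_result` list: `q`, `N`, `N_h`, `sigma2`, `sigma2_h`,
#'   `p_value`.
#' @export
factor_q <- function(y, strata) {
  s <- as_strata(strata)
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  n <- length(y)
  L <- length(unique(s))
  if (n < L + 1L) stop("need at least L + 1 units", call. = FALSE)
  v <- function(z) mean((z - mean(z))^2)   # population variance
  sigma2 <- v(y)
  if (sigma2 == 0) stop("response has zero variance", call. = FALSE)
  nh <- tapply(y, s, length)
  s2h <- tapply(y, s, v)
  q <- 1 - sum(nh * s2h) / (n * sigma2)
  # noncentral-F significance test of the q statistic
  p <- NA_real_
  if (L > 1L && q < 1) {
    mh <- tapply(y, s, mean)
    f_stat <- (n - L) / (L - 1) * q / (1 - q)
    lambda <- max((sum(nh * mh^2) - sum(sqrt(nh) * mh)^2 / n) / sigma2, 0)
    p <- stats::pf(f_stat, L - 1, n - L, ncp = lambda, lower.tail = FALSE)
  }
  structure(list(q = as.numeric(q), N = n,
                 N_h = stats::setNames(as.integer(nh), names(nh)),
                 sigma2 = sigma2,
                 sigma2_h = stats::setNames(as.numeric(s2h), names(s2h)),
                 p_value = p),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("q_result: q = %.4f (N = %d, L = %d strata, p = %s)\n",
              x$q, x$N, length(x$N_h), format.pval(x$p_value)))
  invisible(x)
}

#' Two-factor interaction detection
#'
#' Computes q for each factor and for their overlay (the Cartesian
#' stratification) and classifies the interaction: independence when
#' `q12 = q1 + q2` (within `tol`), nonlinear enhancement when
#' `q12 > q1 + q2`, two-factor enhancement when `q12 > max(q1, q2)`,
#' nonlinear weakening when `q12 < min(q1, q2)`, single-factor nonlinear
#' weakening in between. Boundary ties with the max or min are reported
#' explicitly rather than forced into an inequality class.
#'
#' @param y Numeric response per unit.
#' @param strata_a,strata_b Stratifications of the two factors.
#' @param tol Equality tolerance (default 1e-6).
#' @return An `interaction_result` list: `q1`, `q2`, `q12`, `type`.
#' @export
interaction_detect <- function(y, strata_a, strata_b, tol = 1e-6) {
  sa <- as_strata(strata_a); sb <- as_strata(strata_b)
  q1 <- factor_q(y, sa)$q
  q2 <- factor_q(y, sb)$q
  overlay <- as.integer(interaction(sa, sb, drop = TRUE))
  q12 <- factor_q(y, overlay)$q
  lo <- min(q1, q2); hi <- max(q1, q2)
  type <-
    if (abs(q12 - (q1 + q2)) < tol) "independence"
    else if (q12 > q1 + q2) "nonlinear enhancement"
    else if (abs(q12 - hi) < tol) "equals max"
    else if (q12 > hi) "two-factor enhancement"
    else if (abs(q12 - lo) < tol) "equals min"
    else if (q12 < lo) "nonlinear weakening"
    else "single-factor nonlinear weakening"
  structure(list(q1 = q1, q2 = q2, q12 = q12, type = type),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction: q1 = %.4f, q2 = %.4f, q12 = %.4f -> %s\n",
              x$q1, x$q2, x$q12, x$type))
  invisible(x)
}

#' Variance inflation factors
#'
#' Collinearity screen: each factor is regressed on all the others;
#' `VIF_j = 1 / (1 - R2_j)`. Perfect collinearity is reported as `Inf`.
#'
#' @param factors Numeric matrix or data frame (units x factors, >= 2
#'   factors, more units than factors).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(factors) {
  X <- as.data.frame(factors)
  if (ncol(X) < 2L) stop("need at least 2 factors", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more units than factors", call. = FALSE)
  out <- vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((X[[j]] - mean(X[[j]]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}
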