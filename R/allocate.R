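#' Allocation configuration for the cellular-automata stage
#'
#' @param suitability Named list of six matrices in `[0, 1]` (one
#'   probability-of-development surface per destination class), e.g. from
#'   [learn_suitability()].
#' @param restricted Optional logical matrix; `TRUE` cells never change.
#' @param restricted_from Optional integer class codes whose cells may not
#'   convert away (e.g. `4` to make water a restrictive land type).
#' @param neighborhood_radius Neighbourhood window radius in cells.
#' @param threshold_decay Multiplicative decay of the conversion threshold
#'   per iteration, in (0, 1).
#' @param max_iters Iteration cap.
#' @param tolerance Demand tolerance as a fraction of total area.
#' @param seed Integer seed for the patch sampling.
#' @return An `allocation_config` list.
#' @export
allocation_config <- function(suitability, restricted = NULL,
                              restricted_from = integer(),
                              neighborhood_radius = 1L,
                              threshold_decay = 0.9, max_iters = 200L,
                              tolerance = 0.01, seed = 1L) {
  if (!is.list(suitability) || length(suitability) != 6L)
    stop("`suitability` must be a list of 6 matrices", call. = FALSE)
  rng <- range(unlist(lapply(suitability, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  if (threshold_decay <= 0 || threshold_decay >= 1)
    stop("`threshold_decay` must be in (0, 1)", call. = FALSE)
  structure(list(suitability = suitability, restricted = restricted,
                 restricted_from = as.integer(restricted_from),
                 neighborhood_radius = as.integer(neighborhood_radius),
                 threshold_decay = threshold_decay,
                 max_iters = as.integer(max_iters),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "allocation_config")
}

#' Learn per-class development suitability from observed change
#'
#' Default suitability learner behind the patch allocator: for each
#' destination class a logistic regression of cell membership at the later
#' date on the driver surfaces (a random-forest learner can be swapped in
#' when the randomForest package is available). Fitted probabilities are
#' returned per class as surfaces in `[0, 1]`.
#'
#' @param grid_t0,grid_t1 Co-registered [land_grid()]s (calibration dates).
#' @param drivers Named list of driver matrices.
#' @param method "logistic" (default) or "randomforest".
#' @return Named list of six suitability matrices.
#' @export
learn_suitability <- function(grid_t0, grid_t1, drivers,
                              method = c("logistic", "randomforest")) {
  method <- match.arg(method)
  stop_if_misaligned(grid_t0, grid_t1)
  X <- as.data.frame(lapply(drivers, as.numeric))
  out <- vector("list", 6L)
  names(out) <- names(land_classes())
  for (j in 1:6) {
    y <- as.integer(grid_t1 == j)
    if (length(unique(y)) < 2L) {
      out[[j]] <- matrix(mean(y), nrow(grid_t0), ncol(grid_t0))
      next
    }
    prob <- if (method == "logistic") {
      fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                         data = cbind(y = y, X)))
      stats::predict(fit, type = "response")
    } else {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("randomForest not available", call. = FALSE)
      fit <- randomForest::randomForest(x = X, y = factor(y), ntree = 100)
      stats::predict(fit, type = "prob")[, "1"]
    }
    out[[j]] <- matrix(pmin(1, pmax(0, prob)), nrow(grid_t0), ncol(grid_t0))
  }
  out
}

# Moving-window box sum via padded cumulative sums (torus-free, edge-clipped).
box_share <- function(indicator, radius) {
  nr <- nrow(indicator); nc <- ncol(indicator)
  cs <- matrix(0, nr + 1L, nc + 1L)
  cs[-1L, -1L] <- t(apply(apply(indicator, 2L, cumsum), 1L, cumsum))
  ri <- as.vector(row(indicator)); ci <- as.vector(col(indicator))
  r1 <- pmax(ri - radius, 1L); r2 <- pmin(ri + radius, nr)
  c1 <- pmax(ci - radius, 1L); c2 <- pmin(ci + radius, nc)
  s <- cs[cbind(r2 + 1L, c2 + 1L)] - cs[cbind(r1, c2 + 1L)] -
    cs[cbind(r2 + 1L, c1)] + cs[cbind(r1, c1)]
  matrix(s / ((r2 - r1 + 1) * (c2 - c1 + 1)), nr, nc)
}

#' Allocate projected demand on the map by seeded patch growth
#'
#' Cellular-automata stage: iteratively converts cells of surplus classes
#' to deficit classes. Candidate cells must have a positive transfer
#' probability from their current class, must not be restricted, and are
#' scored by `suitability * (1 + X_j * neighbourhood share of class j)`;
#' cells whose score exceeds a per-class threshold are sampled with
#' probability proportional to the score. The threshold decays by
#' `threshold_decay` each iteration, so allocation starts in the most
#' suitable, best-connected locations and relaxes gradually. Stops when
#' every class is within `tolerance` of demand or `max_iters` is reached;
#' the returned grid carries `converged` and `shortfall` attributes.
#'
#' @param demand Numeric vector of 6 target areas (hm2); its total must
#'   match the grid total within 0.1%.
#' @param current A [land_grid()].
#' @param matrix A [transition_matrix()] gating allowed conversions.
#' @param weights Neighbourhood weights from [neighborhood_weights()].
#' @param config An [allocation_config()].
#' @return A [land_grid()] with attributes `converged` (logical) and
#'   `shortfall` (named per-class area error, hm2).
#' @export
allocate <- function(demand, current, matrix, weights, config) {
  ca <- cell_area(current)
  total <- sum(class_areas(current))
  if (abs(sum(demand) - total) > 0.001 * total)
    stop("demand total does not match grid total within 0.1%", call. = FALSE)
  p <- unclass(matrix)
  X <- weights$X
  grid <- unclass(current)
  restricted <- if (is.null(config$restricted))
    matrix(FALSE, nrow(grid), ncol(grid)) else config$restricted
  if (length(config$restricted_from))
    restricted <- restricted | matrix(grid %in% config$restricted_from,
                                      nrow(grid), ncol(grid))
  tol_cells <- config$tolerance * total / ca
  tau <- rep(1, 6)
  converged <- FALSE
  with_seed(config$seed, {
    for (it in seq_len(config$max_iters)) {
      areas <- tabulate(grid, 6L) * ca
      diff_cells <- round((demand - areas) / ca)
      if (all(abs(diff_cells) <= tol_cells)) { converged <- TRUE; break }
      donors <- which(diff_cells < 0)
      surplus <- pmax(-diff_cells, 0)
      for (j in order(diff_cells, decreasing = TRUE)) {
        need <- diff_cells[j]
        if (need <= 0) next
        gv <- as.vector(grid)
        elig <- which(gv %in% donors & !as.vector(restricted) &
                        p[cbind(gv, j)] > 0 & gv != j)
        if (!length(elig)) next
        nb <- box_share(grid == j, config$neighborhood_radius)
        s <- config$suitability[[j]][elig] * (1 + X[j] * nb[elig])
        keep <- s >= tau[j] * max(s, 0)
        tau[j] <- tau[j] * config$threshold_decay
        elig <- elig[keep]; s <- s[keep]
        if (!length(elig)) next
        take <- min(length(elig), need)
        pick <- if (length(elig) == 1L) elig else
          sample(elig, size = length(elig), replace = FALSE,
                 prob = pmax(s, 1e-12))
        # greedy accept in sampled order, honouring donor surpluses
        got <- 0L
        for (cell in pick) {
          from <- grid[cell]
          if (surplus[from] <= 0) next
          grid[cell] <- j
          surplus[from] <- surplus[from] - 1
          got <- got + 1L
          if (got >= take) break
        }
      }
    }
  })
  out <- land_grid(grid, ca)
  final <- class_areas(out)
  attr(out, "converged") <- converged
  attr(out, "shortfall") <- stats::setNames(demand - final, names(land_classes()))
  out
}

#' Map-agreement validation metrics
#'
#' Cohen's kappa and overall accuracy from the 6x6 confusion matrix of a
#' simulated versus an observed map, plus (when the `initial` map of the
#' simulated interval is supplied) the figure of merit over changed cells:
#' hits / (hits + misses + wrong-change + false alarms).
#'
#' @param simulated,observed Co-registered [land_grid()]s.
#' @param initial Optional [land_grid()] at the start of the simulated
#'   interval; required for the figure of merit.
#' @return List with `kappa`, `overall_accuracy`, `fom` (NA without
#'   `initial`) and the `confusion` matrix.
#' @export
agreement_metrics <- function(simulated, observed, initial = NULL) {
  stop_if_misaligned(simulated, observed)
  tab <- table(factor(simulated, levels = 1:6), factor(observed, levels = 1:6))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  fom <- NA_real_
  if (!is.null(initial)) {
    stop_if_misaligned(initial, observed)
    obs_chg <- observed != initial
    sim_chg <- simulated != initial
    hits <- sum(obs_chg & sim_chg & simulated == observed)
    misses <- sum(obs_chg & !sim_chg)
    wrong <- sum(obs_chg & sim_chg & simulated != observed)
    false_alarm <- sum(!obs_chg & sim_chg)
    denom <- hits + misses + wrong + false_alarm
    fom <- if (denom == 0) 1 else hits / denom
  }
  list(kappa = as.numeric(kappa), overall_accuracy = as.numeric(po),
       fom = fom, confusion = unclass(tab))
}
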