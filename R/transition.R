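#' Construct a land-use transition matrix
#'
#' A 6x6 row-stochastic matrix of transfer probabilities between the six
#' land classes over one projection interval. Rows are origin classes,
#' columns destination classes.
#'
#' @param p Numeric 6x6 matrix; rows must sum to 1 within `tol`.
#' @param tol Row-sum tolerance (default 1e-5, which accepts tables
#'   printed at six decimal places).
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(p, tol = 1e-5) {
  cls <- names(land_classes())
  if (!is.matrix(p) || !all(dim(p) == 6L))
    stop("`p` must be a 6x6 matrix", call. = FALSE)
  p <- matrix(as.numeric(p), 6L, 6L, dimnames = list(cls, cls))
  if (any(p < 0 | p > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("rows must sum to 1 +/- %g (worst deviation %.3g)",
                 tol, max(abs(rs - 1))), call. = FALSE)
  structure(p, class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix (rows = origin, columns = destination):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

is_transition_matrix <- function(p, tol = 1e-5) {
  is.matrix(p) && all(dim(p) == 6L) && all(p >= 0) &&
    all(abs(rowSums(p) - 1) <= tol)
}

#' Estimate a transition matrix from two co-registered land-use maps
#'
#' Cross-tabulates the two dates cell by cell; `p[i, j]` is the share of
#' class-i area at the first date that is class j at the second. Classes
#' absent at the first date receive identity rows.
#'
#' @param grid_t0,grid_t1 `land_grid` objects of identical dimensions.
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(grid_t0, grid_t1) {
  stop_if_misaligned(grid_t0, grid_t1)
  ok <- !is.na(grid_t0) & !is.na(grid_t1)
  tab <- table(factor(grid_t0[ok], levels = 1:6),
               factor(grid_t1[ok], levels = 1:6))
  p <- unclass(tab) / pmax(rowSums(tab), 1)
  empty <- rowSums(tab) == 0
  p[empty, ] <- diag(6)[empty, ]
  transition_matrix(p, tol = 1e-9)
}

#' A single multiplicative scenario edit
#'
#' @param from,to Class codes ("AL", "FO", "GL", "WA", "CL", "UL").
#' @param multiplier Positive scale factor applied to `p[from, to]`.
#' @return One-row data frame.
#' @export
scenario_edit <- function(from, to, multiplier) {
  cls <- names(land_classes())
  if (!(from %in% cls) || !(to %in% cls))
    stop("`from` and `to` must be class codes AL/FO/GL/WA/CL/UL", call. = FALSE)
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("`multiplier` must be positive", call. = FALSE)
  data.frame(from = from, to = to, multiplier = multiplier,
             stringsAsFactors = FALSE)
}

#' Apply multiplicative scenario edits to a transition matrix
#'
#' Each edit scales one entry of its row; the row's remaining probability
#' mass is then redistributed over the non-edited entries in proportion to
#' their previous values, so that every edited row sums to exactly 1.
#' Rows without edits are returned bit-identical.
#'
#' @param matrix A [transition_matrix()].
#' @param edits Data frame of [scenario_edit()] rows (may contain several
#'   edits in the same row, e.g. the AEDS construction-land row).
#' @return Edited [transition_matrix()].
#' @export
apply_scenario_edits <- function(matrix, edits) {
  if (!inherits(matrix, "transition_matrix"))
    matrix <- transition_matrix(matrix)
  p <- unclass(matrix)
  for (r in unique(edits$from)) {
    e <- edits[edits$from == r, , drop = FALSE]
    if (anyDuplicated(e$to))
      stop("duplicate edit for the same (from, to) pair", call. = FALSE)
    old <- p[r, ]
    new <- old
    new[e$to] <- old[e$to] * e$multiplier
    if (all(new[e$to] == old[e$to])) next   # no-op edit leaves the row bit-identical
    if (any(new[e$to] > 1))
      stop(sprintf("edit pushes p[%s, ] above 1", r), call. = FALSE)
    others <- setdiff(colnames(p), e$to)
    rest <- sum(old[others])
    target <- 1 - sum(new[e$to])
    if (target < 0)
      stop(sprintf("edited entries of row %s exceed total probability", r),
           call. = FALSE)
    if (rest <= 0 && abs(target) > 1e-12)
      stop(sprintf("row %s has no remaining mass to redistribute", r),
           call. = FALSE)
    if (rest > 0) new[others] <- old[others] * target / rest
    p[r, ] <- new
  }
  # unedited rows keep the input's (possibly printed-precision) row sums
  transition_matrix(p, tol = 1e-5)
}

#' Markov projection of land-use demand
#'
#' Projects a per-class area vector through `steps` applications of the
#' transition matrix: `areas' = areas %*% P^steps`. Total area is
#' conserved up to the row-sum tolerance of the matrix.
#'
#' @param areas Numeric vector of 6 non-negative areas (hm2), ordered
#'   AL, FO, GL, WA, CL, UL.
#' @param matrix A [transition_matrix()].
#' @param steps Number of projection intervals (>= 1).
#' @return Named numeric vector of projected areas (hm2).
#' @export
project_demand <- function(areas, matrix, steps = 1L) {
  if (length(areas) != 6L || any(areas < 0))
    stop("`areas` must be 6 non-negative values", call. = FALSE)
  if (!is_transition_matrix(unclass(matrix)))
    stop("`matrix` is not row-stochastic", call. = FALSE)
  steps <- as.integer(steps)
  if (steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  v <- matrix(as.numeric(areas), 1L, 6L)
  for (i in seq_len(steps)) v <- v %*% unclass(matrix)
  stats::setNames(as.numeric(v), names(land_classes()))
}

#' Neighbourhood (domain) weights from expansion areas
#'
#' The per-class expansion-intensity weight
#' `X_i = (TA_i - TA_min) / (TA_max + TA_min)`, where `TA_i` is the
#' expansion area of class i over the calibration interval.
#'
#' @param expansion_areas Numeric vector of non-negative expansion areas
#'   (hm2), one per class.
#' @return List with `X` (weights) and `TA` (the input areas).
#' @export
neighborhood_weights <- function(expansion_areas) {
  ta <- as.numeric(expansion_areas)
  if (any(ta < 0)) stop("expansion areas must be non-negative", call. = FALSE)
  if (all(ta == 0)) stop("all expansion areas are zero", call. = FALSE)
  x <- (ta - min(ta)) / (max(ta) + min(ta))
  list(X = stats::setNames(x, names(expansion_areas)), TA = ta)
}
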