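#' Within-cluster sum of squares
#'
#' Exact sum of squared Euclidean distances of each point to its own
#' cluster centroid.
#'
#' @param data Numeric matrix (units x features).
#' @param assignment Integer cluster labels, one per row of `data`.
#' @param centroids Matrix of centroids (clusters x features), rows
#'   indexed by label.
#' @return Scalar WCSS.
#' @export
wcss <- function(data, assignment, centroids) {
  data <- as.matrix(data)
  if (max(assignment) > nrow(centroids))
    stop("assignment label without a centroid", call. = FALSE)
  sum((data - centroids[assignment, , drop = FALSE])^2)
}

#' Select the number of bundles by the elbow rule
#'
#' Runs best-of-`n_init` K-means for k = 1..`k_max`, records the WCSS
#' curve, and selects the k of maximum curvature: the arg max of the
#' second difference of WCSS(k) over the interior ks. A perfectly linear
#' decay has no distinguished elbow; the flattest-curvature case is
#' reported with a `flat` flag.
#'
#' @param data Numeric matrix (units x features), already standardized if
#'   desired.
#' @param k_max Largest k to scan (>= 3).
#' @param n_init Random restarts per k.
#' @param seed Integer seed.
#' @return List: `k_opt`, `wcss_curve` (length `k_max`), `flat` (logical).
#' @export
elbow_select <- function(data, k_max = 8L, n_init = 25L, seed = 1L) {
  data <- as.matrix(data)
  if (k_max < 3L) stop("`k_max` must be >= 3", call. = FALSE)
  if (nrow(unique(data)) < k_max)
    stop("fewer distinct points than `k_max`", call. = FALSE)
  curve <- numeric(k_max)
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      curve[k] <- if (k == 1L) sum(scale(data, scale = FALSE)^2)
      else stats::kmeans(data, centers = k, nstart = n_init,
                         iter.max = 100L)$tot.withinss
    }
  })
  curve <- cummin(curve)   # restarts can leave tiny non-monotonicity
  c(elbow_point(curve), list(wcss_curve = curve))
}

#' Knee of a WCSS curve
#'
#' The discrete maximum-curvature rule behind [elbow_select()]: the elbow
#' is the k maximizing the second difference of WCSS(k). When the curve
#' decays (numerically) linearly there is no distinguished knee; the
#' largest-curvature k is still returned but flagged `flat`.
#'
#' @param wcss_curve Numeric WCSS values for k = 1..k_max.
#' @return List with `k_opt` and `flat`.
#' @export
elbow_point <- function(wcss_curve) {
  if (length(wcss_curve) < 3L) stop("need at least 3 curve points", call. = FALSE)
  d2 <- diff(wcss_curve, differences = 2L)   # curvature at k = 2..k_max-1
  k_opt <- which.max(d2) + 1L
  # negligible curvature relative to the slope = no distinguished knee
  flat <- max(abs(d2)) <= 1e-9 * max(abs(diff(wcss_curve)), .Machine$double.eps)
  list(k_opt = as.integer(k_opt), flat = flat)
}

# Build the unit x service feature matrix for one date.
stack_to_units <- function(stack, units) {
  sapply(seq_len(dim(stack)[3]),
         function(s) as.numeric(aggregate_blocks(stack[, , s], units)))
}

#' Identify ecosystem service bundles by K-means
#'
#' Aggregates each date's per-cell service value stack into spatial units,
#' z-score standardizes every service over the pooled units of all dates,
#' and clusters the pooled space once so bundle labels are comparable
#' across dates. Bundles are named by the services whose centroid z-score
#' exceeds `dominance`.
#'
#' @param stacks Named list of rows x cols x services arrays (one per
#'   date/scenario).
#' @param k Number of bundles.
#' @param units Aggregation factor (cells per block side).
#' @param n_init K-means restarts.
#' @param dominance Centroid z-score above which a service is listed as
#'   dominant for a bundle (default 0.5).
#' @param seed Integer seed.
#' @return A `bundle_model` list: `k`, `centroids` (k x services, z
#'   space), `assignments` (named list of unit-grid matrices of labels),
#'   `labels` (dominant services per bundle), `wcss`, plus the
#'   standardization `center`/`scale`.
#' @export
kmeans_bundles <- function(stacks, k, units = 4L, n_init = 25L,
                           dominance = 0.5, seed = 1L) {
  if (is.null(names(stacks))) names(stacks) <- seq_along(stacks)
  um <- lapply(stacks, stack_to_units, units = units)
  pooled <- do.call(rbind, um)
  if (nrow(unique(pooled)) < k)
    stop("k exceeds the number of distinct units", call. = FALSE)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2L, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(pooled, 2L, ctr), 2L, scl, "/")
  fit <- with_seed(seed, {
    if (k == 1L) {
      list(cluster = rep(1L, nrow(z)), centers = matrix(colMeans(z), 1L),
           tot.withinss = sum(scale(z, scale = FALSE)^2))
    } else {
      stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100L)
    }
  })
  sv <- dimnames(stacks[[1]])[[3]]
  if (is.null(sv)) sv <- paste0("S", seq_len(ncol(pooled)))
  colnames(fit$centers) <- sv
  labels <- apply(fit$centers, 1L, function(ctrd)
    paste(sv[ctrd > dominance], collapse = "/"))
  labels[labels == ""] <- "none-dominant"
  # unstack assignments back to per-date unit grids
  nr <- nrow(aggregate_blocks(stacks[[1]][, , 1], units))
  ncb <- ncol(aggregate_blocks(stacks[[1]][, , 1], units))
  per_date <- vector("list", length(stacks)); names(per_date) <- names(stacks)
  off <- 0L
  for (d in names(stacks)) {
    nu <- nrow(um[[d]])
    per_date[[d]] <- matrix(fit$cluster[off + seq_len(nu)], nr, ncb)
    off <- off + nu
  }
  structure(list(k = as.integer(k), centroids = fit$centers,
                 assignments = per_date, labels = labels,
                 wcss = fit$tot.withinss, center = ctr, scale = scl,
                 units = as.integer(units)),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  cat(sprintf("bundle_model: k = %d over %d dates, %d units each\n",
              x$k, length(x$assignments), length(x$assignments[[1]])))
  for (i in seq_len(x$k))
    cat(sprintf("  ESB%d: %s\n", i, x$labels[i]))
  invisible(x)
}

#' Per-bundle area shares per date
#'
#' @param model A [kmeans_bundles()] result (or any named list of integer
#'   label matrices under `assignments`).
#' @return Data frame: date, bundle, share (percent; sums to 100 per date).
#' @export
bundle_shares <- function(model) {
  asg <- if (inherits(model, "bundle_model")) model$assignments else model
  k <- max(unlist(asg))
  out <- do.call(rbind, lapply(names(asg), function(d) {
    n <- length(asg[[d]])
    data.frame(date = d, bundle = seq_len(k),
               share = 100 * tabulate(asg[[d]], k) / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
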