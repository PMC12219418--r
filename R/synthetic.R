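#' Configuration of a synthetic landscape scene
#'
#' Defines the ground truth from which [gen_scene()] draws a fully
#' synthetic study area: a spatially autocorrelated six-class land-use
#' mosaic, a class-conditional NDVI field and a set of driver surfaces
#' with optional planted associations to the land-use pattern.
#'
#' Default class fractions mimic the 2020 Shanxi composition (arable 37%,
#' forest 28%, grass 28%, water 1%, construction 5.5%, unused 0.5%);
#' default NDVI class means follow the usual vegetation ordering
#' (forest > grass > arable > construction > water/unused).
#'
#' @param n_rows,n_cols Grid dimensions in cells (>= 8).
#' @param cell_area Cell area in hm2.
#' @param class_fractions Six target area shares summing to 1.
#' @param patchiness Spatial-autocorrelation scale of the mosaic, in cells
#'   (Gaussian smoothing radius of the underlying random field).
#' @param ndvi_class_means Six NDVI means in `[0, 1]`, one per class.
#' @param ndvi_noise_sd NDVI noise standard deviation.
#' @param driver_specs Data frame from [driver_spec()]; default
#'   [default_driver_specs()].
#' @param seed Integer seed; all internal RNG streams are derived from it
#'   by fixed offsets.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_rows = 64, n_cols = 64, cell_area = 1,
                         class_fractions = c(0.37, 0.28, 0.28, 0.01, 0.055, 0.005),
                         patchiness = 4,
                         ndvi_class_means = c(AL = 0.55, FO = 0.85, GL = 0.70,
                                              WA = 0.15, CL = 0.25, UL = 0.10),
                         ndvi_noise_sd = 0.05,
                         driver_specs = default_driver_specs(),
                         seed = 1L) {
  if (n_rows < 8 || n_cols < 8)
    stop("grid must be at least 8x8", call. = FALSE)
  if (length(class_fractions) != 6L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must be 6 non-negative shares summing to 1",
         call. = FALSE)
  if (length(ndvi_class_means) != 6L ||
      any(ndvi_class_means < 0 | ndvi_class_means > 1))
    stop("`ndvi_class_means` must be 6 values in [0, 1]", call. = FALSE)
  if (ndvi_noise_sd < 0) stop("`ndvi_noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_area = cell_area,
    class_fractions = stats::setNames(as.numeric(class_fractions),
                                      names(land_classes())),
    patchiness = patchiness,
    ndvi_class_means = stats::setNames(as.numeric(ndvi_class_means),
                                       names(land_classes())),
    ndvi_noise_sd = ndvi_noise_sd,
    driver_specs = driver_specs,
    seed = as.integer(seed)), class = "scene_config")
}

#' Specify one synthetic driver surface
#'
#' A driver is a spatial trend surface plus white noise plus an optional
#' planted land-class association: `link` times a standardized class level
#' is added per cell, so downstream driver detection has recoverable
#' signal with known strength.
#'
#' @param name Driver name.
#' @param trend One of "smooth" (Gaussian random field), "gradient_x",
#'   "gradient_y", "radial" (distance from centre), "noise".
#' @param link Strength of the planted class association (0 = pure
#'   environment, no signal).
#' @param noise_sd White-noise standard deviation.
#' @return One-row data frame.
#' @export
driver_spec <- function(name, trend = "smooth", link = 0, noise_sd = 0.3) {
  trend <- match.arg(trend, c("smooth", "gradient_x", "gradient_y",
                              "radial", "noise"))
  data.frame(name = name, trend = trend, link = link, noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}

#' Default driver set
#'
#' Nine surfaces mirroring the usual natural + socio-economic factor set
#' (terrain, distances, climate, population, GDP). Slope and GDP carry a
#' planted association with the land-use mosaic; the remainder are
#' landscape trends without planted signal.
#'
#' @return Data frame of [driver_spec()] rows.
#' @export
default_driver_specs <- function() {
  rbind(
    driver_spec("dem",           "smooth",     link = 0.0),
    driver_spec("slope",         "smooth",     link = 0.8),
    driver_spec("dist_river",    "radial",     link = 0.0),
    driver_spec("temperature",   "gradient_y", link = 0.0),
    driver_spec("precipitation", "gradient_x", link = 0.0),
    driver_spec("dist_highway",  "radial",     link = 0.0),
    driver_spec("dist_railway",  "gradient_x", link = 0.0),
    driver_spec("pop_density",   "smooth",     link = 0.0),
    driver_spec("gdp",           "smooth",     link = 1.0))
}

# Stationary Gaussian random field on a torus: white noise smoothed with a
# Gaussian kernel of standard deviation `scale` cells via FFT convolution,
# then standardized.
gaussian_field <- function(n_rows, n_cols, scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale <= 0) return(z)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * scale^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)), inverse = TRUE)) /
    (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic scene
#'
#' Draws the land-use mosaic by thresholding a smoothed Gaussian random
#' field at the cumulative target quantiles (class shares are therefore
#' exact up to cell discreteness), the NDVI field from the
#' class-conditional normal model clamped to `[0, 1]`, and each driver
#' surface from its spec. Fully deterministic given `config$seed`.
#'
#' @param config A [scene_config()].
#' @return A `synthetic_scene` list: `landuse` ([land_grid()]), `ndvi`
#'   (matrix), `drivers` (named list of matrices), `truth` (the config).
#' @export
gen_scene <- function(config) {
  if (!inherits(config, "scene_config")) stop("need a scene_config", call. = FALSE)
  nr <- config$n_rows; nc <- config$n_cols; n <- nr * nc
  lu <- with_seed(config$seed + 101L, {
    f <- gaussian_field(nr, nc, config$patchiness)
    counts <- floor(config$class_fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {   # distribute remainder to the largest fractional parts
      fr <- config$class_fractions * n - counts
      counts[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    codes <- integer(n)
    codes[order(f)] <- rep.int(1:6, counts)
    matrix(codes, nr, nc)
  })
  ndvi <- with_seed(config$seed + 202L, {
    v <- config$ndvi_class_means[lu] +
      stats::rnorm(n, sd = config$ndvi_noise_sd)
    matrix(pmin(1, pmax(0, v)), nr, nc)
  })
  level <- as.numeric(scale(as.numeric(lu)))   # standardized class level
  specs <- config$driver_specs
  drivers <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    drivers[[s$name]] <- with_seed(config$seed + 303L + i, {
      base <- switch(s$trend,
        smooth     = gaussian_field(nr, nc, max(config$patchiness, 2)),
        gradient_x = matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc),
        gradient_y = matrix(rep(seq(-1, 1, length.out = nr), nc), nr, nc),
        radial     = {
          d <- sqrt(outer((seq_len(nr) - nr / 2)^2, (seq_len(nc) - nc / 2)^2, "+"))
          (d - mean(d)) / stats::sd(d)
        },
        noise      = matrix(stats::rnorm(n), nr, nc))
      base + s$link * matrix(level, nr, nc) +
        matrix(stats::rnorm(n, sd = s$noise_sd), nr, nc)
    })
  }
  structure(list(landuse = land_grid(lu, config$cell_area),
                 ndvi = ndvi, drivers = drivers, truth = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d cells, %d drivers (seed %d)\n",
              nrow(x$landuse), ncol(x$landuse), length(x$drivers),
              x$truth$seed))
  print(x$landuse)
  invisible(x)
}

#' Evolve a land-use grid under a transition matrix
#'
#' Each cell's destination class is drawn independently from its origin
#' class's row of the matrix, giving ground-truth transitions whose
#' expected frequencies equal the matrix entries (the sampling is
#' spatially independent so binomial statistics apply exactly).
#'
#' @param scene A `synthetic_scene` or a [land_grid()].
#' @param matrix A [transition_matrix()].
#' @param seed Integer seed.
#' @return A [land_grid()] of the same dimensions.
#' @export
evolve_scene <- function(scene, matrix, seed = 1L) {
  grid <- if (inherits(scene, "synthetic_scene")) scene$landuse else scene
  if (!inherits(grid, "land_grid")) stop("need a land_grid", call. = FALSE)
  if (!is_transition_matrix(unclass(matrix)))
    stop("`matrix` is not row-stochastic", call. = FALSE)
  p <- unclass(matrix)
  out <- unclass(grid)
  with_seed(seed, {
    for (k in 1:6) {
      idx <- which(grid == k)
      if (length(idx))
        out[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = p[k, ])
    }
  })
  land_grid(out, cell_area(grid))
}
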