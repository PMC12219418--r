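#' Land-use class codes
#'
#' The six-class legend used throughout the package: arable land (AL),
#' forest (FO), grassland (GL), water (WA), construction land (CL) and
#' unused land (UL), coded 1..6 in rasters.
#'
#' @return Named integer vector of length 6.
#' @export
land_classes <- function() {
  c(AL = 1L, FO = 2L, GL = 3L, WA = 4L, CL = 5L, UL = 6L)
}

#' Ecosystem service codes
#'
#' The eleven services of the per-unit-area value coefficient table:
#' food production (FP), material production (MP), water supply (WS),
#' gas regulation (GR), climate regulation (CR), air purification (AP),
#' water regulation (WR), soil retention (SR), nutrient cycling (NC),
#' biodiversity maintenance (BM) and aesthetic landscape (AL_s).
#'
#' @return Character vector of length 11.
#' @export
service_codes <- function() {
  c("FP", "MP", "WS", "GR", "CR", "AP", "WR", "SR", "NC", "BM", "AL_s")
}

#' Construct a categorical land-use grid
#'
#' A `land_grid` is an integer matrix of class codes 1..6 with an attached
#' cell area, the elementary raster object of the package.
#'
#' @param codes Integer matrix; every non-NA entry must be in 1..6.
#' @param cell_area Area of one cell in hm2 (default 1).
#' @return A `land_grid` object.
#' @export
land_grid <- function(codes, cell_area = 1) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix", call. = FALSE)
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  bad <- !is.na(codes) & (codes < 1L | codes > 6L)
  if (any(bad)) stop("land-use codes must lie in 1..6", call. = FALSE)
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("`cell_area` must be a single positive number", call. = FALSE)
  structure(codes, cell_area = as.numeric(cell_area), class = c("land_grid", "matrix"))
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("land_grid: %d x %d cells, cell area %g hm2\n",
              nrow(x), ncol(x), cell_area(x)))
  sh <- class_areas(x) / sum(class_areas(x))
  cat("class shares:",
      paste(sprintf("%s %.3f", names(land_classes()), sh), collapse = ", "), "\n")
  invisible(x)
}

#' Cell area of a grid
#' @param grid A `land_grid`.
#' @return Cell area in hm2.
#' @export
cell_area <- function(grid) attr(grid, "cell_area")

#' Per-class areas of a land-use grid
#'
#' @param grid A `land_grid`.
#' @return Named numeric vector (hm2), one entry per class AL..UL.
#' @export
class_areas <- function(grid) {
  counts <- tabulate(grid[!is.na(grid)], nbins = 6L)
  stats::setNames(counts * cell_area(grid), names(land_classes()))
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are not co-registered: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster with a trivial affine transform (origin 0,0);
#' integer grids are written without decimals.
#'
#' @param x Numeric matrix or `land_grid`.
#' @param path Output file path.
#' @param cellsize Cell size in map units (default 1).
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, cellsize = 1, nodata = -9999) {
  m <- unclass(x)
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", cellsize),
    sprintf("NODATA_value %g", nodata))
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_asc()] or compatible.
#' @return Numeric matrix with NODATA cells as NA; attributes `cellsize`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]])
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Aggregate a raster into coarse blocks
#'
#' Block-mean aggregation used to form the spatial units for correlation,
#' bundling and driver detection. Trailing rows/columns that do not fill a
#' complete block are dropped.
#'
#' @param x Numeric matrix.
#' @param factor Aggregation factor (cells per block side); 1 returns `x`.
#' @param fun Summary function applied per block (default `mean`).
#' @return Matrix of block summaries.
#' @export
aggregate_blocks <- function(x, factor = 1L, fun = mean) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(unclass(x))
  nr <- (nrow(x) %/% factor) * factor
  nc <- (ncol(x) %/% factor) * factor
  if (nr < factor || nc < factor)
    stop("grid smaller than one aggregation block", call. = FALSE)
  x <- unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% factor
  ci <- (seq_len(nc) - 1L) %/% factor
  out <- tapply(x, list(ri[row(x)], ci[col(x)]), fun)
  matrix(as.numeric(out), nr %/% factor, nc %/% factor)
}

#' Percent change between two values
#'
#' Standard bookkeeping helper: `100 * (later - earlier) / earlier`.
#'
#' @param earlier,later Numeric vectors (areas, values).
#' @return Percent change (positive = increase).
#' @export
percent_change <- function(earlier, later) {
  if (any(earlier == 0)) stop("`earlier` must be non-zero", call. = FALSE)
  100 * (later - earlier) / earlier
}
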