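#' Build an ecosystem service value coefficient table
#'
#' Equivalent-factor valuation: the per-unit-area value of service s on
#' land type i is `VC[s, i] = E_a * V[s, i]`, where `V` is the
#' dimensionless equivalent-factor table and `E_a` the standard unit value
#' equivalent. `E_a` is either supplied directly (yuan/hm2) or derived
#' from the study area's mean grain yield `Q` (kg/hm2) and mean grain
#' price `F` (yuan/kg) as one seventh of the grain value per hectare,
#' `E_a = Q * F / 7`.
#'
#' @param V 11 x 6 non-negative matrix of equivalent factors (rows =
#'   services, columns = land types AL..UL).
#' @param E_a Standard unit value equivalent (yuan/hm2); give either this
#'   or both `Q` and `F`.
#' @param Q,F Mean grain yield and price, used only when `E_a` is absent.
#' @return An `esv_coefficients` object: 11 x 6 matrix (yuan/hm2) with
#'   attribute `E_a`.
#' @export
build_coefficients <- function(V, E_a = NULL, Q = NULL, F_price = NULL) {
  have_ea <- !is.null(E_a)
  have_qf <- !is.null(Q) && !is.null(F_price)
  if (have_ea == have_qf)
    stop("supply exactly one of `E_a` or (`Q`, `F_price`)", call. = FALSE)
  if (!have_ea) E_a <- Q * F_price / 7
  if (!is.matrix(V) || nrow(V) != 11L || ncol(V) != 6L || any(V < 0))
    stop("`V` must be a non-negative 11 x 6 matrix", call. = FALSE)
  vc <- E_a * V
  dimnames(vc) <- list(service_codes(), names(land_classes()))
  structure(vc, E_a = E_a, class = c("esv_coefficients", "matrix"))
}

#' Read a coefficient table from CSV
#'
#' Expects the layout of the published per-unit-area table: a `service`
#' column plus six land-type columns, 11 service rows, values in yuan/hm2.
#'
#' @param path CSV file path.
#' @param E_a Standard unit equivalent recorded with the table (yuan/hm2).
#' @return An `esv_coefficients` object.
#' @export
read_esv_coefficients <- function(path, E_a = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  if (nrow(m) != 11L || ncol(m) != 6L)
    stop("coefficient table must be 11 services x 6 land types", call. = FALSE)
  rownames(m) <- df[[1]]
  m <- m[, names(land_classes())]
  storage.mode(m) <- "double"
  structure(m, E_a = E_a, class = c("esv_coefficients", "matrix"))
}

#' @export
print.esv_coefficients <- function(x, ...) {
  cat(sprintf("esv_coefficients (yuan/hm2), E_a = %s\n",
              format(attr(x, "E_a"))))
  m <- rbind(unclass(x), Total = colSums(x))
  print(round(m, 2))
  invisible(x)
}

#' Per-land-type total coefficients
#'
#' Column sums of the 11 services: the total value per hm2 of each land
#' type.
#'
#' @param coeffs An `esv_coefficients` object.
#' @return Named numeric vector of 6 totals (yuan/hm2).
#' @export
coefficient_totals <- function(coeffs) colSums(unclass(coeffs))

#' NDVI correction coefficients
#'
#' Dynamic adjustment of the equivalent-factor method: each cell's
#' correction factor is its NDVI divided by the study-area mean NDVI, so
#' the factors average to exactly 1 and reweight value toward densely
#' vegetated cells.
#'
#' @param ndvi Numeric matrix of NDVI values (NA = nodata).
#' @return An `ndvi_correction` list: `F_k` (matrix of factors) and
#'   `ndvi_mean`.
#' @export
ndvi_correction <- function(ndvi) {
  mu <- mean(ndvi, na.rm = TRUE)
  if (!is.finite(mu) || mu <= 0)
    stop("NDVI has no valid cells or non-positive mean", call. = FALSE)
  structure(list(F_k = unclass(ndvi) / mu, ndvi_mean = mu),
            class = "ndvi_correction")
}

#' Compute ecosystem service value over a land-use grid
#'
#' Static valuation (no correction) values every cell of land type i at
#' `cell_area * VC[s, i]` per service; dynamic valuation multiplies by the
#' cell's NDVI correction factor. Returns totals, per-service totals, the
#' per-cell per-service value stack and the areas used.
#'
#' @param grid A [land_grid()].
#' @param coeffs An `esv_coefficients` table.
#' @param correction Optional [ndvi_correction()] co-registered with the
#'   grid; `NULL` for the static model.
#' @return An `esv_result` list: `total` (yuan), `per_service` (11
#'   totals), `per_cell` (rows x cols x 11 array), `areas` (hm2 per class).
#' @export
compute_esv <- function(grid, coeffs, correction = NULL) {
  if (!inherits(grid, "land_grid")) stop("need a land_grid", call. = FALSE)
  f <- if (is.null(correction)) matrix(1, nrow(grid), ncol(grid))
       else correction$F_k
  stop_if_misaligned(grid, f, "grid and correction")
  vc <- unclass(coeffs)
  base <- cell_area(grid) * as.numeric(f)
  stack <- array(NA_real_, c(nrow(grid), ncol(grid), 11L),
                 dimnames = list(NULL, NULL, service_codes()))
  for (s in 1:11) stack[, , s] <- base * vc[s, ][as.numeric(grid)]
  per_service <- apply(stack, 3L, sum, na.rm = TRUE)
  structure(list(total = sum(per_service), per_service = per_service,
                 per_cell = stack, areas = class_areas(grid)),
            class = "esv_result")
}

#' @export
print.esv_result <- function(x, ...) {
  cat(sprintf("esv_result: total %.2f yuan (%.4f billion yuan)\n",
              x$total, x$total / 1e9))
  print(round(x$per_service, 2))
  invisible(x)
}

#' Contribution of land conversion to ecosystem service value change
#'
#' For every cell that changed class between the two dates, the value
#' change is `area * F_k * (VC_total_after - VC_total_before)`, aggregated
#' by transition (i -> j). Contributions are reported under three
#' normalizations: share of the net change (sign-aware, the published
#' formula), share of total gains (positive transitions only) and share of
#' total losses, because gain and loss rankings are reported separately.
#'
#' @param grid_t0,grid_t1 Co-registered [land_grid()]s.
#' @param coeffs An `esv_coefficients` table.
#' @param correction Optional [ndvi_correction()]; by default the later
#'   date's correction is the one to pass. `NULL` gives static values.
#' @return A `contribution_result` list: `table` (data frame with one row
#'   per occurring transition: from, to, area, desv, pct_net, pct_gain,
#'   pct_loss) and `desv_total` (yuan).
#' @export
transition_contribution <- function(grid_t0, grid_t1, coeffs,
                                    correction = NULL) {
  stop_if_misaligned(grid_t0, grid_t1)
  f <- if (is.null(correction)) matrix(1, nrow(grid_t0), ncol(grid_t0))
       else correction$F_k
  totals <- coefficient_totals(coeffs)
  chg <- which(unclass(grid_t0) != unclass(grid_t1))
  cls <- names(land_classes())
  if (!length(chg)) {
    tab <- data.frame(from = character(), to = character(), area = numeric(),
                      desv = numeric(), pct_net = numeric(),
                      pct_gain = numeric(), pct_loss = numeric())
    return(structure(list(table = tab, desv_total = 0),
                     class = "contribution_result"))
  }
  d <- cell_area(grid_t0) * f[chg] *
    (totals[grid_t1[chg]] - totals[grid_t0[chg]])
  key <- paste(cls[grid_t0[chg]], cls[grid_t1[chg]], sep = "-")
  desv <- tapply(d, key, sum)
  area <- tapply(rep(cell_area(grid_t0), length(chg)), key, sum)
  total <- sum(desv)
  gains <- sum(desv[desv > 0]); losses <- sum(desv[desv < 0])
  tab <- data.frame(
    from = sub("-.*", "", names(desv)), to = sub(".*-", "", names(desv)),
    area = as.numeric(area), desv = as.numeric(desv),
    pct_net = if (total != 0) 100 * as.numeric(desv) / total else NA_real_,
    pct_gain = ifelse(desv > 0 & gains > 0, 100 * as.numeric(desv) / gains, NA_real_),
    pct_loss = ifelse(desv < 0 & losses < 0, 100 * as.numeric(desv) / losses, NA_real_),
    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$desv)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, desv_total = total),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("contribution_result: net change %.2f yuan over %d transitions\n",
              x$desv_total, nrow(x$table)))
  print(utils::head(x$table, 10))
  invisible(x)
}
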