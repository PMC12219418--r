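#' Pearson correlation with p-value
#'
#' Textbook Pearson r between two series with the usual t-based two-sided
#' p-value (delegated to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two series of equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = as.numeric(ct$estimate), p = ct$p.value)
}

#' Pairwise trade-off / synergy relations across dates
#'
#' For each date's per-cell service value stack, cells are aggregated into
#' square blocks (the spatial units), and every unordered service pair is
#' correlated across units. Negative correlations are trade-offs,
#' non-negative ones synergies (r = 0 counts as synergy), and synergies
#' with `|r| >= strong_threshold` are strong synergies.
#'
#' @param stacks Named list (one element per date/scenario) of
#'   rows x cols x services arrays, e.g. `per_cell` from [compute_esv()].
#' @param units Aggregation factor in cells per block side.
#' @param strong_threshold Threshold for "strong" synergy (default 0.8).
#' @return A `relation_set` list: `table` (data frame: date, s1, s2, r, p,
#'   class), `counts` (n_total, n_negative, n_positive, n_strong) and
#'   `shares` (percentages, rounded to 2 decimals).
#' @export
relation_matrix <- function(stacks, units = 4L, strong_threshold = 0.8) {
  if (!length(stacks)) stop("no stacks supplied", call. = FALSE)
  if (is.null(names(stacks))) names(stacks) <- seq_along(stacks)
  rows <- list()
  for (d in names(stacks)) {
    st <- stacks[[d]]
    sv <- dimnames(st)[[3]]
    if (is.null(sv)) sv <- paste0("S", seq_len(dim(st)[3]))
    um <- sapply(seq_len(dim(st)[3]),
                 function(s) as.numeric(aggregate_blocks(st[, , s], units)))
    if (nrow(um) < 3L) stop("fewer than 3 spatial units", call. = FALSE)
    for (a in seq_len(ncol(um) - 1L)) for (b in (a + 1L):ncol(um)) {
      r <- if (stats::sd(um[, a]) == 0 || stats::sd(um[, b]) == 0)
        list(r = NA_real_, p = NA_real_) else pearson_cor(um[, a], um[, b])
      rows[[length(rows) + 1L]] <- data.frame(
        date = d, s1 = sv[a], s2 = sv[b], r = r$r, p = r$p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$class <- ifelse(is.na(tab$r), NA_character_,
                ifelse(tab$r < 0, "trade-off",
                 ifelse(abs(tab$r) >= strong_threshold, "strong-synergy",
                        "synergy")))
  structure(c(list(table = tab),
              relation_shares(sum(!is.na(tab$r) & tab$r < 0),
                              nrow(tab),
                              n_strong = sum(tab$class == "strong-synergy",
                                             na.rm = TRUE))),
            class = "relation_set")
}

#' Trade-off / synergy shares from relation counts
#'
#' @param n_negative Number of negative (trade-off) relations.
#' @param n_total Total relations.
#' @param n_strong Number of strong synergies (optional).
#' @return List with `counts` and `shares` (percent, 2 decimals).
#' @export
relation_shares <- function(n_negative, n_total, n_strong = NA_integer_) {
  if (n_total < 1 || n_negative < 0 || n_negative > n_total)
    stop("invalid relation counts", call. = FALSE)
  n_positive <- n_total - n_negative
  shares <- c(tradeoff = round(100 * n_negative / n_total, 2),
              synergy = round(100 * n_positive / n_total, 2),
              strong_synergy = if (is.na(n_strong)) NA_real_
                               else round(100 * n_strong / n_total, 2))
  list(counts = c(n_total = n_total, n_negative = n_negative,
                  n_positive = n_positive, n_strong = n_strong),
       shares = shares)
}

#' @export
print.relation_set <- function(x, ...) {
  cat(sprintf("relation_set: %d relations (%d dates x %d pairs)\n",
              x$counts["n_total"], length(unique(x$table$date)),
              nrow(x$table) / length(unique(x$table$date))))
  cat(sprintf("trade-off %.2f%%, synergy %.2f%%, strong synergy %.2f%%\n",
              x$shares["tradeoff"], x$shares["synergy"],
              x$shares["strong_synergy"]))
  invisible(x)
}
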