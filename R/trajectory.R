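#' Encode a four-date bundle sequence
#'
#' Positional decimal coding of a cell's bundle labels at the four dates:
#' `c1*1000 + c2*100 + c3*10 + c4`, invertible for labels in 1..3.
#'
#' @param codes Integer vector (or 4-column matrix) of labels in 1..3.
#' @return Integer code(s), e.g. `c(1,2,3,3)` -> 1233.
#' @export
encode_trajectory <- function(codes) {
  m <- if (is.matrix(codes)) codes else matrix(codes, nrow = 1L)
  if (ncol(m) != 4L) stop("need exactly 4 dates", call. = FALSE)
  if (any(!m %in% 1:3)) stop("bundle codes must be in 1..3", call. = FALSE)
  as.integer(m[, 1] * 1000L + m[, 2] * 100L + m[, 3] * 10L + m[, 4])
}

#' Decode a trajectory code
#' @param code Integer code from [encode_trajectory()].
#' @return Integer matrix with 4 columns of labels.
#' @export
decode_trajectory <- function(code) {
  m <- cbind(code %/% 1000L, (code %/% 100L) %% 10L,
             (code %/% 10L) %% 10L, code %% 10L)
  if (any(!m %in% 1:3)) stop("not a valid trajectory code", call. = FALSE)
  m
}

#' Stability metrics of a four-date sequence
#'
#' The three determination metrics: number of changes (consecutive unequal
#' pairs, 0-3), diversity (distinct labels, 1-3) and similarity (maximum
#' label multiplicity, 1-4).
#'
#' @param codes Integer vector of 4 labels (or 4-column matrix).
#' @return Named vector (or matrix) with `changes`, `diversity`,
#'   `similarity`.
#' @export
std_metrics <- function(codes) {
  m <- if (is.matrix(codes)) codes else matrix(codes, nrow = 1L)
  if (ncol(m) != 4L) stop("need exactly 4 dates", call. = FALSE)
  changes <- rowSums(m[, -1, drop = FALSE] != m[, -4, drop = FALSE])
  diversity <- apply(m, 1L, function(r) length(unique(r)))
  similarity <- apply(m, 1L, function(r) max(tabulate(r)))
  out <- cbind(changes = changes, diversity = diversity,
               similarity = similarity)
  if (!is.matrix(codes)) out[1L, ] else out
}

#' Classify a trajectory into the five stability types
#'
#' Rule set on the metric triple (changes, diversity, similarity):
#' (0,1,4) stable; (1,2,3) metastable; (1,2,2) gradual; (2,2,3) cyclic
#' (one excursion and return, e.g. 1211); every other triple is "other"
#' (this catch-all covers, among others, all three-change sequences).
#'
#' @param codes Integer vector of 4 labels, a 4-column matrix, or
#'   trajectory code integers (values > 10 are decoded).
#' @return Character class(es): "stable", "metastable", "gradual",
#'   "cyclic" or "other".
#' @export
classify_trajectory <- function(codes) {
  if (!is.matrix(codes) && all(codes > 10)) codes <- decode_trajectory(codes)
  m <- std_metrics(if (is.matrix(codes)) codes else matrix(codes, nrow = 1L))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L,
                                 dimnames = list(NULL, names(m)))
  key <- paste(m[, "changes"], m[, "diversity"], m[, "similarity"])
  cls <- c("0 1 4" = "stable", "1 2 3" = "metastable",
           "1 2 2" = "gradual", "2 2 3" = "cyclic")[key]
  cls[is.na(cls)] <- "other"
  unname(cls)
}

#' Area shares of the five trajectory types
#'
#' Classifies every cell's four-date bundle sequence and tabulates the
#' area percentage of each stability type.
#'
#' @param maps List of exactly 4 co-registered integer label matrices
#'   (bundle maps in chronological order).
#' @return Named numeric vector of percentages over the five types
#'   (sums to 100).
#' @export
trajectory_shares <- function(maps) {
  if (length(maps) != 4L) stop("need exactly 4 bundle maps", call. = FALSE)
  for (i in 2:4) stop_if_misaligned(maps[[1]], maps[[i]], "bundle maps")
  seqs <- cbind(as.integer(maps[[1]]), as.integer(maps[[2]]),
                as.integer(maps[[3]]), as.integer(maps[[4]]))
  cls <- classify_trajectory(seqs)
  lv <- c("stable", "metastable", "gradual", "cyclic", "other")
  counts <- table(factor(cls, levels = lv))
  stats::setNames(100 * as.numeric(counts) / length(cls), lv)
}
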