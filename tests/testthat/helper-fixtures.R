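# Shared fixture builders; everything is generated in code at test time.

# Gaussian blobs around given centers (rows of `centers`).
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# A three-archetype landscape: vertical bands of crop-, forest/grass- and
# water-dominated mosaics, with the band as ground-truth unit label.
make_archetype_landscape <- function(nr = 48, nc = 48, units = 4, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  third <- nc / 3
  g <- matrix(NA_integer_, nr, nc)
  for (j in seq_len(nc)) {
    p <- if (j <= third) c(0.70, 0.02, 0.08, 0.00, 0.20, 0.00)      # crop/built
    else if (j <= 2 * third) c(0.05, 0.55, 0.38, 0.00, 0.02, 0.00)  # forest/grass
    else c(0.15, 0.05, 0.25, 0.50, 0.05, 0.00)                      # water
    g[, j] <- sample.int(6L, nr, replace = TRUE, prob = p)
  }
  truth_band <- matrix(rep(cut(seq_len(nc), c(0, third, 2 * third, nc),
                               labels = FALSE), each = nr), nr, nc)
  ub <- aggregate_blocks(truth_band, units, fun = function(v)
    as.numeric(names(which.max(table(v)))))
  list(grid = land_grid(g), truth_units = round(ub))
}

# Independent brute-force trajectory classifier used as the exhaustive
# oracle: literal restatement of the five signatures, written differently
# from the package implementation (rle-based change count).
oracle_classify <- function(codes) {
  runs <- rle(codes)$lengths
  changes <- length(runs) - 1L
  diversity <- length(unique(codes))
  similarity <- max(table(codes))
  if (changes == 0 && diversity == 1 && similarity == 4) "stable"
  else if (changes == 1 && diversity == 2 && similarity == 3) "metastable"
  else if (changes == 1 && diversity == 2 && similarity == 2) "gradual"
  else if (changes == 2 && diversity == 2 && similarity == 3) "cyclic"
  else "other"
}

all_81_sequences <- function() {
  as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3))[, 4:1]
}
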