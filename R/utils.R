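# Internal geometry and image helpers.

# Cross-distance matrix between two n x 2 coordinate sets (rows = points).
.crossDist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Mean over unordered point pairs of the Euclidean distance; 0 for < 2 points.
.meanPairwise <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 2L) return(0)
  mean(stats::dist(p))
}

# Sum of each region_px x region_px block of m (partial blocks at the
# right/bottom edges allowed). Returns a small matrix of block sums.
.blockSums <- function(m, block) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ceiling(seq_len(nr) / block)
  ci <- ceiling(seq_len(nc) / block)
  rs <- rowsum(m, ri, reorder = TRUE)            # sum rows within row-blocks
  t(rowsum(t(rs), ci, reorder = TRUE))           # then columns
}

# Block index grids matching .blockSums.
.blockIndex <- function(nr, nc, block) {
  list(row = ceiling(seq_len(nr) / block), col = ceiling(seq_len(nc) / block))
}

.emptyElements <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
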