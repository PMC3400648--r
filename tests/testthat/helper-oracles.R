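# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations.

# Summed absolute forward-difference gradient of one block, with the
# differences taken on the whole plane (zero past the image edge).
bruteBlockGradient <- function(plane, rows, cols) {
  nr <- nrow(plane); nc <- ncol(plane)
  s <- 0
  for (r in rows) for (cc in cols) {
    if (cc < nc) s <- s + abs(plane[r, cc + 1] - plane[r, cc])
    if (r < nr) s <- s + abs(plane[r + 1, cc] - plane[r, cc])
  }
  s
}

# Exhaustive local-maximum search: masked pixels that are >= every pixel of
# their row and column profile within the window.
bruteLocalMax <- function(m, mask, r) {
  hits <- NULL
  nr <- nrow(m); nc <- ncol(m)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    if (mask[y, x] != 1L) next
    xs <- max(1, x - r):min(nc, x + r)
    ys <- max(1, y - r):min(nr, y + r)
    if (m[y, x] >= max(m[y, xs]) && m[y, x] >= max(m[ys, x]))
      hits <- rbind(hits, c(x - 1, y - 1, m[y, x]))
  }
  hits
}

# Plain-loop Lloyd iteration with the same conventions (lowest-id ties,
# empty clusters dropped), kept deliberately naive.
bruteKmeans <- function(elements, seeds, maxIter = 100, tol = 0.5) {
  cent <- seeds[order(seeds$id), ]
  n <- nrow(elements)
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    for (i in seq_len(n)) {
      best <- Inf; bj <- 1L
      for (j in seq_len(nrow(cent))) {
        d <- sqrt((elements[i, 1] - cent$x[j])^2 +
                    (elements[i, 2] - cent$y[j])^2)
        if (d < best) { best <- d; bj <- j }
      }
      assign[i] <- bj
    }
    keep <- sort(unique(assign))
    cent <- cent[keep, , drop = FALSE]
    assign <- match(assign, keep)
    moved <- 0
    for (j in seq_len(nrow(cent))) {
      mx <- mean(elements[assign == j, 1]); my <- mean(elements[assign == j, 2])
      moved <- max(moved, sqrt((mx - cent$x[j])^2 + (my - cent$y[j])^2))
      cent$x[j] <- mx; cent$y[j] <- my
    }
    if (moved <= tol) break
  }
  list(centroids = cent, assignment = cent$id[assign])
}

# Plain-loop silhouette with the same singleton convention.
bruteSilhouette <- function(elements, assignment) {
  n <- nrow(elements)
  labs <- unique(assignment)
  s <- numeric(n)
  if (length(labs) < 2L) return(rep(0, n))
  for (i in seq_len(n)) {
    own <- assignment[i]
    sameIdx <- setdiff(which(assignment == own), i)
    if (length(sameIdx) == 0L) { s[i] <- 0; next }
    a <- mean(sqrt((elements[sameIdx, 1] - elements[i, 1])^2 +
                     (elements[sameIdx, 2] - elements[i, 2])^2))
    b <- Inf
    for (l in setdiff(labs, own)) {
      idx <- which(assignment == l)
      b <- min(b, mean(sqrt((elements[idx, 1] - elements[i, 1])^2 +
                              (elements[idx, 2] - elements[i, 2])^2)))
    }
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  s
}

# Sequential minimum-distance assignment: repeatedly take the globally
# closest admissible (parent, child) pair.
bruteGreedyMatch <- function(a, b, radPx) {
  pairs <- NULL
  usedChild <- integer(0)
  nkids <- stats::setNames(integer(nrow(a)), as.character(a$id))
  for (pass in 1:2) {
    repeat {
      best <- Inf; bi <- NA; bj <- NA
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (b$id[j] %in% usedChild) next
        if (nkids[[as.character(a$id[i])]] != pass - 1L) next
        d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
        if (d <= radPx && (d < best ||
              (d == best && (a$id[i] < a$id[bi] ||
                 (a$id[i] == a$id[bi] && b$id[j] < b$id[bj]))))) {
          best <- d; bi <- i; bj <- j
        }
      }
      if (!is.finite(best)) break
      pairs <- rbind(pairs, data.frame(from = a$id[bi], to = b$id[bj],
                                       dist_px = best))
      usedChild <- c(usedChild, b$id[bj])
      nkids[[as.character(a$id[bi])]] <- nkids[[as.character(a$id[bi])]] + 1L
    }
  }
  pairs
}

# A ClusterState built directly from coordinates and one seed per group.
stateFromBlobs <- function(blobs, frame = 0L, px = 0.25) {
  el <- do.call(rbind, blobs)
  seeds <- data.frame(id = seq_along(blobs),
                      x = vapply(blobs, function(b) mean(b[, 1]), numeric(1)),
                      y = vapply(blobs, function(b) mean(b[, 2]), numeric(1)))
  kmeansAssign(el, seeds, frameIndex = frame, pixelSizeUm = px, quiet = TRUE)
}

# Ground-truth seeds (in-field cells at frame 0) for a simulated movie.
truthSeeds <- function(truth) {
  p0 <- truth@positions[truth@positions$frame == 0 & truth@positions$in_field, ]
  data.frame(id = p0$cell_id, x = p0$x_px, y = p0$y_px)
}
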