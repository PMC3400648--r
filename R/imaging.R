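#' Fuse focal planes into a highest-contrast composite
#'
#' Tiles the image into `regionPx` x `regionPx` blocks (partial blocks at the
#' edges allowed) and, for each block, copies in the focal plane that
#' maximizes the summed absolute gradient
#' \eqn{\sum |I(x+1,y)-I(x,y)| + |I(x,y+1)-I(x,y)|} over the block. Forward
#' differences are taken on each whole plane, with zero contribution past the
#' image edge. Ties between planes are broken towards the lowest plane index.
#'
#' @param stack a [FrameStack].
#' @param regionPx block edge length in pixels (>= 2). If larger than the
#'   image, the whole image is treated as a single region (with a warning).
#' @return a [CompositeImage].
#' @export
#' @examples
#' p1 <- matrix(0, 16, 16); p2 <- p1; p2[8, 8] <- 100
#' fuseFocalPlanes(FrameStack(planes = list(p1, p2)), regionPx = 8)
fuseFocalPlanes <- function(stack, regionPx = 32L) {
  stopifnot(is(stack, "FrameStack"))
  if (length(stack@planes) == 0L) stop("empty stack: no focal planes")
  regionPx <- as.integer(regionPx)
  if (regionPx < 2L) stop("regionPx must be >= 2")
  pl <- stack@planes
  nr <- nrow(pl[[1L]]); nc <- ncol(pl[[1L]])
  if (regionPx > max(nr, nc)) {
    warning("regionPx larger than the image; using a single whole-image region")
    regionPx <- max(nr, nc)
  }
  if (length(pl) == 1L) {
    return(CompositeImage(intensity = pl[[1L]],
                          sourcePlane = matrix(1L, nr, nc)))
  }
  # per-plane block gradient sums
  gsum <- lapply(pl, function(p) {
    gx <- cbind(abs(p[, -1, drop = FALSE] - p[, -nc, drop = FALSE]), 0)
    gy <- rbind(abs(p[-1, , drop = FALSE] - p[-nr, , drop = FALSE]), 0)
    .blockSums(gx + gy, regionPx)
  })
  nb <- dim(gsum[[1L]])
  best <- matrix(1L, nb[1], nb[2])
  bestVal <- gsum[[1L]]
  for (k in 2:length(pl)) {
    upd <- gsum[[k]] > bestVal            # strict: ties keep the lower index
    best[upd] <- k
    bestVal[upd] <- gsum[[k]][upd]
  }
  idx <- .blockIndex(nr, nc, regionPx)
  src <- best[cbind(rep(idx$row, times = nc), rep(idx$col, each = nr))]
  src <- matrix(src, nr, nc)
  comp <- matrix(0, nr, nc)
  for (k in unique(as.vector(src))) {
    sel <- src == k
    comp[sel] <- pl[[k]][sel]
  }
  CompositeImage(intensity = comp, sourcePlane = src)
}

#' Noise threshold from image statistics
#'
#' Returns \eqn{\theta = \mu + \sigma}, the image-wide mean plus standard
#' deviation of the composite intensities; the added standard deviation
#' accounts for background variability. The population standard deviation
#' (divisor n) over all pixels is used.
#'
#' @param image a [CompositeImage] or a plain intensity matrix.
#' @return the intensity threshold, a scalar in detector units.
#' @export
computeThreshold <- function(image) {
  m <- if (is(image, "CompositeImage")) image@intensity else image
  if (length(m) == 0L) stop("empty image")
  v <- as.numeric(m)
  mean(v) + sqrt(mean((v - mean(v))^2))
}

#' Binarize an image by an intensity step function
#'
#' @param image a [CompositeImage] or intensity matrix.
#' @param theta intensity threshold; negative values are clamped to 0.
#' @return an integer matrix of 0/1, 1 where intensity strictly exceeds theta.
#' @export
applyThreshold <- function(image, theta) {
  m <- if (is(image, "CompositeImage")) image@intensity else image
  theta <- max(0, theta)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > theta] <- 1L
  out
}

#' Locate binary elements as local intensity peaks
#'
#' Finds, inside the thresholded mask, pixels that are simultaneously the
#' maximum of their row profile and of their column profile within a
#' `windowPx`-wide window (the row/column cross-referencing peak rule).
#' Plateaus of equal maxima within one window yield exactly one element,
#' tie-broken to the lowest y then lowest x. Coordinates are 0-based pixels.
#'
#' @param image a [CompositeImage] or intensity matrix.
#' @param mask 0/1 matrix from [applyThreshold()].
#' @param windowPx odd window width >= 3 (default 5).
#' @param frameIndex frame number recorded in the output map.
#' @param thresholdUsed threshold recorded in the output map.
#' @return a [BinaryElementMap].
#' @export
detectPeaks <- function(image, mask, windowPx = 5L, frameIndex = 0L,
                        thresholdUsed = 0) {
  m <- if (is(image, "CompositeImage")) image@intensity else image
  windowPx <- as.integer(windowPx)
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stop("windowPx must be odd and >= 3")
  r <- (windowPx - 1L) %/% 2L
  # masked pixels are sparse: compare each candidate with its row/column
  # window neighbours directly instead of building full running-max images
  H <- nrow(m); W <- ncol(m)
  cand <- which(mask == 1L)
  if (length(cand) > 0L) {
    rowI <- ((cand - 1L) %% H) + 1L
    colI <- ((cand - 1L) %/% H) + 1L
    ok <- rep(TRUE, length(cand))
    v <- m[cand]
    for (s in c(-(r:1), 1:r)) {
      inC <- colI + s >= 1L & colI + s <= W            # row profile (x)
      ok[inC] <- ok[inC] & v[inC] >= m[cand[inC] + s * H]
      inR <- rowI + s >= 1L & rowI + s <= H            # column profile (y)
      ok[inR] <- ok[inR] & v[inR] >= m[cand[inR] + s]
    }
    cand <- cand[ok]
  }
  hits <- cbind(row = ((cand - 1L) %% H) + 1L,
                col = ((cand - 1L) %/% H) + 1L)
  if (nrow(hits) == 0L) {
    return(BinaryElementMap(frameIndex = as.integer(frameIndex),
                            elements = .emptyElements(),
                            thresholdUsed = max(0, thresholdUsed)))
  }
  vals <- m[hits]
  # raster order: lowest y (row) first, then lowest x (column)
  o <- order(hits[, 1], hits[, 2])
  hits <- hits[o, , drop = FALSE]; vals <- vals[o]
  keep <- .dedupPlateaus(hits, vals, r)
  el <- cbind(x = hits[keep, 2] - 1, y = hits[keep, 1] - 1)
  BinaryElementMap(frameIndex = as.integer(frameIndex), elements = el,
                   thresholdUsed = max(0, thresholdUsed))
}

# Collapse plateaus: candidates with exactly equal intensity connected within
# Chebyshev distance <= r keep only their first member in raster order.
# Only tied intensity values need examination, so this stays cheap.
.dedupPlateaus <- function(hits, vals, r) {
  keep <- rep(TRUE, nrow(hits))
  dupVals <- unique(vals[duplicated(vals)])
  for (v in dupVals) {
    ii <- which(vals == v)
    if (length(ii) < 2L) next
    # union by chaining in raster order
    comp <- seq_along(ii)
    for (a in 2:length(ii)) {
      for (b in 1:(a - 1)) {
        if (abs(hits[ii[a], 1] - hits[ii[b], 1]) <= r &&
            abs(hits[ii[a], 2] - hits[ii[b], 2]) <= r) {
          comp[comp == comp[a]] <- comp[b]
          break
        }
      }
    }
    for (g in unique(comp)) {
      mem <- ii[comp == g]
      if (length(mem) > 1L) keep[mem[-1L]] <- FALSE
    }
  }
  keep
}

#' One-call element detection for a frame stack
#'
#' Convenience wrapper running focal fusion, thresholding and peak detection.
#'
#' @param stack a [FrameStack].
#' @param regionPx fusion block size (default 32).
#' @param windowPx peak window (default 5).
#' @param theta optional fixed threshold; when `NULL` (default) the
#'   `mu + sigma` threshold of the composite is used.
#' @return a [BinaryElementMap] (with the composite attached as attribute
#'   `"composite"` for reuse).
#' @export
detectElements <- function(stack, regionPx = 32L, windowPx = 5L, theta = NULL) {
  comp <- fuseFocalPlanes(stack, regionPx)
  if (is.null(theta)) theta <- computeThreshold(comp)
  mask <- applyThreshold(comp, theta)
  bem <- detectPeaks(comp, mask, windowPx, frameIndex = stack@frameIndex,
                     thresholdUsed = theta)
  attr(bem, "composite") <- comp
  bem
}
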