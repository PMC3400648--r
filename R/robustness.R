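# Operational-range analysis: sweep the intensity threshold and quantify
# element counts, centroid counts and centroid displacement.

#' Threshold sweep of a single frame
#'
#' For each threshold (ascending): re-detect peaks on the fused composite,
#' proximity-validate the reference seeds (seeds with no element within
#' `removeRadiusUm` are dropped) and re-run k-means from the surviving seeds.
#' Records the element count, the validated centroid count, and each
#' reference centroid's displacement from its position at the highest
#' (cleanest) threshold. SNR is reported as `refIntensity / threshold`.
#'
#' @param stack a [FrameStack] (or a [CompositeImage]).
#' @param thresholds numeric vector, sorted ascending.
#' @param referenceSeeds data.frame with `id`, `x`, `y` (e.g. manually
#'   identified cells, or simulator truth).
#' @param regionPx,windowPx imaging parameters.
#' @param removeRadiusUm seed validation radius (default 12.5 um).
#' @param pixelSizeUm micrometres per pixel.
#' @param refIntensity reference spot peak intensity for the SNR column
#'   (default: the composite maximum).
#' @return list of class `SweepResult`: `summary` (data.frame `threshold`,
#'   `n_elements`, `n_centroids`, `mean_displacement_um`, `snr`),
#'   `displacement` (threshold x seed matrix, um), `perSeedElements`
#'   (threshold x seed counts of elements nearest each reference seed), and
#'   `thresholds`.
#' @export
thresholdSweep <- function(stack, thresholds, referenceSeeds, regionPx = 32L,
                           windowPx = 5L, removeRadiusUm = 12.5,
                           pixelSizeUm = 0.25, refIntensity = NULL) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  comp <- if (is(stack, "CompositeImage")) stack
    else fuseFocalPlanes(stack, regionPx)
  if (min(thresholds) < min(comp@intensity))
    warning("threshold below the image minimum: every pixel passes the filter")
  if (is.null(refIntensity)) refIntensity <- max(comp@intensity)
  seeds <- .asSeedFrame(referenceSeeds)
  k <- nrow(seeds)
  nT <- length(thresholds)
  nEl <- integer(nT); nCe <- integer(nT)
  posX <- matrix(NA_real_, nT, k); posY <- matrix(NA_real_, nT, k)
  perSeed <- matrix(0L, nT, k,
                    dimnames = list(NULL, as.character(seeds$id)))
  for (i in seq_len(nT)) {
    th <- thresholds[i]
    mask <- applyThreshold(comp, th)
    bem <- detectPeaks(comp, mask, windowPx, thresholdUsed = th)
    el <- bem@elements
    nEl[i] <- nrow(el)
    if (nrow(el) == 0L) next
    # elements per reference seed (nearest-seed census)
    dref <- .crossDist(el, cbind(seeds$x, seeds$y))
    nearest <- max.col(-dref, ties.method = "first")
    cnt <- tabulate(nearest, nbins = k)
    perSeed[i, ] <- cnt
    # proximity validation, then k-means from the surviving reference seeds
    removePx <- removeRadiusUm / pixelSizeUm
    ok <- apply(dref, 2, min) <= removePx
    if (!any(ok)) next
    st <- suppressWarnings(
      kmeansAssign(el, seeds[ok, , drop = FALSE], pixelSizeUm = pixelSizeUm,
                   quiet = TRUE, computeSilhouette = FALSE))
    nCe[i] <- nrow(st@centroids)
    j <- match(st@centroids$id, seeds$id)
    posX[i, j] <- st@centroids$x
    posY[i, j] <- st@centroids$y
  }
  ref <- nT   # displacement reference: highest threshold in the sweep
  disp <- sqrt((posX - matrix(posX[ref, ], nT, k, byrow = TRUE))^2 +
                 (posY - matrix(posY[ref, ], nT, k, byrow = TRUE))^2) *
    pixelSizeUm
  colnames(disp) <- as.character(seeds$id)
  summary <- data.frame(threshold = thresholds, n_elements = nEl,
                        n_centroids = nCe,
                        mean_displacement_um = rowMeans(disp, na.rm = TRUE),
                        snr = refIntensity / thresholds)
  summary$mean_displacement_um[is.nan(summary$mean_displacement_um)] <- NA
  structure(list(summary = summary, displacement = disp,
                 perSeedElements = perSeed, thresholds = thresholds),
            class = "SweepResult")
}

#' Minimum element requirements across a sweep
#'
#' From a [thresholdSweep()] result, reports the smallest total element count
#' (and its threshold) at which every reference centroid still has at least
#' one element assigned, and the smallest count at which every centroid keeps
#' at least `m` elements. Returns NA when a condition is never satisfied in
#' the sweep.
#'
#' @param sweep a `SweepResult`.
#' @param m the per-centroid element requirement for the relaxed criterion
#'   (default 5).
#' @param trueCentroidCount optionally restrict the census to the first
#'   `trueCentroidCount` reference seeds.
#' @return data.frame with one row per criterion: `min_per_centroid`,
#'   `n_elements`, `threshold`, `n_centroids_covered`.
#' @export
minimumElementsAnalysis <- function(sweep, m = 5L, trueCentroidCount = NULL) {
  cnt <- sweep$perSeedElements
  if (!is.null(trueCentroidCount))
    cnt <- cnt[, seq_len(trueCentroidCount), drop = FALSE]
  nEl <- sweep$summary$n_elements
  th <- sweep$thresholds
  pick <- function(minPer) {
    ok <- apply(cnt, 1, function(r) all(r >= minPer))
    if (!any(ok)) return(data.frame(min_per_centroid = minPer,
                                    n_elements = NA_integer_,
                                    threshold = NA_real_,
                                    n_centroids_covered = NA_integer_))
    i <- which(ok)[which.min(nEl[ok])]
    data.frame(min_per_centroid = minPer, n_elements = nEl[i],
               threshold = th[i],
               n_centroids_covered = sum(cnt[i, ] >= minPer))
  }
  rbind(pick(1L), pick(as.integer(m)))
}

#' Plot a threshold sweep (calibration and operational-range curves)
#'
#' Two stacked panels: element count against threshold (calibration curve),
#' and centroid count plus per-cell displacement against element count
#' (operational range).
#'
#' @param sweep a `SweepResult`.
#' @param trueCount optional horizontal reference line for the true cell
#'   count.
#' @return invisibly, `NULL`; called for the plot side effect.
#' @export
plotSweep <- function(sweep, trueCount = NULL) {
  s <- sweep$summary
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  graphics::plot(s$threshold, s$n_elements, type = "b", log = "y",
                 xlab = "intensity threshold", ylab = "binary elements")
  graphics::plot(s$n_elements, s$n_centroids, type = "b",
                 xlab = "binary elements", ylab = "centroids")
  if (!is.null(trueCount))
    graphics::abline(h = trueCount, lty = 2, col = "red")
  d <- sweep$displacement
  if (ncol(d) > 0L) {
    graphics::par(new = TRUE)
    cols <- grDevices::rainbow(ncol(d))
    graphics::matplot(s$n_elements, d, type = "l", axes = FALSE, xlab = "",
                      ylab = "", col = cols, lty = 1)
    graphics::axis(4)
    graphics::mtext("displacement (um)", side = 4, line = 2.5)
  }
  invisible(NULL)
}
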