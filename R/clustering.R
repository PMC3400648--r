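# Seeded k-means identification of cells from binary element maps, with the
# seed creation/removal rules, silhouette validation and the split test.

.asSeedFrame <- function(seeds) {
  if (is.data.frame(seeds)) {
    if (!all(c("x", "y") %in% names(seeds))) stop("seeds need x and y columns")
    if (is.null(seeds$id)) seeds$id <- seq_len(nrow(seeds))
    out <- seeds[, c("id", "x", "y")]
  } else {
    seeds <- matrix(as.numeric(seeds), ncol = 2)
    out <- data.frame(id = seq_len(nrow(seeds)), x = seeds[, 1], y = seeds[, 2])
  }
  out[order(out$id), , drop = FALSE]  # lowest-id tie-breaks in which.min
}

# Build a validated ClusterState from a converged assignment.
.makeClusterState <- function(elements, cent, assignIds, frameIndex,
                              pixelSizeUm, computeSilhouette = TRUE) {
  ids <- cent$id
  n <- integer(length(ids)); sepUm <- numeric(length(ids))
  cdistUm <- numeric(length(ids))
  for (j in seq_along(ids)) {
    mem <- elements[assignIds == ids[j], , drop = FALSE]
    n[j] <- nrow(mem)
    sepUm[j] <- .meanPairwise(mem) * pixelSizeUm
    cdistUm[j] <- if (n[j] > 0L)
      mean(sqrt((mem[, 1] - cent$x[j])^2 + (mem[, 2] - cent$y[j])^2)) *
        pixelSizeUm else 0
  }
  sil <- if (computeSilhouette && length(ids) >= 2L)
    silhouetteScores(elements, assignIds)$meanScore else 0
  ClusterState(
    frameIndex = as.integer(frameIndex), elements = elements,
    centroids = data.frame(id = ids, x = cent$x, y = cent$y, n_elements = n,
                           mean_separation_um = sepUm,
                           mean_centroid_dist_um = cdistUm),
    assignment = as.integer(assignIds), silhouetteMean = sil,
    pixelSizeUm = pixelSizeUm)
}

#' Seeded k-means clustering of binary elements
#'
#' Iterates assignment-to-nearest-centroid and centroid recomputation (the
#' within-cluster mean) until no centroid moves more than `tolPx` or `maxIter`
#' is reached. Seeds keep their ids through the iteration; nearest-seed ties
#' break towards the lowest centroid id; clusters that lose all elements are
#' dropped with a warning.
#'
#' @param elements n x 2 matrix of element coordinates (columns x, y, pixels).
#' @param seeds k x 2 matrix, or data.frame with columns `id`, `x`, `y`.
#' @param maxIter maximum Lloyd iterations (default 100).
#' @param tolPx convergence tolerance on centroid movement (default 0.5 px).
#' @param frameIndex frame number stored in the result.
#' @param pixelSizeUm micrometres per pixel for the derived columns.
#' @param quiet suppress the empty-cluster warning.
#' @param computeSilhouette compute the mean silhouette of the converged
#'   state (default TRUE; the silhouette needs the full element distance
#'   matrix, which bulk re-analyses such as threshold sweeps skip).
#' @return a [ClusterState].
#' @export
kmeansAssign <- function(elements, seeds, maxIter = 100L, tolPx = 0.5,
                         frameIndex = 0L, pixelSizeUm = 0.25, quiet = FALSE,
                         computeSilhouette = TRUE) {
  elements <- matrix(as.numeric(elements), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(elements) == 0L) stop("no elements to cluster")
  cent <- .asSeedFrame(seeds)
  if (nrow(cent) == 0L) stop("no seeds")
  dropped <- FALSE
  assign <- NULL
  for (it in seq_len(maxIter)) {
    d <- .crossDist(elements, cbind(cent$x, cent$y))
    nearest <- max.col(-d, ties.method = "first")   # lowest id wins ties
    assign <- cent$id[nearest]
    sizes <- tabulate(nearest, nbins = nrow(cent))
    if (any(sizes == 0L)) {
      dropped <- TRUE
      keep <- sizes > 0L
      cent <- cent[keep, , drop = FALSE]
      d <- d[, keep, drop = FALSE]
      nearest <- max.col(-d, ties.method = "first")
      assign <- cent$id[nearest]
    }
    newx <- tapply(elements[, 1], factor(nearest, seq_len(nrow(cent))), mean)
    newy <- tapply(elements[, 2], factor(nearest, seq_len(nrow(cent))), mean)
    move <- sqrt((newx - cent$x)^2 + (newy - cent$y)^2)
    cent$x <- as.numeric(newx); cent$y <- as.numeric(newy)
    if (max(move) <= tolPx) break
  }
  if (dropped && !quiet)
    warning("empty cluster(s) dropped during k-means", call. = FALSE)
  .makeClusterState(elements, cent, assign, frameIndex, pixelSizeUm,
                    computeSilhouette)
}

#' Silhouette scores of a clustering
#'
#' For element i, `a_i` is the mean distance to the other members of its
#' cluster and `b_i` the smallest, over the other clusters, of the mean
#' distance to that cluster's members; the silhouette is
#' `s_i = (b_i - a_i) / max(a_i, b_i)`. Values near 1 mean the element fits
#' its cluster well. Singleton cluster members score 0 by convention; a
#' clustering with a single cluster scores 0 overall (with a warning).
#'
#' @param elements n x 2 coordinate matrix.
#' @param assignment vector of cluster labels, one per element.
#' @return list with `scores` (per element) and `meanScore`.
#' @export
silhouetteScores <- function(elements, assignment) {
  elements <- matrix(as.numeric(elements), ncol = 2)
  n <- nrow(elements)
  stopifnot(length(assignment) == n)
  labs <- unique(assignment)
  if (length(labs) < 2L) {
    warning("silhouette undefined for a single cluster; returning 0",
            call. = FALSE)
    return(list(scores = rep(0, n), meanScore = 0))
  }
  d <- as.matrix(stats::dist(elements))
  # column sums of distances into each cluster, per element
  sums <- vapply(labs, function(l)
    rowSums(d[, assignment == l, drop = FALSE]), numeric(n))
  sizes <- vapply(labs, function(l) sum(assignment == l), numeric(1))
  own <- match(assignment, labs)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nc <- sizes[own[i]]
    if (nc <= 1) { scores[i] <- 0; next }
    a <- sums[i, own[i]] / (nc - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    m <- max(a, b)
    scores[i] <- if (m > 0) (b - a) / m else 0
  }
  list(scores = scores, meanScore = mean(scores))
}

#' Seed set for the next frame from the previous cluster state
#'
#' Seeds start as the previous frame's centroids. Any element farther than
#' `spawnRadiusUm` from every seed spawns a new seed at its own position
#' (elements processed in order; freshly spawned seeds count for subsequent
#' elements) -- this admits both cells entering the field and sporadic rogue
#' elements, which later validation distinguishes. Any seed with no element
#' within `removeRadiusUm` is then removed (clusters that left the field, or
#' noise seeds whose elements vanished).
#'
#' @param prev [ClusterState] of frame t-1, or a seed data.frame.
#' @param elements element coordinates of frame t (pixels).
#' @param spawnRadiusUm new-seed distance rule (default 30 um = 120 px at
#'   0.25 um/px).
#' @param removeRadiusUm proximity-validation radius (default 12.5 um = 50 px).
#' @param pixelSizeUm micrometres per pixel.
#' @param nextId first id given to newly spawned seeds (default: max + 1).
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
updateSeeds <- function(prev, elements, spawnRadiusUm = 30,
                        removeRadiusUm = 12.5, pixelSizeUm = 0.25,
                        nextId = NULL) {
  seeds <- if (is(prev, "ClusterState"))
    prev@centroids[, c("id", "x", "y")] else .asSeedFrame(prev)
  elements <- matrix(as.numeric(elements), ncol = 2)
  spawnPx <- spawnRadiusUm / pixelSizeUm
  removePx <- removeRadiusUm / pixelSizeUm
  if (is.null(nextId)) nextId <- if (nrow(seeds)) max(seeds$id) + 1L else 1L
  for (i in seq_len(nrow(elements))) {
    if (nrow(seeds) == 0L ||
        min(sqrt((seeds$x - elements[i, 1])^2 +
                 (seeds$y - elements[i, 2])^2)) > spawnPx) {
      seeds <- rbind(seeds, data.frame(id = nextId, x = elements[i, 1],
                                       y = elements[i, 2]))
      nextId <- nextId + 1L
    }
  }
  if (nrow(seeds) > 0L && nrow(elements) > 0L) {
    dmin <- apply(.crossDist(cbind(seeds$x, seeds$y), elements), 1, min)
    seeds <- seeds[dmin <= removePx, , drop = FALSE]
  } else {
    seeds <- seeds[integer(0), , drop = FALSE]
  }
  rownames(seeds) <- NULL
  seeds
}

# Extra seed offsetPx away from a centroid, towards its farthest member.
.splitSeed <- function(state, cid, offsetPx) {
  cent <- state@centroids[state@centroids$id == cid, ]
  mem <- state@elements[state@assignment == cid, , drop = FALSE]
  v <- cbind(mem[, 1] - cent$x, mem[, 2] - cent$y)
  dd <- sqrt(rowSums(v^2))
  j <- which.max(dd)
  dir <- if (dd[j] > 0) v[j, ] / dd[j] else c(1, 0)
  c(cent$x + offsetPx * dir[1], cent$y + offsetPx * dir[2])
}

#' Division-aware cluster split test
#'
#' A cluster whose mean pairwise element separation exceeds
#' `splitThresholdUm` (~1.5 cell diameters) is likely to contain a completed
#' division: k-means is rerun with one extra seed placed `offsetPx` pixels
#' from the suspect centroid, in the direction of the cluster's farthest
#' member, and the split is accepted only if the mean silhouette improves.
#' With `centroidId = NULL` the test iterates over all clusters until none
#' triggers.
#'
#' @param state a [ClusterState].
#' @param centroidId test only this cluster (default: all).
#' @param splitThresholdUm mean-separation trigger (default 15 um).
#' @param offsetPx displacement of the extra seed (default 10 px).
#' @param force attempt the split regardless of the separation trigger
#'   (used when a mitotic curve has already confirmed a division).
#' @param requireImprovement accept the split only if the mean silhouette
#'   improves (the first-pass rule). A curve-confirmed mitotic re-split is
#'   applied unconditionally (`FALSE`): the contraction-expansion signature
#'   itself is the evidence that two daughters exist.
#' @param maxIter,tolPx k-means controls.
#' @param nextId id for the first added centroid (default: max + 1).
#' @return a [ClusterState] (possibly unchanged).
#' @export
splitTest <- function(state, centroidId = NULL, splitThresholdUm = 15,
                      offsetPx = 10, force = FALSE,
                      requireImprovement = TRUE, maxIter = 100L,
                      tolPx = 0.5, nextId = NULL) {
  stopifnot(is(state, "ClusterState"))
  if (is.null(nextId)) nextId <- max(state@centroids$id) + 1L
  tested <- character(0)
  repeat {
    cent <- state@centroids
    if (is.null(centroidId)) {
      trig <- cent$id[cent$n_elements >= 2L &
                        cent$mean_separation_um > splitThresholdUm]
    } else {
      cand <- cent[cent$id == centroidId, ]
      if (nrow(cand) == 0L || cand$n_elements < 2L) return(state)
      trig <- if (force || cand$mean_separation_um > splitThresholdUm)
        centroidId else integer(0)
    }
    sig <- paste(trig, cent$n_elements[match(trig, cent$id)])
    trig <- trig[!(sig %in% tested)]
    if (length(trig) == 0L) return(state)
    cid <- trig[1L]
    tested <- c(tested,
                paste(cid, cent$n_elements[match(cid, cent$id)]))
    extra <- .splitSeed(state, cid, offsetPx)
    seeds <- rbind(cent[, c("id", "x", "y")],
                   data.frame(id = nextId, x = extra[1], y = extra[2]))
    cand <- suppressWarnings(
      kmeansAssign(state@elements, seeds, maxIter = maxIter, tolPx = tolPx,
                   frameIndex = state@frameIndex,
                   pixelSizeUm = state@pixelSizeUm, quiet = TRUE))
    accepted <- cand@silhouetteMean > state@silhouetteMean ||
      (!requireImprovement &&
         nrow(cand@centroids) > nrow(state@centroids))
    if (accepted) {
      state <- cand
      nextId <- nextId + 1L
      tested <- character(0)   # memberships changed; re-test everything
      if (!is.null(centroidId)) return(state)
    } else if (!is.null(centroidId)) {
      return(state)
    }
  }
}

#' Automatic first-frame seeding
#'
#' Groups elements by single-linkage connected components at a linking radius
#' (default 30 um, three cell diameters) and seeds one centroid per component
#' at the component mean. An alternative to a manually supplied seed file for
#' the initial timeframe.
#'
#' @param elements n x 2 element coordinates (pixels).
#' @param linkRadiusUm single-linkage radius (default 30 um).
#' @param pixelSizeUm micrometres per pixel.
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
autoSeeds <- function(elements, linkRadiusUm = 30, pixelSizeUm = 0.25) {
  elements <- matrix(as.numeric(elements), ncol = 2)
  n <- nrow(elements)
  if (n == 0L) return(data.frame(id = integer(0), x = numeric(0),
                                 y = numeric(0)))
  r <- linkRadiusUm / pixelSizeUm
  d <- as.matrix(stats::dist(elements))
  adj <- d <= r
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  data.frame(
    id = seq_len(max(comp)),
    x = as.numeric(tapply(elements[, 1], comp, mean)),
    y = as.numeric(tapply(elements[, 2], comp, mean)))
}
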