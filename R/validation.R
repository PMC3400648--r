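# Evaluation of pipeline output against simulator ground truth.

#' Division detection accuracy against ground truth
#'
#' Matches detected division events to true divisions by the frame of the
#' contraction minimum (within `toleranceFrames`) and the mother's position
#' (within one cell diameter). The census follows the conditions under which
#' the mitotic signature is defined at all: mothers carrying at least
#' `minVesicles` vesicles, dividing at least `borderUm` inside the field (a
#' border-truncated cloud is not fully observable), and no earlier than
#' `minObservableFrame` (a baseline-referenced detector cannot see a
#' contraction that precedes any baseline). Detected events whose mother sits
#' within `borderUm` of the border are likewise excluded; detected events
#' matching a true division of a smaller mother count as correct detections
#' (they are real divisions) but are outside the recall census.
#'
#' @param result a [runPipeline()] result.
#' @param truth the [GroundTruth] of the simulated movie.
#' @param toleranceFrames matching tolerance on the frame of minimum
#'   (default 3 frames).
#' @param minVesicles recall census: minimum mother vesicle count (default 16).
#' @param borderUm census margin from the field border (default 10 um).
#' @param minObservableFrame earliest observable division (default 18 frames:
#'   baseline window + contraction).
#' @param endMarginFrames divisions closer than this to the end of the movie
#'   (default 8 frames) are excluded from the census: confirmation is a
#'   post-minimum crossing of the baseline, which takes the daughters tens of
#'   minutes of separation the movie no longer shows.
#' @param matchRadiusUm spatial matching radius (default 10 um).
#' @return list with `recall`, `precision`, `nTrue`, `nDetected`, `nMatched`,
#'   `nFalse`, and the matched event table.
#' @export
divisionAccuracy <- function(result, truth, toleranceFrames = 3L,
                             minVesicles = 16L, borderUm = 10,
                             minObservableFrame = 18L, endMarginFrames = 8L,
                             matchRadiusUm = 10) {
  cfg <- truth@config
  px <- cfg@pixelSizeUm
  fw <- cfg@fieldUm[1]; fh <- cfg@fieldUm[2]
  interior <- function(xu, yu)
    xu >= borderUm & xu <= fw - borderUm & yu >= borderUm & yu <= fh - borderUm
  tc <- truth@cells
  pos <- truth@positions
  motherPos <- function(cellId, frame) {
    p <- pos[pos$cell_id == cellId & pos$frame == frame, ]
    if (nrow(p) == 0L) c(NA, NA) else c(p$x_px[1], p$y_px[1])
  }
  allTrue <- tc[!is.na(tc$division_frame), , drop = FALSE]
  allTrue$x <- NA_real_; allTrue$y <- NA_real_
  for (i in seq_len(nrow(allTrue))) {
    xy <- motherPos(allTrue$cell_id[i], allTrue$end_frame[i])
    allTrue$x[i] <- xy[1]; allTrue$y[i] <- xy[2]
  }
  allTrue <- allTrue[!is.na(allTrue$x), , drop = FALSE]
  lastFrame <- max(pos$frame)
  census <- allTrue$n_vesicles >= minVesicles &
    interior(allTrue$x * px, allTrue$y * px) &
    allTrue$division_frame >= minObservableFrame &
    allTrue$division_frame <= lastFrame - endMarginFrames

  nd <- result$trackGraph@nodes
  div <- result$divisions
  if (nrow(div) > 0L) {
    pn <- t(vapply(seq_len(nrow(div)), function(i) {
      r <- nd[nd$track_id == div$parent_track[i] &
                nd$frame == div$frame_confirmed[i] - 1L, ]
      c(r$x[1], r$y[1])
    }, numeric(2)))
    keep <- interior(pn[, 1] * px, pn[, 2] * px)
    div <- div[keep, , drop = FALSE]
    pn <- pn[keep, , drop = FALSE]
  } else pn <- matrix(numeric(0), ncol = 2)

  used <- integer(0)
  matchedCensus <- 0L
  matchedAny <- 0L
  rows <- list()
  for (i in seq_len(nrow(div))) {
    cand <- which(abs(allTrue$division_frame - div$frame_min[i]) <=
                    toleranceFrames & !(allTrue$cell_id %in% used))
    hit <- NA_integer_
    for (j in cand) {
      if (sqrt((allTrue$x[j] - pn[i, 1])^2 +
                 (allTrue$y[j] - pn[i, 2])^2) * px < matchRadiusUm) {
        hit <- j; break
      }
    }
    if (!is.na(hit)) {
      used <- c(used, allTrue$cell_id[hit])
      matchedAny <- matchedAny + 1L
      if (census[hit]) matchedCensus <- matchedCensus + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        true_cell = allTrue$cell_id[hit],
        true_frame = allTrue$division_frame[hit],
        detected_frame_min = div$frame_min[i], in_census = census[hit])
    }
  }
  nTrue <- sum(census)
  nDet <- nrow(div)
  list(recall = if (nTrue > 0) matchedCensus / nTrue else NA_real_,
       precision = if (nDet > 0) matchedAny / nDet else NA_real_,
       nTrue = nTrue, nDetected = nDet, nMatched = matchedCensus,
       nFalse = nDet - matchedAny,
       matches = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Lineage topology agreement for non-contacting lineages
#'
#' A true lineage (the progeny tree of one frame-0 cell) is non-contacting if
#' no member ever comes within `contactUm` (one cell diameter: physical
#' contact) of another cell -- including a sibling, once both are past the
#' post-division separation window. For each such lineage whose members stay
#' in the field, the detected lineage rooted at the matching frame-0 cell
#' must reproduce the topology: same number of cells, and a one-to-one match
#' of division times within `toleranceFrames`.
#'
#' @param result a [runPipeline()] result.
#' @param truth the [GroundTruth].
#' @param contactUm contact distance (default 10 um, the cell diameter).
#' @param toleranceFrames division-time tolerance (default 3).
#' @return list with `nLineages`, `nMatched`, and a per-lineage data.frame.
#' @export
lineageAccuracy <- function(result, truth, contactUm = 10,
                            toleranceFrames = 3L) {
  cfg <- truth@config
  px <- cfg@pixelSizeUm
  tc <- truth@cells
  pos <- truth@positions
  # assign every true cell to its founding progenitor
  root <- stats::setNames(tc$cell_id, tc$cell_id)
  repeat {
    p <- tc$parent_id[match(root, tc$cell_id)]
    done <- is.na(p)
    if (all(done)) break
    root[!done] <- p[!done]
  }
  pos$root <- root[as.character(pos$cell_id)]
  frames <- sort(unique(pos$frame))
  birth <- stats::setNames(tc$birth_frame, tc$cell_id)
  badRoots <- integer(0)
  for (f in frames) {
    p <- pos[pos$frame == f, ]
    if (nrow(p) < 2L) next
    d <- .crossDist(cbind(p$x_px, p$y_px), cbind(p$x_px, p$y_px)) * px
    other <- outer(p$root, p$root, "!=")
    # within a lineage, siblings only count as contact once both are past
    # their post-division separation window
    settled <- birth[as.character(p$cell_id)] + 18L <= f
    same <- !other & outer(settled, settled, "&")
    diag(same) <- FALSE
    tooClose <- d < contactUm & (other | same)
    badRoots <- union(badRoots, unique(p$root[rowSums(tooClose) > 0]))
  }
  progenitors <- tc$cell_id[is.na(tc$parent_id) & tc$birth_frame == 0L]
  good <- setdiff(progenitors, badRoots)
  # also require the whole lineage to stay in the field (observable)
  inField <- tapply(pos$in_field, pos$root, all)
  good <- good[as.logical(inField[as.character(good)])]

  lin <- result$lineage
  cl <- lin@cells
  div <- result$divisions
  out <- list()
  for (g in good) {
    p0 <- pos[pos$cell_id == g & pos$frame == 0L, ]
    if (nrow(p0) == 0L) next
    cand <- cl[is.na(cl$parent_id) & cl$birth_frame == 0L, ]
    if (nrow(cand) == 0L) next
    j <- which.min((cand$birth_x - p0$x_px)^2 + (cand$birth_y - p0$y_px)^2)
    if (sqrt((cand$birth_x[j] - p0$x_px)^2 +
               (cand$birth_y[j] - p0$y_px)^2) * px > 10) next
    # detected subtree
    ids <- cand$cell_id[j]
    repeat {
      more <- cl$cell_id[!is.na(cl$parent_id) & cl$parent_id %in% ids &
                           !(cl$cell_id %in% ids)]
      if (length(more) == 0L) break
      ids <- c(ids, more)
    }
    subTracks <- lin@trackMap$track_id[lin@trackMap$cell_id %in% ids]
    detDiv <- sort(div$frame_min[div$parent_track %in% subTracks])
    trueIds <- tc$cell_id[root[as.character(tc$cell_id)] == g]
    trueDiv <- sort(tc$division_frame[tc$cell_id %in% trueIds &
                                        !is.na(tc$division_frame)])
    okCount <- length(detDiv) == length(trueDiv) &&
      length(ids) == length(trueIds)
    okTimes <- okCount && (length(trueDiv) == 0L ||
                             all(abs(detDiv - trueDiv) <= toleranceFrames))
    out[[length(out) + 1L]] <- data.frame(
      progenitor = g, n_true_cells = length(trueIds),
      n_detected_cells = length(ids), n_true_divisions = length(trueDiv),
      n_detected_divisions = length(detDiv), topology_match = okTimes)
  }
  df <- if (length(out)) do.call(rbind, out) else NULL
  list(nLineages = length(out),
       nMatched = if (length(out)) sum(df$topology_match) else 0L,
       perLineage = df)
}
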