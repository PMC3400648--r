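# Lineage trees, motility vectors and population statistics.

#' Build a lineage tree from tracks and confirmed divisions
#'
#' One lineage cell per biological cell. Track bifurcations confirmed by a
#' division event become mother-daughter edges. Bifurcations without a
#' confirming event (e.g. a cell entering the field splitting off a
#' neighbour's cluster) are reconciled: the child track nearest the parent's
#' last position continues the same cell, the other child becomes a new
#' progenitor. Cells ending before the last frame without dividing are
#' labelled `"lost"`, others `"movie_end"`.
#'
#' @param trackGraph a [TrackGraph].
#' @param divisions data.frame of division events with columns
#'   `parent_track`, `daughter_a`, `daughter_b` (track ids), `frame_min`,
#'   `frame_confirmed`, `baseline_um`, `minimum_um` (zero rows allowed).
#' @param lastFrame final frame index of the movie (default: max node frame).
#' @return a [LineageTree].
#' @export
buildLineage <- function(trackGraph, divisions = NULL, lastFrame = NULL) {
  trk <- trackGraph@tracks
  nd <- trackGraph@nodes
  if (is.null(lastFrame)) lastFrame <- max(nd$frame)
  if (is.null(divisions) || nrow(divisions) == 0L) {
    divisions <- data.frame(parent_track = integer(0), daughter_a = integer(0),
                            daughter_b = integer(0), frame_min = integer(0),
                            frame_confirmed = integer(0),
                            baseline_um = numeric(0), minimum_um = numeric(0))
  }
  if (nrow(divisions) > 0L &&
      !all(c(divisions$parent_track, divisions$daughter_a,
             divisions$daughter_b) %in% trk$track_id))
    stop("division references a track id absent from the track graph")
  childrenOf <- split(trk$track_id[!is.na(trk$parent_track_id)],
                      trk$parent_track_id[!is.na(trk$parent_track_id)])
  nodePos <- function(tid, frame) {
    r <- nd[nd$track_id == tid & nd$frame == frame, ]
    c(r$x[1], r$y[1])
  }
  cellsDf <- data.frame()
  trackMap <- data.frame(track_id = integer(0), cell_id = integer(0))
  nextCell <- 1L
  # walk each root: a cell is a chain of tracks
  queue <- lapply(trk$track_id[is.na(trk$parent_track_id)],
                  function(t) list(track = t, parent = NA_integer_))
  while (length(queue) > 0L) {
    job <- queue[[1L]]; queue <- queue[-1L]
    cellId <- nextCell; nextCell <- nextCell + 1L
    tid <- job$track
    birth <- trk$start_frame[trk$track_id == tid]
    bp <- nodePos(tid, birth)
    repeat {
      trackMap <- rbind(trackMap,
                        data.frame(track_id = tid, cell_id = cellId))
      endF <- trk$end_frame[trk$track_id == tid]
      kids <- childrenOf[[as.character(tid)]]
      if (is.null(kids) || length(kids) == 0L) {
        reason <- if (endF >= lastFrame) "movie_end" else "lost"
        ep <- nodePos(tid, endF)
        cellsDf <- rbind(cellsDf, data.frame(
          cell_id = cellId, parent_id = job$parent, birth_frame = birth,
          end_frame = endF, end_reason = reason,
          birth_x = bp[1], birth_y = bp[2], end_x = ep[1], end_y = ep[2]))
        break
      }
      div <- divisions[divisions$parent_track == tid, , drop = FALSE]
      if (nrow(div) > 0L) {
        ep <- nodePos(tid, endF)
        cellsDf <- rbind(cellsDf, data.frame(
          cell_id = cellId, parent_id = job$parent, birth_frame = birth,
          end_frame = endF, end_reason = "division",
          birth_x = bp[1], birth_y = bp[2], end_x = ep[1], end_y = ep[2]))
        for (k in kids)
          queue <- c(queue, list(list(track = k, parent = cellId)))
        break
      }
      # unconfirmed bifurcation: nearest child continues this cell
      ep <- nodePos(tid, endF)
      if (length(kids) == 1L) {
        tid <- kids
        next
      }
      starts <- vapply(kids, function(k)
        sqrt(sum((nodePos(k, trk$start_frame[trk$track_id == k]) - ep)^2)),
        numeric(1))
      keep <- kids[which.min(starts)]
      other <- setdiff(kids, keep)
      for (k in other)
        queue <- c(queue, list(list(track = k, parent = NA_integer_)))
      tid <- keep
    }
  }
  LineageTree(cells = cellsDf, trackMap = trackMap,
              pixelSizeUm = trackGraph@pixelSizeUm,
              frameIntervalMin = trackGraph@frameIntervalMin)
}

#' Per-cell motility vectors
#'
#' The mean velocity of each cell between its birth and its end (division,
#' loss, or movie end): net displacement divided by elapsed time, in um/h.
#' The mean instantaneous (path) speed is also reported. Cells observed in a
#' single frame get a zero vector and are flagged.
#'
#' @param lineage a [LineageTree].
#' @param trackGraph the [TrackGraph] the lineage was built from.
#' @return data.frame: `cell_id`, `vx_um_per_h`, `vy_um_per_h`,
#'   `speed_um_per_h` (net), `path_speed_um_per_h`, `elapsed_h`, `flagged`.
#' @export
motilityVectors <- function(lineage, trackGraph) {
  px <- lineage@pixelSizeUm
  dth <- lineage@frameIntervalMin / 60
  nd <- trackGraph@nodes
  nd$cell_id <- lineage@trackMap$cell_id[
    match(nd$track_id, lineage@trackMap$track_id)]
  out <- lapply(split(nd[!is.na(nd$cell_id), ], nd$cell_id[!is.na(nd$cell_id)]),
                function(g) {
    g <- g[order(g$frame), ]
    nfr <- nrow(g)
    if (nfr < 2L) {
      return(data.frame(cell_id = g$cell_id[1], vx_um_per_h = 0,
                        vy_um_per_h = 0, speed_um_per_h = 0,
                        path_speed_um_per_h = 0, elapsed_h = 0,
                        flagged = TRUE))
    }
    el <- (g$frame[nfr] - g$frame[1]) * dth
    vx <- (g$x[nfr] - g$x[1]) * px / el
    vy <- (g$y[nfr] - g$y[1]) * px / el
    path <- sum(sqrt(diff(g$x)^2 + diff(g$y)^2)) * px / el
    data.frame(cell_id = g$cell_id[1], vx_um_per_h = vx, vy_um_per_h = vy,
               speed_um_per_h = sqrt(vx^2 + vy^2),
               path_speed_um_per_h = path, elapsed_h = el, flagged = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population statistics and doubling time
#'
#' Per-frame centroid counts and mean binary elements per cluster, plus the
#' two-point doubling time \eqn{T = \Delta t / \log_2(N_1 / N_0)} between two
#' chosen frames, and the analogous halving time of the mean elements per
#' cluster (vesicles dilute two-fold per division).
#'
#' @param states list of [ClusterState]s.
#' @param t0Frame,t1Frame frame indices of the comparison points (defaults:
#'   first and last available frame).
#' @param frameIntervalMin minutes between frames.
#' @return list with `perFrame` (data.frame `frame`, `n_centroids`,
#'   `mean_elements_per_cluster`), `doublingTimeH` (NA when counts do not
#'   increase) and `vesicleHalvingTimeH`.
#' @export
populationStats <- function(states, t0Frame = NULL, t1Frame = NULL,
                            frameIntervalMin = 5) {
  pf <- do.call(rbind, lapply(states, function(s) data.frame(
    frame = s@frameIndex, n_centroids = nrow(s@centroids),
    mean_elements_per_cluster = if (nrow(s@centroids))
      mean(s@centroids$n_elements) else 0)))
  if (is.null(t0Frame)) t0Frame <- min(pf$frame)
  if (is.null(t1Frame)) t1Frame <- max(pf$frame)
  stopifnot(t0Frame < t1Frame)
  n0 <- pf$n_centroids[match(t0Frame, pf$frame)]
  n1 <- pf$n_centroids[match(t1Frame, pf$frame)]
  e0 <- pf$mean_elements_per_cluster[match(t0Frame, pf$frame)]
  e1 <- pf$mean_elements_per_cluster[match(t1Frame, pf$frame)]
  dtH <- (t1Frame - t0Frame) * frameIntervalMin / 60
  doubling <- if (!is.na(n1) && !is.na(n0) && n1 > n0 && n0 > 0)
    dtH / log2(n1 / n0) else NA_real_
  halving <- if (!is.na(e1) && !is.na(e0) && e0 > e1 && e1 > 0)
    dtH / log2(e0 / e1) else NA_real_
  list(perFrame = pf, doublingTimeH = doubling, vesicleHalvingTimeH = halving)
}

#' Doubling time from two population counts
#'
#' The two-point estimator \eqn{T = \Delta t / \log_2(N_1 / N_0)}. With the
#' reference counts of 41 centroids growing to 133 over 40 h this gives
#' ~23.6 h.
#'
#' @param n0,n1 population counts at the two timepoints.
#' @param deltaHours elapsed time in hours.
#' @return doubling time in hours (NA if `n1 <= n0`).
#' @export
doublingTime <- function(n0, n1, deltaHours) {
  if (n1 <= n0 || n0 <= 0) return(NA_real_)
  deltaHours / log2(n1 / n0)
}

#' Export a lineage forest as Newick strings
#'
#' One Newick string per progenitor, with branch lengths in hours (a cell's
#' branch length is its lifetime from birth to division/loss/movie end).
#' Node labels are `c<cell_id>`.
#'
#' @param lineage a [LineageTree].
#' @return character vector of Newick strings.
#' @export
lineageNewick <- function(lineage) {
  cl <- lineage@cells
  dth <- lineage@frameIntervalMin / 60
  kidsOf <- split(cl$cell_id[!is.na(cl$parent_id)],
                  cl$parent_id[!is.na(cl$parent_id)])
  rec <- function(id) {
    r <- cl[cl$cell_id == id, ]
    len <- (r$end_frame - r$birth_frame) * dth
    kids <- kidsOf[[as.character(id)]]
    lab <- paste0("c", id)
    if (is.null(kids) || length(kids) == 0L)
      return(sprintf("%s:%g", lab, len))
    sprintf("(%s)%s:%g", paste(vapply(kids, rec, character(1)),
                               collapse = ","), lab, len)
  }
  roots <- cl$cell_id[is.na(cl$parent_id)]
  vapply(roots, function(r) paste0(rec(r), ";"), character(1))
}

#' Export a lineage forest as a nested list / JSON
#'
#' @param lineage a [LineageTree].
#' @param file optional path; when given, JSON is written there.
#' @return (invisibly, when writing) the nested list representation.
#' @export
lineageJSON <- function(lineage, file = NULL) {
  cl <- lineage@cells
  dth <- lineage@frameIntervalMin / 60
  kidsOf <- split(cl$cell_id[!is.na(cl$parent_id)],
                  cl$parent_id[!is.na(cl$parent_id)])
  rec <- function(id) {
    r <- cl[cl$cell_id == id, ]
    kids <- kidsOf[[as.character(id)]]
    out <- list(cell_id = id, birth_frame = r$birth_frame,
                end_frame = r$end_frame, end_reason = r$end_reason,
                lifetime_h = (r$end_frame - r$birth_frame) * dth)
    if (!is.null(kids) && length(kids) > 0L)
      out$daughters <- lapply(kids, rec)
    out
  }
  forest <- lapply(cl$cell_id[is.na(cl$parent_id)], rec)
  if (!is.null(file)) {
    jsonlite::write_json(forest, file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(forest))
  }
  forest
}
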