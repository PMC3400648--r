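# Frame-to-frame centroid linkage and track assembly.

#' Link centroids of two consecutive frames
#'
#' Cross-frame centroid pairs are sorted by Euclidean distance ascending and
#' linked greedily: a first pass builds a one-to-one matching, then remaining
#' unparented next-frame centroids take their nearest previous-frame centroid
#' as a second child, flagging that parent as a division candidate. All links
#' require the pair to lie within `linkRadiusUm` (the average single-cell
#' diameter); next-frame centroids with no admissible parent become new
#' progenitors. A third child for one parent is disallowed. Distance ties are
#' broken by (parent id, child id).
#'
#' @param cPrev,cNext [ClusterState]s of frames t and t+1.
#' @param linkRadiusUm maximum link distance (default 10 um).
#' @return a `LinkRecord`: list with `frame_from`, `frame_to`, `pairs`
#'   (data.frame `from`, `to`, `dist_px`), `new_progenitors` (centroid ids in
#'   `cNext`), and `division_candidates` (parent ids with two children).
#' @export
linkFrames <- function(cPrev, cNext, linkRadiusUm = 10) {
  stopifnot(is(cNext, "ClusterState"))
  px <- cNext@pixelSizeUm
  radPx <- linkRadiusUm / px
  a <- if (is.null(cPrev)) data.frame(id = integer(0), x = numeric(0),
                                      y = numeric(0)) else cPrev@centroids
  b <- cNext@centroids
  pairs <- data.frame(from = integer(0), to = integer(0), dist_px = numeric(0))
  if (nrow(a) > 0L && nrow(b) > 0L) {
    d <- .crossDist(cbind(a$x, a$y), cbind(b$x, b$y))
    cand <- which(d <= radPx, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cd <- data.frame(from = a$id[cand[, 1]], to = b$id[cand[, 2]],
                       dist_px = d[cand])
      cd <- cd[order(cd$dist_px, cd$from, cd$to), , drop = FALSE]
      parented <- character(0)
      kids <- stats::setNames(integer(nrow(a)), as.character(a$id))
      take <- integer(0)
      for (pass in 1:2) {
        # pass 1: parents take a first child; pass 2: a second (division)
        for (i in seq_len(nrow(cd))) {
          p <- as.character(cd$from[i]); c2 <- as.character(cd$to[i])
          if (c2 %in% parented) next
          if (kids[p] != pass - 1L) next
          parented <- c(parented, c2)
          kids[p] <- kids[p] + 1L
          take <- c(take, i)
        }
      }
      pairs <- cd[sort(take), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  linked <- pairs$to
  list(
    frame_from = if (is.null(cPrev)) cNext@frameIndex - 1L else
      cPrev@frameIndex,
    frame_to = cNext@frameIndex,
    pairs = pairs,
    new_progenitors = setdiff(b$id, linked),
    division_candidates = as.integer(names(table(pairs$from))[
      table(pairs$from) == 2L])
  )
}

#' Assemble tracks from a sequence of link records
#'
#' Concatenates consecutive-frame link records into a [TrackGraph]. A track
#' continues while its centroid has a single child; both children of a
#' two-child (division candidate) parent start new tracks that point back at
#' the parent track; parentless centroids root new tracks.
#'
#' @param links list of link records from [linkFrames()] covering consecutive
#'   frame pairs, in order.
#' @param states list of [ClusterState]s for all frames (first frame plus one
#'   per link), supplying node coordinates.
#' @param frameIntervalMin minutes between frames.
#' @return a [TrackGraph].
#' @export
buildTrackGraph <- function(links, states, frameIntervalMin = 5) {
  stopifnot(length(states) == length(links) + 1L)
  frames <- vapply(states, frameIndex, integer(1))
  if (length(links) > 0L) {
    ff <- vapply(links, function(l) l$frame_from, numeric(1))
    ft <- vapply(links, function(l) l$frame_to, numeric(1))
    if (any(ft != ff + 1L) || any(ff != frames[-length(frames)]))
      stop("link records must cover consecutive frame pairs in order")
  }
  px <- states[[1L]]@pixelSizeUm
  nextTrack <- 1L
  trackOf <- list()  # per frame: named vector centroid id -> track id
  rows <- vector("list", length(states))
  trk <- data.frame(track_id = integer(0), parent_track_id = integer(0),
                    start_frame = integer(0), end_frame = integer(0))
  newTrack <- function(parent, frame) {
    trk <<- rbind(trk, data.frame(track_id = nextTrack,
                                  parent_track_id = parent,
                                  start_frame = frame, end_frame = frame))
    nextTrack <<- nextTrack + 1L
    nextTrack - 1L
  }
  st0 <- states[[1L]]
  cur <- stats::setNames(
    vapply(st0@centroids$id, function(i) newTrack(NA_integer_, frames[1L]),
           integer(1)),
    as.character(st0@centroids$id))
  rows[[1L]] <- data.frame(frame = frames[1L], centroid_id = st0@centroids$id,
                           track_id = as.integer(cur),
                           x = st0@centroids$x, y = st0@centroids$y)
  for (k in seq_along(links)) {
    lk <- links[[k]]
    stn <- states[[k + 1L]]
    fr <- frames[k + 1L]
    nxt <- integer(0)
    nchild <- table(lk$pairs$from)
    for (cid in stn@centroids$id) {
      i <- match(cid, lk$pairs$to)
      if (is.na(i)) {
        tid <- newTrack(NA_integer_, fr)
      } else {
        p <- lk$pairs$from[i]
        ptid <- cur[[as.character(p)]]
        if (nchild[[as.character(p)]] == 1L) {
          tid <- ptid                      # continuation
          trk$end_frame[trk$track_id == tid] <- fr
        } else {
          tid <- newTrack(ptid, fr)        # division candidate child
        }
      }
      nxt[as.character(cid)] <- tid
    }
    cur <- nxt
    rows[[k + 1L]] <- data.frame(frame = fr, centroid_id = stn@centroids$id,
                                 track_id = as.integer(cur[
                                   as.character(stn@centroids$id)]),
                                 x = stn@centroids$x, y = stn@centroids$y)
  }
  nodes <- do.call(rbind, rows)
  # end frames: last frame each track appears
  agg <- tapply(nodes$frame, nodes$track_id, max)
  trk$end_frame <- as.integer(agg[as.character(trk$track_id)])
  agg0 <- tapply(nodes$frame, nodes$track_id, min)
  trk$start_frame <- as.integer(agg0[as.character(trk$track_id)])
  TrackGraph(nodes = nodes, tracks = trk, pixelSizeUm = px,
             frameIntervalMin = frameIntervalMin)
}
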