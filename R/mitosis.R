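# Mitotic curves and division detection from the contraction-expansion
# signature of a cell's binary element cloud.

#' Mitotic curve of one track
#'
#' For every frame of a track, the mean pairwise separation of the cluster's
#' binary elements and the mean element-to-centroid distance, both in
#' micrometres, plus the element count. Frames where the cluster holds a
#' single element record separation 0 and are flagged.
#'
#' @param trackGraph a [TrackGraph].
#' @param trackId the track to profile.
#' @param states list of [ClusterState]s covering the track's frames (indexed
#'   by frame order as used to build the graph).
#' @return data.frame with columns `track_id`, `frame`,
#'   `mean_separation_um`, `mean_centroid_dist_um`, `n_elements`, `flagged`.
#' @export
mitoticCurve <- function(trackGraph, trackId, states) {
  nd <- trackGraph@nodes
  nd <- nd[nd$track_id == trackId, , drop = FALSE]
  if (nrow(nd) == 0L) stop("unknown track id: ", trackId)
  frames <- vapply(states, frameIndex, integer(1))
  out <- lapply(seq_len(nrow(nd)), function(i) {
    st <- states[[match(nd$frame[i], frames)]]
    ce <- st@centroids
    j <- match(nd$centroid_id[i], ce$id)
    data.frame(track_id = trackId, frame = nd$frame[i],
               mean_separation_um = ce$mean_separation_um[j],
               mean_centroid_dist_um = ce$mean_centroid_dist_um[j],
               n_elements = ce$n_elements[j],
               flagged = ce$n_elements[j] < 2L)
  })
  do.call(rbind, out)
}

#' Mitotic curves for every track
#'
#' @inheritParams mitoticCurve
#' @return one data.frame, rows ordered by track then frame.
#' @export
mitoticCurves <- function(trackGraph, states) {
  ids <- trackGraph@tracks$track_id
  do.call(rbind, lapply(ids, mitoticCurve, trackGraph = trackGraph,
                        states = states))
}

# Core scan of a separation series for contraction-expansion signatures.
# Returns completed events and, if the series ends mid-signature, the pending
# contraction. Flagged (single-element) frames never set the baseline and
# cannot trigger onset or confirmation, but may hold the running minimum of
# an established contraction.
.divisionScan <- function(frames, sep, flagged, baselineWindow = 12L,
                          contractionFraction = 0.6) {
  n <- length(sep)
  events <- list()
  state <- "normal"
  base <- NA_real_; onset <- NA_integer_; minIdx <- NA_integer_
  minVal <- NA_real_
  hist <- numeric(0)  # unflagged values seen while in normal state
  for (t in seq_len(n)) {
    if (state == "normal") {
      if (flagged[t]) next
      if (length(hist) >= baselineWindow) {
        b <- stats::median(utils::tail(hist, baselineWindow))
        if (sep[t] < contractionFraction * b) {
          state <- "contracting"; base <- b; onset <- t
          minIdx <- t; minVal <- sep[t]
          next
        }
      }
      hist <- c(hist, sep[t])
    } else {
      if (sep[t] <= minVal) { minVal <- sep[t]; minIdx <- t }
      if (!flagged[t] && t > minIdx && sep[t] > base) {
        events[[length(events) + 1L]] <- data.frame(
          onset_frame = frames[onset], frame_of_minimum = frames[minIdx],
          frame_confirmed = frames[t], baseline_um = base,
          minimum_um = minVal)
        state <- "normal"
        hist <- numeric(0)  # restart baseline accumulation after the event
      }
    }
  }
  pending <- if (state == "contracting")
    list(onset = frames[onset], minIdx = frames[minIdx], minVal = minVal,
         baseline = base) else NULL
  list(events = if (length(events)) do.call(rbind, events) else
    data.frame(onset_frame = integer(0), frame_of_minimum = integer(0),
               frame_confirmed = integer(0), baseline_um = numeric(0),
               minimum_um = numeric(0)),
    pending = pending)
}

#' Detect division events on a mitotic curve
#'
#' Scans a track's mean-separation series for the mitotic signature: the
#' baseline is the median separation over the `baselineWindowFrames` frames
#' preceding a candidate contraction; contraction onset is the first frame
#' whose separation falls below `contractionFraction` times that baseline;
#' the frame of minimum is the argmin thereafter; and the division is
#' confirmed at the first post-minimum frame whose separation exceeds the
#' baseline (the stable pre-contraction level). Several sequential signatures
#' on one curve yield several events.
#'
#' @param curve data.frame from [mitoticCurve()] (or a numeric separation
#'   series, taken as unflagged consecutive frames starting at 0).
#' @param baselineWindowFrames frames in the baseline median (default 12,
#'   i.e. one hour at 5-minute framing).
#' @param contractionFraction onset threshold as a fraction of baseline
#'   (default 0.6).
#' @return data.frame of events (`onset_frame`, `frame_of_minimum`,
#'   `frame_confirmed`, `baseline_um`, `minimum_um`); zero rows when no
#'   contraction-expansion pattern completes.
#' @export
detectDivision <- function(curve, baselineWindowFrames = 12L,
                           contractionFraction = 0.6) {
  if (is.numeric(curve)) {
    curve <- data.frame(frame = seq_along(curve) - 1L,
                        mean_separation_um = curve,
                        flagged = FALSE)
  }
  if (nrow(curve) <= baselineWindowFrames) {
    message("track too short for division detection")
    return(.divisionScan(integer(0), numeric(0), logical(0))$events)
  }
  .divisionScan(curve$frame, curve$mean_separation_um, curve$flagged,
                baselineWindowFrames, contractionFraction)$events
}
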