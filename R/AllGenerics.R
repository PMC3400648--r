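#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("sourcePlane", function(x) standardGeneric("sourcePlane"))

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname accessors
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' @rdname accessors
#' @export
setGeneric("silhouetteMean", function(x) standardGeneric("silhouetteMean"))

#' @rdname accessors
#' @export
setGeneric("trackNodes", function(x) standardGeneric("trackNodes"))

#' @rdname accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' Accessors for mldcyto classes
#'
#' Small read-only accessors for the package's S4 containers: `elements()`
#' returns the element coordinate matrix, `centroids()` the centroid table,
#' `planes()` the focal-plane list, `intensity()`/`sourcePlane()` the fused
#' composite, `assignment()` the element-to-centroid map, `trackNodes()` and
#' `tracks()` the track graph tables, and `cells()` the per-cell table of a
#' lineage tree or ground truth.
#'
#' @param x an mldcyto object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("planes", "FrameStack", function(x) x@planes)
#' @rdname accessors
setMethod("frameIndex", "FrameStack", function(x) x@frameIndex)
#' @rdname accessors
setMethod("pixelSize", "FrameStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("intensity", "CompositeImage", function(x) x@intensity)
#' @rdname accessors
setMethod("sourcePlane", "CompositeImage", function(x) x@sourcePlane)
#' @rdname accessors
setMethod("elements", "BinaryElementMap", function(x) x@elements)
#' @rdname accessors
setMethod("frameIndex", "BinaryElementMap", function(x) x@frameIndex)
#' @rdname accessors
setMethod("thresholdUsed", "BinaryElementMap", function(x) x@thresholdUsed)
#' @rdname accessors
setMethod("elements", "ClusterState", function(x) x@elements)
#' @rdname accessors
setMethod("centroids", "ClusterState", function(x) x@centroids)
#' @rdname accessors
setMethod("assignment", "ClusterState", function(x) x@assignment)
#' @rdname accessors
setMethod("frameIndex", "ClusterState", function(x) x@frameIndex)
#' @rdname accessors
setMethod("pixelSize", "ClusterState", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("silhouetteMean", "ClusterState", function(x) x@silhouetteMean)
#' @rdname accessors
setMethod("trackNodes", "TrackGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("tracks", "TrackGraph", function(x) x@tracks)
#' @rdname accessors
setMethod("cells", "LineageTree", function(x) x@cells)
#' @rdname accessors
setMethod("cells", "GroundTruth", function(x) x@cells)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@planes[[1L]])
  cat("FrameStack: frame", object@frameIndex, "(t =", object@timestampMin,
      "min),", length(object@planes), "plane(s) of", d[1], "x", d[2],
      "px,", object@pixelSizeUm, "um/px\n")
})

setMethod("show", "CompositeImage", function(object) {
  cat("CompositeImage:", nrow(object@intensity), "x", ncol(object@intensity),
      "px fused from", length(unique(as.vector(object@sourcePlane))),
      "source plane(s)\n")
})

setMethod("show", "BinaryElementMap", function(object) {
  cat("BinaryElementMap: frame", object@frameIndex, "-", nrow(object@elements),
      "binary elements (threshold", signif(object@thresholdUsed, 5), ")\n")
})

setMethod("show", "ClusterState", function(object) {
  cat("ClusterState: frame", object@frameIndex, "-", nrow(object@centroids),
      "centroids over", nrow(object@elements), "elements; mean silhouette",
      signif(object@silhouetteMean, 3), "\n")
})

setMethod("show", "TrackGraph", function(object) {
  nd <- nrow(object@tracks[!is.na(object@tracks$parent_track_id), ])
  cat("TrackGraph:", nrow(object@tracks), "tracks over",
      length(unique(object@nodes$frame)), "frames;", nd,
      "child tracks from bifurcations\n")
})

setMethod("show", "LineageTree", function(object) {
  cl <- object@cells
  cat("LineageTree:", nrow(cl), "cells,",
      sum(is.na(cl$parent_id)), "progenitors,",
      sum(cl$end_reason == "division"), "divisions\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@fieldUm[1], "x", object@fieldUm[2], "um field,",
      object@nFrames, "frames @", object@frameIntervalMin, "min,",
      object@initialCells, "initial cells, SNR", object@snr,
      ", seed", object@rngSeed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cells), "cells,",
      sum(!is.na(object@cells$division_frame)), "divisions,",
      length(unique(object@vesicles$vesicle_id)), "vesicles\n")
})
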