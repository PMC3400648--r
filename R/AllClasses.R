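#' @import methods
NULL

#' FrameStack: the focal-plane images for one timepoint
#'
#' Container for the raw intensity data of a single timepoint: one or more
#' focal-plane images on a shared pixel grid, plus the frame index, acquisition
#' time and pixel calibration. Intensities are in arbitrary detector units.
#'
#' @slot planes list of numeric matrices (rows = y, columns = x), all of
#'   identical dimension; plane order follows acquisition z-order.
#' @slot frameIndex integer frame number, 0-based.
#' @slot timestampMin minutes from experiment start
#'   (`frameIndex * frame interval`).
#' @slot pixelSizeUm micrometres per pixel (> 0).
#'
#' @aliases FrameStack-class
#' @export FrameStack
#' @exportClass FrameStack
FrameStack <- setClass("FrameStack",
  representation(
    planes      = "list",
    frameIndex  = "integer",
    timestampMin = "numeric",
    pixelSizeUm = "numeric"
  ),
  prototype(frameIndex = 0L, timestampMin = 0, pixelSizeUm = 0.25)
)

setValidity("FrameStack", function(object) {
  if (length(object@planes) < 1L) return("a FrameStack needs at least one plane")
  if (!all(vapply(object@planes, is.matrix, logical(1))))
    return("all planes must be matrices")
  d <- dim(object@planes[[1L]])
  for (p in object@planes)
    if (!identical(dim(p), d)) return("all planes must share identical dimensions")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  if (object@frameIndex < 0L) return("frameIndex must be >= 0")
  TRUE
})

#' CompositeImage: focal-fused single image
#'
#' Result of absolute-gradient focal fusion: for each block of the image the
#' focal plane with the highest local contrast is copied in, and
#' `sourcePlane` records which plane supplied each pixel (1-based plane index).
#'
#' @slot intensity numeric matrix of fused intensities.
#' @slot sourcePlane integer matrix, same dimension, plane index per pixel.
#'
#' @aliases CompositeImage-class
#' @export CompositeImage
#' @exportClass CompositeImage
CompositeImage <- setClass("CompositeImage",
  representation(intensity = "matrix", sourcePlane = "matrix")
)

setValidity("CompositeImage", function(object) {
  if (!identical(dim(object@intensity), dim(object@sourcePlane)))
    return("intensity and sourcePlane must have identical dimensions")
  if (any(object@sourcePlane < 1L)) return("sourcePlane entries must be >= 1")
  TRUE
})

#' BinaryElementMap: detected point sources of one frame
#'
#' The per-frame list of binary elements -- above-threshold local intensity
#' maxima, each marking one nanoparticle-loaded vesicle. Coordinates are
#' 0-based pixels, `x` = column, `y` = row.
#'
#' @slot frameIndex integer frame number.
#' @slot elements numeric matrix with columns `x`, `y` (0-based pixels).
#' @slot thresholdUsed the intensity threshold that produced the map.
#'
#' @aliases BinaryElementMap-class
#' @export BinaryElementMap
#' @exportClass BinaryElementMap
BinaryElementMap <- setClass("BinaryElementMap",
  representation(frameIndex = "integer", elements = "matrix",
                 thresholdUsed = "numeric"),
  prototype(frameIndex = 0L,
            elements = matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("x", "y"))),
            thresholdUsed = 0)
)

setValidity("BinaryElementMap", function(object) {
  e <- object@elements
  if (ncol(e) != 2L) return("elements must have two columns (x, y)")
  if (nrow(e) > 0L) {
    if (any(e < 0)) return("element coordinates must be >= 0")
    if (anyDuplicated(e)) return("duplicate element coordinates")
  }
  if (object@thresholdUsed < 0) return("thresholdUsed must be >= 0")
  TRUE
})

#' ClusterState: per-frame cell clusters
#'
#' The converged k-means state of one frame: centroid table, element
#' coordinates, element-to-centroid assignment and cluster fit scores.
#'
#' @slot frameIndex integer frame number.
#' @slot elements numeric matrix with columns `x`, `y` (0-based pixels).
#' @slot centroids data.frame with columns `id`, `x`, `y`, `n_elements`,
#'   `mean_separation_um` (mean over unordered element pairs),
#'   `mean_centroid_dist_um` (mean element-to-centroid distance).
#' @slot assignment integer vector, one centroid `id` per element.
#' @slot silhouetteMean mean silhouette score over all elements, in [-1, 1].
#' @slot pixelSizeUm micrometres per pixel used for the micrometre columns.
#'
#' @aliases ClusterState-class
#' @export ClusterState
#' @exportClass ClusterState
ClusterState <- setClass("ClusterState",
  representation(frameIndex = "integer", elements = "matrix",
                 centroids = "data.frame", assignment = "integer",
                 silhouetteMean = "numeric", pixelSizeUm = "numeric"),
  prototype(frameIndex = 0L, silhouetteMean = 0, pixelSizeUm = 0.25)
)

setValidity("ClusterState", function(object) {
  if (length(object@assignment) != nrow(object@elements))
    return("assignment length must equal the number of elements")
  if (nrow(object@centroids) > 0L) {
    need <- c("id", "x", "y", "n_elements", "mean_separation_um",
              "mean_centroid_dist_um")
    if (!all(need %in% names(object@centroids)))
      return(paste("centroids must have columns:", paste(need, collapse = ", ")))
    if (!all(object@assignment %in% object@centroids$id))
      return("assignment refers to unknown centroid ids")
    if (any(object@centroids$n_elements < 1L))
      return("every centroid must own at least one element")
    if (sum(object@centroids$n_elements) != nrow(object@elements))
      return("cluster sizes must partition the elements")
  }
  if (abs(object@silhouetteMean) > 1 + 1e-9)
    return("silhouetteMean must lie in [-1, 1]")
  TRUE
})

#' TrackGraph: temporal linkage of centroids
#'
#' Tracks are maximal single-cell paths through the frame-to-frame centroid
#' links; a track ends when its centroid vanishes or when it acquires two
#' children (a division candidate), in which case both children start new
#' tracks pointing back at the parent.
#'
#' @slot nodes data.frame with columns `frame`, `centroid_id`, `track_id`,
#'   `x`, `y` (pixels).
#' @slot tracks data.frame with columns `track_id`, `parent_track_id` (NA for
#'   roots), `start_frame`, `end_frame`.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalMin minutes between frames.
#'
#' @aliases TrackGraph-class
#' @export TrackGraph
#' @exportClass TrackGraph
TrackGraph <- setClass("TrackGraph",
  representation(nodes = "data.frame", tracks = "data.frame",
                 pixelSizeUm = "numeric", frameIntervalMin = "numeric"),
  prototype(pixelSizeUm = 0.25, frameIntervalMin = 5)
)

setValidity("TrackGraph", function(object) {
  tr <- object@tracks
  if (nrow(tr) == 0L) return(TRUE)
  if (any(tr$end_frame < tr$start_frame))
    return("track end_frame must be >= start_frame")
  kids <- table(tr$parent_track_id[!is.na(tr$parent_track_id)])
  if (any(kids > 2L)) return("out-degree must be <= 2")
  ed <- tr[!is.na(tr$parent_track_id), , drop = FALSE]
  if (nrow(ed) > 0L) {
    par <- tr[match(ed$parent_track_id, tr$track_id), ]
    if (anyNA(par$track_id)) return("parent_track_id refers to unknown track")
    if (any(ed$start_frame <= par$start_frame))
      return("frame index must increase along edges")
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$parent_track_id),
                 to = as.character(ed$track_id)),
      vertices = data.frame(name = as.character(tr$track_id)))
    if (!igraph::is_dag(g)) return("track graph must be acyclic")
  }
  TRUE
})

#' LineageTree: cells and their familial relationships
#'
#' One node per cell (a track, or a chain of tracks merged across unconfirmed
#' bifurcations); edges run mother to daughter at confirmed divisions.
#'
#' @slot cells data.frame with columns `cell_id`, `parent_id` (NA for
#'   progenitors), `birth_frame`, `end_frame`, `end_reason` (one of
#'   `"division"`, `"lost"`, `"movie_end"`), `birth_x`, `birth_y`,
#'   `end_x`, `end_y` (pixels).
#' @slot trackMap data.frame mapping `track_id` to `cell_id`.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalMin minutes between frames.
#'
#' @aliases LineageTree-class
#' @export LineageTree
#' @exportClass LineageTree
LineageTree <- setClass("LineageTree",
  representation(cells = "data.frame", trackMap = "data.frame",
                 pixelSizeUm = "numeric", frameIntervalMin = "numeric"),
  prototype(pixelSizeUm = 0.25, frameIntervalMin = 5)
)

setValidity("LineageTree", function(object) {
  cl <- object@cells
  if (nrow(cl) == 0L) return(TRUE)
  if (any(cl$end_frame < cl$birth_frame))
    return("end_frame must be >= birth_frame")
  kids <- table(cl$parent_id[!is.na(cl$parent_id)])
  if (any(kids > 2L)) return("branching must be binary")
  if (!all(cl$end_reason %in% c("division", "lost", "movie_end")))
    return("unknown end_reason")
  TRUE
})

#' SimConfig: synthetic movie configuration
#'
#' All physical and imaging parameters of the synthetic time-lapse generator.
#' Defaults emulate a typical confocal acquisition: a 336 x 256 um field imaged at
#' 0.25 um/pixel in 8 focal planes every 5 minutes, adherent cells of 10 um
#' diameter carrying 10-50 quantum-dot-loaded vesicles on a perinuclear ring,
#' an inter-mitotic time of 23 +/- 2 h, and Gaussian background noise.
#'
#' @slot fieldUm numeric length-2, field width and height in micrometres.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot nPlanes number of focal planes per timepoint.
#' @slot frameIntervalMin minutes between frames.
#' @slot nFrames number of timepoints.
#' @slot initialCells number of cells at frame 0.
#' @slot vesiclesPerCell integer length-2 range, vesicles drawn uniformly.
#' @slot cellDiameterUm nominal cell diameter (10 um).
#' @slot imtHours mean inter-mitotic time in hours.
#' @slot imtSdHours standard deviation of the inter-mitotic time.
#' @slot motilityUmPerH mean random-walk speed in um/h.
#' @slot snr target signal-to-noise ratio, defined as rendered spot peak
#'   intensity over the realized `mu + sigma` threshold of the composite.
#' @slot backgroundMean,backgroundSd Gaussian background, detector units.
#' @slot spotSigmaUm Gaussian spot radius (sd) in micrometres.
#' @slot intensityCv fractional spot-to-spot intensity variation.
#' @slot ringRadiusUm perinuclear ring radius.
#' @slot ringJitterUm per-frame positional jitter of each vesicle.
#' @slot condensedRadiusUm vesicle cloud radius at full mitotic contraction.
#' @slot contractionMin duration of the pre-division contraction (minutes).
#' @slot separationMin time for daughters to separate (minutes).
#' @slot separationUm final daughter separation distance.
#' @slot zSdPlanes sd of vesicle z positions around the cell plane, in planes.
#' @slot zProfileSdPlanes sd of the Gaussian intensity fall-off across planes.
#' @slot entryRatePerH Poisson rate of new cells entering the field per hour.
#' @slot minInitialSeparationUm minimum pairwise distance of initial cells.
#' @slot domainMarginUm the simulated monolayer extends this far beyond the
#'   imaged field on every side, so cells wander in and out of view with
#'   balanced flux; `initialCells` is the expected count inside the field.
#' @slot initialAgeMode `"stationary"` (cell-cycle ages drawn from the
#'   age distribution of an exponentially growing population, the default),
#'   `"uniform"`, or `"zero"` (all cells newborn).
#' @slot rngSeed integer random seed; identical seeds give identical movies.
#'
#' @aliases SimConfig-class
#' @export SimConfig
#' @exportClass SimConfig
SimConfig <- setClass("SimConfig",
  representation(
    fieldUm = "numeric", pixelSizeUm = "numeric", nPlanes = "integer",
    frameIntervalMin = "numeric", nFrames = "integer",
    initialCells = "integer", vesiclesPerCell = "integer",
    cellDiameterUm = "numeric", imtHours = "numeric", imtSdHours = "numeric",
    motilityUmPerH = "numeric", snr = "numeric",
    backgroundMean = "numeric", backgroundSd = "numeric",
    spotSigmaUm = "numeric", intensityCv = "numeric",
    ringRadiusUm = "numeric", ringJitterUm = "numeric",
    condensedRadiusUm = "numeric", contractionMin = "numeric",
    separationMin = "numeric", separationUm = "numeric",
    zSdPlanes = "numeric", zProfileSdPlanes = "numeric",
    entryRatePerH = "numeric", minInitialSeparationUm = "numeric",
    domainMarginUm = "numeric", initialAgeMode = "character",
    rngSeed = "integer"
  ),
  prototype(
    fieldUm = c(336, 256), pixelSizeUm = 0.25, nPlanes = 8L,
    frameIntervalMin = 5, nFrames = 48L, initialCells = 10L,
    vesiclesPerCell = c(10L, 50L), cellDiameterUm = 10,
    imtHours = 23, imtSdHours = 2, motilityUmPerH = 10, snr = 2.5,
    backgroundMean = 400, backgroundSd = 20, spotSigmaUm = 0.5,
    intensityCv = 0.15, ringRadiusUm = 4.5, ringJitterUm = 0.4,
    condensedRadiusUm = 0.6, contractionMin = 30, separationMin = 60,
    separationUm = 16, zSdPlanes = 0.75, zProfileSdPlanes = 1,
    entryRatePerH = 0, minInitialSeparationUm = 24, domainMarginUm = 20,
    initialAgeMode = "stationary", rngSeed = 1L
  )
)

setValidity("SimConfig", function(object) {
  if (length(object@fieldUm) != 2L || any(object@fieldUm <= 0))
    return("fieldUm must be two positive lengths")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  if (object@nPlanes < 1L) return("nPlanes must be >= 1")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@initialCells < 0L) return("initialCells must be >= 0")
  v <- object@vesiclesPerCell
  if (length(v) != 2L || v[1] > v[2] || v[1] < 1L || v[2] > 200L)
    return("vesiclesPerCell must be a range within [1, 200]")
  pos <- c(object@frameIntervalMin, object@cellDiameterUm, object@imtHours,
           object@snr, object@spotSigmaUm,
           object@ringRadiusUm, object@condensedRadiusUm,
           object@contractionMin, object@separationMin, object@separationUm)
  if (any(pos <= 0)) return("physical scales must be positive")
  if (object@backgroundSd < 0) return("backgroundSd must be >= 0")
  if (!object@initialAgeMode %in% c("stationary", "uniform", "zero"))
    return("initialAgeMode must be 'stationary', 'uniform' or 'zero'")
  if (object@domainMarginUm < 0) return("domainMarginUm must be >= 0")
  TRUE
})

#' GroundTruth: simulator-emitted truth for a synthetic movie
#'
#' @slot cells data.frame: `cell_id`, `parent_id`, `birth_frame`,
#'   `end_frame`, `end_reason` (`"division"`, `"exit"`, `"movie_end"`),
#'   `division_frame` (NA if none), `n_vesicles`.
#' @slot positions data.frame: `frame`, `cell_id`, `x_px`, `y_px`,
#'   `phase` (`"interphase"`, `"contracting"`, `"separating"`),
#'   `cloud_radius_um`, `in_field`.
#' @slot vesicles data.frame of ownership periods: `vesicle_id`, `cell_id`,
#'   `start_frame`, `end_frame`.
#' @slot config the [SimConfig] that produced the movie.
#'
#' @aliases GroundTruth-class
#' @export GroundTruth
#' @exportClass GroundTruth
GroundTruth <- setClass("GroundTruth",
  representation(cells = "data.frame", positions = "data.frame",
                 vesicles = "data.frame", config = "SimConfig")
)

setValidity("GroundTruth", function(object) {
  cl <- object@cells
  if (nrow(cl) > 0L && any(cl$end_frame < cl$birth_frame))
    return("cell end_frame must be >= birth_frame")
  TRUE
})
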