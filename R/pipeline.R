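# End-to-end pipeline: imaging -> clustering -> tracking -> mitosis ->
# lineage, with per-frame mitotic-curve monitoring so a confirmed division
# immediately re-splits the cluster and reassigns elements to the daughters.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with the reference values as
#' defaults. Distances are micrometres unless the name says pixels;
#' micrometre/pixel conversion uses `pixelSizeUm` only.
#'
#' @param pixelSizeUm micrometres per pixel (default 0.25: 120 px = 30 um).
#' @param frameIntervalMin minutes between frames (default 5).
#' @param regionPx focal-fusion block size (default 32 px).
#' @param windowPx peak-finder window (odd, default 5 px).
#' @param theta fixed intensity threshold, or `NULL` for the per-frame
#'   `mu + sigma` rule.
#' @param spawnRadiusUm new-seed distance (default 30 um = 120 px).
#' @param removeRadiusUm seed proximity-validation radius (default 12.5 um
#'   = 50 px).
#' @param splitThresholdUm mean-separation trigger for attempting the
#'   silhouette-gated split (default 10 um, one average cell diameter: the
#'   acceptance gate makes more frequent attempts safe, and merged sibling
#'   pairs are otherwise unresolved until far larger separations; the
#'   classical 1.5-diameter trigger, 15 um, remains the [splitTest()]
#'   default).
#' @param splitOffsetPx extra-seed offset (default 10 px).
#' @param linkRadiusUm frame-to-frame link radius (default 10 um, one cell
#'   diameter).
#' @param baselineWindowFrames mitotic-curve baseline window (default 12
#'   frames = 1 h).
#' @param contractionFraction contraction onset fraction (default 0.6).
#' @param maxBaselineUm divisions whose pre-contraction baseline mean pairwise
#'   separation exceeds this are discarded as multi-cell artifacts
#'   (default 10 um, the average single cell diameter: a stable separation
#'   above one cell diameter cannot belong to a single mother).
#' @param minMotherElements a division is confirmed only if the mother's
#'   pre-contraction median element count is at least this (default 5, the
#'   minimum number of binary elements for reliable cell identification):
#'   the separation series of a sparser cluster is too unstable to carry the
#'   mitotic signature.
#' @param divisionMinParentAgeFrames a division is kept only if the mother's
#'   track is at least this old at the frame of minimum (default 24 frames =
#'   2 h): no cell divides within two hours of being born, so contraction
#'   signatures on just-created fragment tracks (cluster-identity churn in
#'   crowded regions) are artifacts. Tracks seeded in the first frame are
#'   exempt -- their cells are of unknown, not young, age.
#' @param kmeansMaxIter,kmeansTolPx k-means controls (100 iterations, 0.5 px).
#' @param seedMode `"manual"` (seed file / data.frame required) or `"auto"`
#'   (connected-component seeding of the first frame).
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(pixelSizeUm = 0.25, frameIntervalMin = 5,
                           regionPx = 32L, windowPx = 5L, theta = NULL,
                           spawnRadiusUm = 30, removeRadiusUm = 12.5,
                           splitThresholdUm = 10, splitOffsetPx = 10,
                           linkRadiusUm = 10, baselineWindowFrames = 12L,
                           contractionFraction = 0.6, maxBaselineUm = 10,
                           minMotherElements = 5L,
                           divisionMinParentAgeFrames = 24L,
                           kmeansMaxIter = 100L,
                           kmeansTolPx = 0.5, seedMode = c("manual", "auto")) {
  structure(list(
    pixelSizeUm = pixelSizeUm, frameIntervalMin = frameIntervalMin,
    regionPx = as.integer(regionPx), windowPx = as.integer(windowPx),
    theta = theta, spawnRadiusUm = spawnRadiusUm,
    removeRadiusUm = removeRadiusUm, splitThresholdUm = splitThresholdUm,
    splitOffsetPx = splitOffsetPx, linkRadiusUm = linkRadiusUm,
    baselineWindowFrames = as.integer(baselineWindowFrames),
    contractionFraction = contractionFraction,
    maxBaselineUm = maxBaselineUm,
    minMotherElements = as.integer(minMotherElements),
    divisionMinParentAgeFrames = as.integer(divisionMinParentAgeFrames),
    kmeansMaxIter = as.integer(kmeansMaxIter), kmeansTolPx = kmeansTolPx,
    seedMode = match.arg(seedMode)), class = "PipelineConfig")
}

.emptyClusterState <- function(frame, px) {
  ClusterState(
    frameIndex = as.integer(frame), elements = .emptyElements(),
    centroids = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                           n_elements = integer(0),
                           mean_separation_um = numeric(0),
                           mean_centroid_dist_um = numeric(0)),
    assignment = integer(0), silhouetteMean = 0, pixelSizeUm = px)
}

# Normalize the pipeline input to a (nFrames, getFrame) pair.
.frameSource <- function(input, config) {
  if (is.list(input) && !is.null(input$getFrame)) {
    return(list(nFrames = input$nFrames, getFrame = input$getFrame))
  }
  if (is.list(input) && length(input) > 0L && is(input[[1L]], "FrameStack")) {
    return(list(nFrames = length(input),
                getFrame = function(t) input[[t + 1L]]))
  }
  if (is.character(input)) {
    paths <- if (length(input) == 1L && dir.exists(input))
      listFramePaths(input) else input
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) stop("unreadable input: ", missing[1L])
    return(list(nFrames = length(paths), getFrame = function(t)
      readFrameStack(paths[t + 1L], frameIndex = t,
                     pixelSizeUm = config$pixelSizeUm,
                     frameIntervalMin = config$frameIntervalMin)))
  }
  stop("unreadable input: expected FrameStack list, generator, or TIFF path(s)")
}

#' Run the full tracking pipeline
#'
#' Executes element detection, per-frame seeded clustering with the seed
#' creation/removal and split rules, frame-to-frame linkage, online mitotic
#' curve monitoring (a confirmed contraction-expansion signature forces the
#' cluster split and emits a division event), and lineage/motility/population
#' summaries.
#'
#' @param input a list of [FrameStack]s, a [frameGenerator()] result, a
#'   directory of TIFFs, or a character vector of TIFF paths.
#' @param config a [pipelineConfig()].
#' @param seeds first-frame seeds: data.frame with `x`, `y` (and optionally
#'   `id`), a path to a seed CSV (`x_px,y_px`), or `NULL` with
#'   `seedMode = "auto"`.
#' @param outDir optional directory; when given, all CSV/JSON artifacts and a
#'   run manifest are written there.
#' @param verbose print per-frame progress to stderr.
#' @return list with `states`, `elementMaps`, `links`, `trackGraph`,
#'   `divisions` (data.frame), `lineage` ([LineageTree]), `motility`,
#'   `stats`, `config`, `seedMode`.
#' @export
runPipeline <- function(input, config = pipelineConfig(), seeds = NULL,
                        outDir = NULL, verbose = FALSE) {
  src <- .frameSource(input, config)
  nF <- src$nFrames
  px <- config$pixelSizeUm
  states <- vector("list", nF)
  maps <- vector("list", nF)
  links <- vector("list", max(0L, nF - 1L))
  reg <- list()        # per current centroid id: hist df + handled marker
  emissions <- list()  # centroid-level division emissions
  nextId <- 1L

  clusterFirst <- function(bem) {
    el <- bem@elements
    if (nrow(el) == 0L) return(.emptyClusterState(bem@frameIndex, px))
    sd0 <- if (is.character(seeds)) readSeedCsv(seeds)
      else if (!is.null(seeds)) .asSeedFrame(seeds)
      else if (config$seedMode == "auto")
        autoSeeds(el, config$spawnRadiusUm, px)
      else stop("missing first-frame seeds in manual seed mode")
    if (nrow(sd0) == 0L) stop("missing first-frame seeds in manual seed mode")
    st <- suppressWarnings(
      kmeansAssign(el, sd0, config$kmeansMaxIter, config$kmeansTolPx,
                   bem@frameIndex, px, quiet = TRUE))
    splitTest(st, splitThresholdUm = config$splitThresholdUm,
              offsetPx = config$splitOffsetPx,
              maxIter = config$kmeansMaxIter, tolPx = config$kmeansTolPx)
  }

  histRow <- function(st, cid) {
    ce <- st@centroids
    j <- match(cid, ce$id)
    list(frame = st@frameIndex, sep = ce$mean_separation_um[j],
         cdist = ce$mean_centroid_dist_um[j], n = ce$n_elements[j],
         flagged = ce$n_elements[j] < 2L)
  }
  histKeep <- 4L * config$baselineWindowFrames + 48L
  forced <- list()   # per-frame confirmed mother -> daughter pair overrides
  relink <- function(prevState, state) {
    lk <- linkFrames(prevState, state, config$linkRadiusUm)
    for (fd in forced) {
      pr <- lk$pairs
      pcent <- prevState@centroids
      scent <- state@centroids
      pi <- match(fd$parent, pcent$id)
      keepKids <- fd$kids[fd$kids %in% scent$id]
      pr <- pr[!(pr$to %in% keepKids) & pr$from != fd$parent, , drop = FALSE]
      for (k in keepKids) {
        si <- match(k, scent$id)
        pr <- rbind(pr, data.frame(
          from = fd$parent, to = k,
          dist_px = sqrt((pcent$x[pi] - scent$x[si])^2 +
                           (pcent$y[pi] - scent$y[si])^2)))
      }
      lk$pairs <- pr
      lk$new_progenitors <- setdiff(scent$id, pr$to)
      tb <- table(pr$from)
      lk$division_candidates <- as.integer(names(tb)[tb == 2L])
    }
    lk
  }
  appendHist <- function(h, nw) {
    if (is.null(h)) h <- list(frame = integer(0), sep = numeric(0),
                              flagged = logical(0))
    h$frame <- c(h$frame, nw$frame)
    h$sep <- c(h$sep, nw$sep)
    h$cdist <- c(h$cdist, nw$cdist)
    h$n <- c(h$n, nw$n)
    h$flagged <- c(h$flagged, nw$flagged)
    n <- length(h$frame)
    if (n > histKeep) {
      idx <- (n - histKeep + 1L):n
      h$frame <- h$frame[idx]; h$sep <- h$sep[idx]
      h$cdist <- h$cdist[idx]; h$n <- h$n[idx]
      h$flagged <- h$flagged[idx]
    }
    h
  }
  # median pre-contraction element count: a mean-separation series carried by
  # fewer than minElements points is too unstable to diagnose mitosis
  baselineN <- function(h, onsetFrame) {
    sel <- h$frame < onsetFrame & !h$flagged
    v <- utils::tail(h$n[sel], config$baselineWindowFrames)
    if (length(v) == 0L) return(0)
    stats::median(v)
  }
  motherOk <- function(h, onsetFrame, baseline) {
    baseline <= config$maxBaselineUm &&
      baselineN(h, onsetFrame) >= config$minMotherElements
  }

  prev <- NULL
  for (t in seq_len(nF) - 1L) {
    stack <- src$getFrame(t)
    bem <- detectElements(stack, config$regionPx, config$windowPx,
                          theta = config$theta)
    maps[[t + 1L]] <- bem
    if (t == 0L) {
      st <- clusterFirst(bem)
      for (cid in st@centroids$id)
        reg[[as.character(cid)]] <- list(
          hist = appendHist(NULL, histRow(st, cid)), handled = -Inf)
      states[[1L]] <- st
      prev <- st
      if (nrow(st@centroids) > 0L) nextId <- max(st@centroids$id) + 1L
      next
    }
    el <- bem@elements
    if (nrow(el) == 0L) {
      st <- .emptyClusterState(t, px)
      links[[t]] <- linkFrames(prev, st, config$linkRadiusUm)
      states[[t + 1L]] <- st
      reg <- list()
      prev <- st
      next
    }
    sds <- updateSeeds(prev, el, config$spawnRadiusUm, config$removeRadiusUm,
                       px, nextId = nextId)
    if (nrow(sds) == 0L) sds <- data.frame(id = nextId, x = el[1, 1],
                                           y = el[1, 2])
    nextId <- max(nextId, max(sds$id) + 1L)
    st <- suppressWarnings(
      kmeansAssign(el, sds, config$kmeansMaxIter, config$kmeansTolPx, t, px,
                   quiet = TRUE))
    st <- splitTest(st, splitThresholdUm = config$splitThresholdUm,
                    offsetPx = config$splitOffsetPx,
                    maxIter = config$kmeansMaxIter,
                    tolPx = config$kmeansTolPx, nextId = nextId)
    if (nrow(st@centroids) > 0L) nextId <- max(nextId,
                                               max(st@centroids$id) + 1L)
    forced <- list()
    link <- relink(prev, st)

    # --- online mitosis confirmation: force the split when a track's curve
    # completes the contraction-expansion signature
    emittedParents <- integer(0)
    tried <- integer(0)
    repeat {
      didSplit <- FALSE
      tab <- table(link$pairs$from)
      singles <- as.integer(names(tab)[tab == 1L])
      for (p in setdiff(singles, tried)) {
        r <- reg[[as.character(p)]]
        if (is.null(r)) next
        child <- link$pairs$to[link$pairs$from == p]
        cur <- histRow(st, child)
        scan <- .divisionScan(c(r$hist$frame, cur$frame),
                              c(r$hist$sep, cur$sep),
                              c(r$hist$flagged, cur$flagged),
                              config$baselineWindowFrames,
                              config$contractionFraction)
        ev <- scan$events
        ev <- ev[ev$onset_frame > r$handled, , drop = FALSE]
        if (nrow(ev) == 0L) next
        ev <- ev[nrow(ev), ]
        if (!motherOk(r$hist, ev$onset_frame, ev$baseline_um)) {
          # merged multi-cell cluster or too few elements: not a mother
          reg[[as.character(p)]]$handled <- ev$onset_frame
          next
        }
        if (cur$flagged || cur$sep <= ev$baseline_um) next
        tried <- c(tried, p)
        st2 <- splitTest(st, centroidId = child, force = TRUE,
                         requireImprovement = FALSE,
                         splitThresholdUm = config$splitThresholdUm,
                         offsetPx = config$splitOffsetPx,
                         maxIter = config$kmeansMaxIter,
                         tolPx = config$kmeansTolPx, nextId = nextId)
        if (nrow(st2@centroids) > nrow(st@centroids)) {
          newId <- setdiff(st2@centroids$id, st@centroids$id)
          st <- st2
          nextId <- max(nextId, max(st@centroids$id) + 1L)
          # the re-split defines the daughters: both split products are the
          # mother's children, regardless of the generic link radius
          forced[[length(forced) + 1L]] <- list(parent = p,
                                                kids = c(child, newId))
          link <- relink(prev, st)
          reg[[as.character(p)]]$handled <- ev$onset_frame
          emissions[[length(emissions) + 1L]] <- data.frame(
            parent_centroid = p, frame_confirmed = t,
            frame_min = ev$frame_of_minimum, baseline_um = ev$baseline_um,
            minimum_um = ev$minimum_um)
          emittedParents <- c(emittedParents, p)
          didSplit <- TRUE
          break
        }
      }
      if (!didSplit) break
    }
    # --- two-child parents produced by the split test: emit only when the
    # parent's curve shows the mitotic signature (reconciliation)
    tab <- table(link$pairs$from)
    for (p in setdiff(as.integer(names(tab)[tab == 2L]), emittedParents)) {
      r <- reg[[as.character(p)]]
      if (is.null(r)) next
      scan <- .divisionScan(r$hist$frame, r$hist$sep, r$hist$flagged,
                            config$baselineWindowFrames,
                            config$contractionFraction)
      ev <- scan$events
      ev <- ev[ev$onset_frame > r$handled, , drop = FALSE]
      if (nrow(ev) > 0L) {
        ev <- ev[nrow(ev), ]
        reg[[as.character(p)]]$handled <- ev$onset_frame
        if (!motherOk(r$hist, ev$onset_frame, ev$baseline_um)) next
        emInfo <- data.frame(parent_centroid = p, frame_confirmed = t,
                             frame_min = ev$frame_of_minimum,
                             baseline_um = ev$baseline_um,
                             minimum_um = ev$minimum_um)
      } else if (!is.null(scan$pending) && scan$pending$onset > r$handled) {
        reg[[as.character(p)]]$handled <- scan$pending$onset
        if (!motherOk(r$hist, scan$pending$onset, scan$pending$baseline))
          next
        emInfo <- data.frame(parent_centroid = p, frame_confirmed = t,
                             frame_min = scan$pending$minIdx,
                             baseline_um = scan$pending$baseline,
                             minimum_um = scan$pending$minVal)
      } else next
      emissions[[length(emissions) + 1L]] <- emInfo
      emittedParents <- c(emittedParents, p)
    }
    # --- registry handover to the new frame's centroids
    newReg <- list()
    tab <- table(link$pairs$from)
    for (cid in st@centroids$id) {
      i <- match(cid, link$pairs$to)
      if (is.na(i)) {
        newReg[[as.character(cid)]] <- list(
          hist = appendHist(NULL, histRow(st, cid)), handled = -Inf)
        next
      }
      p <- link$pairs$from[i]
      nkids <- tab[[as.character(p)]]
      inherit <- FALSE
      if (nkids == 1L) {
        inherit <- TRUE
      } else if (!(p %in% emittedParents)) {
        # unconfirmed bifurcation: nearest child keeps the history
        sibs <- link$pairs[link$pairs$from == p, ]
        inherit <- cid == sibs$to[which.min(sibs$dist_px)]
      }
      r <- if (inherit && !is.null(reg[[as.character(p)]]))
        reg[[as.character(p)]] else list(hist = NULL, handled = -Inf)
      r$hist <- appendHist(r$hist, histRow(st, cid))
      newReg[[as.character(cid)]] <- r
    }
    reg <- newReg
    links[[t]] <- link
    states[[t + 1L]] <- st
    prev <- st
    if (verbose)
      message(sprintf("frame %d: %d elements, %d centroids", t, nrow(el),
                      nrow(st@centroids)))
  }

  tg <- buildTrackGraph(links, states, config$frameIntervalMin)
  divisions <- .translateEmissions(emissions, tg)
  divisions <- .validateDivisions(divisions, tg,
                                  config$divisionMinParentAgeFrames)
  lineage <- buildLineage(tg, divisions, lastFrame = nF - 1L)
  motility <- if (nrow(lineage@cells) > 0L) motilityVectors(lineage, tg)
    else NULL
  stats <- populationStats(states, frameIntervalMin = config$frameIntervalMin)
  res <- list(states = states, elementMaps = maps, links = links,
              trackGraph = tg, divisions = divisions, lineage = lineage,
              motility = motility, stats = stats, config = config,
              seedMode = if (is.null(seeds)) config$seedMode else "manual")
  if (!is.null(outDir)) .writeBundle(res, outDir)
  invisible(res)
}

# Keep only divisions whose mother track had a stable identity for a
# biologically plausible time before contracting; signatures on just-born
# fragment tracks are cluster-identity churn, not mitosis.
.validateDivisions <- function(divisions, tg, minAgeFrames) {
  if (nrow(divisions) == 0L) return(divisions)
  tr <- tg@tracks
  start <- tr$start_frame[match(divisions$parent_track, tr$track_id)]
  divisions[start == 0L | divisions$frame_min - start >= minAgeFrames, ,
            drop = FALSE]
}

# Map centroid-level division emissions onto track ids.
.translateEmissions <- function(emissions, tg) {
  empty <- data.frame(parent_track = integer(0), daughter_a = integer(0),
                      daughter_b = integer(0), frame_min = integer(0),
                      frame_confirmed = integer(0), baseline_um = numeric(0),
                      minimum_um = numeric(0))
  if (length(emissions) == 0L) return(empty)
  nd <- tg@nodes
  rows <- lapply(emissions, function(e) {
    pNode <- nd[nd$frame == e$frame_confirmed - 1L &
                  nd$centroid_id == e$parent_centroid, ]
    if (nrow(pNode) == 0L) return(NULL)
    ptid <- pNode$track_id[1L]
    kids <- tg@tracks$track_id[!is.na(tg@tracks$parent_track_id) &
                                 tg@tracks$parent_track_id == ptid &
                                 tg@tracks$start_frame == e$frame_confirmed]
    if (length(kids) != 2L) return(NULL)
    data.frame(parent_track = ptid, daughter_a = kids[1L],
               daughter_b = kids[2L], frame_min = e$frame_min,
               frame_confirmed = e$frame_confirmed,
               baseline_um = e$baseline_um, minimum_um = e$minimum_um)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# Write every pipeline artifact plus a run manifest.
.writeBundle <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeElementsCsv(res$elementMaps, file.path(outDir, "elements.csv"))
  writeClustersCsv(res$states, file.path(outDir, "clusters.csv"))
  writeTracksCsv(res$trackGraph, file.path(outDir, "tracks.csv"))
  writeDivisionsCsv(res$divisions, file.path(outDir, "divisions.csv"))
  writeStatsCsv(res$stats, file.path(outDir, "stats.csv"))
  lineageJSON(res$lineage, file.path(outDir, "lineage.json"))
  writeLines(lineageNewick(res$lineage), file.path(outDir, "lineage.nwk"))
  if (!is.null(res$motility))
    utils::write.csv(res$motility, file.path(outDir, "motility.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "mldcyto",
    version = as.character(utils::packageVersion("mldcyto")),
    seed_mode = res$seedMode,
    n_frames = length(res$states),
    config = res$config[!vapply(res$config, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
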