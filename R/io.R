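# Readers and writers: TIFF stacks in; CSV/JSON/Newick/YAML out.

#' Read a multi-page TIFF as a FrameStack
#'
#' Each page of the file becomes one focal plane. Intensities are read in
#' native integer units (8/16-bit grayscale).
#'
#' @param path TIFF file path.
#' @param frameIndex frame number to record.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalMin minutes between frames (for the timestamp).
#' @return a [FrameStack].
#' @export
readFrameStack <- function(path, frameIndex = 0L, pixelSizeUm = 0.25,
                           frameIntervalMin = 5) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pl <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse any channel dim
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  FrameStack(planes = pl, frameIndex = as.integer(frameIndex),
             timestampMin = frameIndex * frameIntervalMin,
             pixelSizeUm = pixelSizeUm)
}

#' List the TIFF series of a movie directory
#'
#' @param dir directory containing one multi-page TIFF per timepoint (or a
#'   single-plane TIFF series); files are taken in lexical order.
#' @return character vector of paths.
#' @export
listFramePaths <- function(dir) {
  if (!dir.exists(dir)) stop("not a directory: ", dir)
  paths <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(paths) == 0L) stop("no TIFF files found in ", dir)
  paths
}

#' Read a seed file (CSV with columns x_px, y_px)
#'
#' @param path CSV path.
#' @return data.frame with `id`, `x`, `y`.
#' @export
readSeedCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df)))
    stop("seed file needs columns x_px, y_px: ", path)
  data.frame(id = seq_len(nrow(df)), x = df$x_px, y = df$y_px)
}

#' @rdname pipelineWriters
#' @export
writeElementsCsv <- function(maps, path) {
  df <- do.call(rbind, lapply(maps, function(m) {
    e <- m@elements
    if (nrow(e) == 0L)
      return(data.frame(frame_index = integer(0), x_px = numeric(0),
                        y_px = numeric(0), threshold = numeric(0)))
    data.frame(frame_index = m@frameIndex, x_px = e[, 1], y_px = e[, 2],
               threshold = m@thresholdUsed)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname pipelineWriters
#' @export
writeClustersCsv <- function(states, path) {
  df <- do.call(rbind, lapply(states, function(s) {
    ce <- s@centroids
    if (nrow(ce) == 0L)
      return(NULL)
    data.frame(frame = s@frameIndex, centroid_id = ce$id, x = ce$x, y = ce$y,
               n_elements = ce$n_elements,
               mean_separation_um = ce$mean_separation_um,
               silhouette_mean = s@silhouetteMean)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname pipelineWriters
#' @export
writeTracksCsv <- function(trackGraph, path) {
  nd <- trackGraph@nodes
  tr <- trackGraph@tracks
  df <- data.frame(track_id = nd$track_id, frame = nd$frame,
                   centroid_id = nd$centroid_id, x = nd$x, y = nd$y,
                   parent_track_id = tr$parent_track_id[
                     match(nd$track_id, tr$track_id)])
  df <- df[order(df$track_id, df$frame), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname pipelineWriters
#' @export
writeDivisionsCsv <- function(divisions, path) {
  df <- data.frame(parent_track = divisions$parent_track,
                   daughter_a = divisions$daughter_a,
                   daughter_b = divisions$daughter_b,
                   frame_min = divisions$frame_min,
                   frame_confirmed = divisions$frame_confirmed,
                   baseline_um = divisions$baseline_um,
                   minimum_um = divisions$minimum_um)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Writers for pipeline artifacts
#'
#' Each writer emits one plain CSV so any stage of the pipeline can be
#' inspected or diffed: per-frame binary elements
#' (`frame_index,x_px,y_px,threshold`), per-frame clusters
#' (`frame,centroid_id,x,y,n_elements,mean_separation_um,silhouette_mean`),
#' tracks (`track_id,frame,centroid_id,x,y,parent_track_id`), divisions
#' (`parent_track,daughter_a,daughter_b,frame_min,frame_confirmed,baseline_um,minimum_um`),
#' per-frame population statistics, and threshold sweeps.
#'
#' @param maps list of [BinaryElementMap].
#' @param states list of [ClusterState].
#' @param trackGraph a [TrackGraph].
#' @param divisions division event data.frame.
#' @param stats result of [populationStats()].
#' @param sweep result of [thresholdSweep()].
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @name pipelineWriters
#' @export
writeStatsCsv <- function(stats, path) {
  utils::write.csv(stats$perFrame, path, row.names = FALSE)
  invisible(stats$perFrame)
}

#' @rdname pipelineWriters
#' @export
writeSweepCsv <- function(sweep, path) {
  utils::write.csv(sweep$summary, path, row.names = FALSE)
  invisible(sweep$summary)
}

#' Read or write a simulator configuration as YAML
#'
#' @param config a [SimConfig].
#' @param path YAML file path.
#' @return `readSimConfig` returns a [SimConfig]; `writeSimConfig` its path,
#'   invisibly.
#' @export
writeSimConfig <- function(config, path) {
  sl <- slotNames("SimConfig")
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simConfig, vals)
}
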