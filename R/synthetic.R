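# Ground-truthed synthetic time-lapse generator: adherent cells carrying
# quantum-dot-loaded vesicles on a perinuclear ring, random-walk motility,
# mitotic contraction + daughter separation with binomial vesicle
# partitioning, Gaussian spots spread across focal planes, Gaussian
# background noise.

#' Construct a simulator configuration
#'
#' Any [SimConfig] slot can be overridden by name; see the class documentation
#' for the meaning and default of every parameter.
#'
#' @param ... named overrides of `SimConfig` slots, e.g. `nFrames = 60L`,
#'   `snr = 2.5`, `rngSeed = 7L`.
#' @return a validated [SimConfig].
#' @export
#' @examples
#' cfg <- simConfig(fieldUm = c(64, 64), nFrames = 4L, initialCells = 2L)
simConfig <- function(...) {
  args <- list(...)
  intSlots <- c("nPlanes", "nFrames", "initialCells", "vesiclesPerCell",
                "rngSeed")
  if (!is.null(args$fieldUm)) args$fieldUm <- as.numeric(args$fieldUm)
  for (nm in intersect(names(args), intSlots))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimConfig"), args))
}

.frames <- function(cfg) cfg@nFrames
.fieldPx <- function(cfg) round(cfg@fieldUm / cfg@pixelSizeUm)

# Spot amplitude (above background) needed for rendered-peak / realized
# mu+sigma threshold to equal the configured SNR. The composite's mean and
# sd include the spots themselves, so the amplitude is solved as a fixed
# point of theta(A) = mu_bg + E[spots](A) + sqrt(sd_bg^2 + Var[spots](A)).
.spotAmplitude <- function(cfg, nVesicles) {
  mu <- cfg@backgroundMean; sd <- cfg@backgroundSd
  if (nVesicles < 1L) return(cfg@snr * (mu + sd) - mu)
  px <- .fieldPx(cfg)
  npx <- px[1] * px[2]
  sigPx <- cfg@spotSigmaUm / cfg@pixelSizeUm
  cvf <- 1 + cfg@intensityCv^2
  theta <- function(A) {
    e1 <- nVesicles * A * 2 * pi * sigPx^2 / npx
    e2 <- nVesicles * A^2 * cvf * pi * sigPx^2 / npx
    mu + e1 + sqrt(sd^2 + max(0, e2 - e1^2))
  }
  f <- function(A) cfg@snr * theta(A) - mu - A
  hi <- 1e7
  if (f(hi) > 0)
    stop("configured SNR is unattainable at this vesicle density: ",
         "the spots' own contribution to the mu + sigma threshold grows ",
         "faster than their amplitude; reduce density or SNR")
  stats::uniroot(f, c(1e-6, hi), tol = 1e-6)$root
}

#' Simulate the ground-truth cell and vesicle history of a movie
#'
#' Runs the biological model only (no pixels): initial cells are placed with
#' a minimum pairwise separation and uniformly random cell-cycle ages; cells
#' random-walk; each cell divides at its inter-mitotic time (Gaussian,
#' truncated at 2 h), contracting its vesicle cloud over the preceding
#' `contractionMin` minutes, partitioning vesicles binomially between the
#' daughters, which then separate to `separationUm` over `separationMin`
#' minutes while their vesicle rings re-expand; cells leaving the field end
#' with reason `"exit"`; new cells may enter at `entryRatePerH`.
#'
#' @param config a [SimConfig].
#' @return a [GroundTruth].
#' @export
simulateGroundTruth <- function(config) {
  stopifnot(is(config, "SimConfig"))
  cfg <- config
  set.seed(cfg@rngSeed)
  dtMin <- cfg@frameIntervalMin
  nF <- cfg@nFrames
  fw <- cfg@fieldUm[1]; fh <- cfg@fieldUm[2]
  stepSd <- cfg@motilityUmPerH * (dtMin / 60) / sqrt(pi / 2)
  mar <- cfg@domainMarginUm
  cF <- max(1L, round(cfg@contractionMin / dtMin))
  sF <- max(1L, round(cfg@separationMin / dtMin))
  reexpF <- cF   # ring re-expansion mirrors the contraction duration
  drawImt <- function(n) pmax(120, stats::rnorm(n, cfg@imtHours * 60,
                                                cfg@imtSdHours * 60))
  margin <- cfg@cellDiameterUm / 2

  # --- initial placement over the extended domain (field + margin) with
  # minimum pairwise separation (dart throwing); initialCells is the expected
  # in-field count, scaled up by the area ratio for the whole domain
  placeInitial <- function(n, minSep) {
    nTotal <- round(n * (fw + 2 * mar) * (fh + 2 * mar) / (fw * fh))
    pos <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pos) < nTotal && tries < 50000L) {
      p <- c(stats::runif(1, -mar + margin, fw + mar - margin),
             stats::runif(1, -mar + margin, fh + mar - margin))
      if (nrow(pos) == 0L || min(sqrt((pos[, 1] - p[1])^2 +
                                      (pos[, 2] - p[2])^2)) >= minSep) {
        pos <- rbind(pos, p)
      }
      tries <- tries + 1L
    }
    if (nrow(pos) < nTotal)
      warning("could not place all initial cells at the requested separation")
    pos
  }
  pos0 <- placeInitial(cfg@initialCells, cfg@minInitialSeparationUm)

  nextCell <- 1L; nextVes <- 1L
  cellRows <- list(); posRows <- list(); vesRows <- list(); attrRows <- list()
  active <- list()

  newVesicles <- function(n, cellId, frame) {
    ids <- seq.int(nextVes, length.out = n)
    nextVes <<- nextVes + n
    attrRows[[length(attrRows) + 1L]] <<- data.frame(
      vesicle_id = ids,
      angle = stats::runif(n, 0, 2 * pi),
      rfac = pmax(0.15, stats::rnorm(n, 1, 0.3)),
      z = stats::rnorm(n, 0, cfg@zSdPlanes),
      ifac = exp(stats::rnorm(n, 0, cfg@intensityCv)))
    ids
  }
  openOwnership <- function(ves, cellId, frame) {
    if (length(ves) == 0L) return(invisible(NULL))
    vesRows[[length(vesRows) + 1L]] <<- data.frame(
      vesicle_id = ves, cell_id = cellId, start_frame = frame,
      end_frame = NA_integer_)
  }
  spawnCell <- function(x, y, parent, birthFrame, ves, ageMin, sepAxis = NULL) {
    id <- nextCell; nextCell <<- nextCell + 1L
    if (nextCell > 10000L) stop("simulation exceeded 10^4 cells")
    imt <- drawImt(1)
    divFrame <- floor((birthFrame * dtMin + (imt - ageMin)) / dtMin)
    if (divFrame <= birthFrame) divFrame <- birthFrame + 1L
    z <- min(max(stats::rnorm(1, (cfg@nPlanes - 1) / 2, 0.5), 0),
             cfg@nPlanes - 1)
    openOwnership(ves, id, birthFrame)
    active[[as.character(id)]] <<- list(
      id = id, parent = parent, birth = birthFrame, x = x, y = y, z = z,
      divFrame = divFrame, ves = ves, sepAxis = sepAxis)
    id
  }
  endCell <- function(id, frame, reason, divFrame = NA_integer_) {
    a <- active[[as.character(id)]]
    cellRows[[length(cellRows) + 1L]] <<- data.frame(
      cell_id = a$id, parent_id = a$parent, birth_frame = a$birth,
      end_frame = frame, end_reason = reason, division_frame = divFrame,
      n_vesicles = length(a$ves), z_planes = a$z)
    for (i in seq_along(vesRows)) {
      sel <- vesRows[[i]]$cell_id == id & is.na(vesRows[[i]]$end_frame)
      vesRows[[i]]$end_frame[sel] <<- frame
    }
    active[[as.character(id)]] <<- NULL
  }

  for (i in seq_len(nrow(pos0))) {
    nv <- sample(cfg@vesiclesPerCell[1]:cfg@vesiclesPerCell[2], 1)
    age <- switch(cfg@initialAgeMode,
      uniform = stats::runif(1, 0, cfg@imtHours * 60),
      # stationary age density of exponential growth: f(a) ~ 2^(-a/T)
      stationary = -cfg@imtHours * 60 *
        log2(1 - stats::runif(1) / 2),
      zero = 0)
    spawnCell(pos0[i, 1], pos0[i, 2], NA_integer_, 0L,
              newVesicles(nv, nextCell, 0L), age)
  }

  for (t in seq_len(nF) - 1L) {
    # entries
    if (cfg@entryRatePerH > 0 && t > 0L) {
      nIn <- stats::rpois(1, cfg@entryRatePerH * dtMin / 60)
      for (k in seq_len(nIn)) {
        side <- sample(4, 1)
        p <- switch(side,
                    c(2, stats::runif(1, 0, fh)),
                    c(fw - 2, stats::runif(1, 0, fh)),
                    c(stats::runif(1, 0, fw), 2),
                    c(stats::runif(1, 0, fw), fh - 2))
        nv <- sample(cfg@vesiclesPerCell[1]:cfg@vesiclesPerCell[2], 1)
        spawnCell(p[1], p[2], NA_integer_, t,
                  newVesicles(nv, nextCell, t),
                  stats::runif(1, 0, cfg@imtHours * 60))
      }
    }
    # divisions scheduled for this frame
    for (id in names(active)) {
      a <- active[[id]]
      if (!is.na(a$divFrame) && a$divFrame == t && t > a$birth) {
        u <- stats::runif(1, 0, 2 * pi)
        axis <- c(cos(u), sin(u))
        toA <- stats::rbinom(length(a$ves), 1, 0.5) == 1L
        endCell(a$id, t - 1L, "division", divFrame = t)
        spawnCell(a$x, a$y, a$id, t, a$ves[toA], 0, sepAxis = axis)
        spawnCell(a$x, a$y, a$id, t, a$ves[!toA], 0, sepAxis = -axis)
      }
    }
    # motion + bookkeeping
    for (id in names(active)) {
      a <- active[[id]]
      if (a$birth < t) {
        a$x <- a$x + stats::rnorm(1, 0, stepSd)
        a$y <- a$y + stats::rnorm(1, 0, stepSd)
        if (!is.null(a$sepAxis) && (t - a$birth) <= sF) {
          drift <- cfg@separationUm / (2 * sF)
          a$x <- a$x + drift * a$sepAxis[1]
          a$y <- a$y + drift * a$sepAxis[2]
        }
        active[[id]] <- a
      }
      if (a$x < -mar - 2 || a$x > fw + mar + 2 ||
          a$y < -mar - 2 || a$y > fh + mar + 2) {
        endCell(a$id, t - 1L, "exit")
        next
      }
      age <- t - a$birth
      if (!is.na(a$divFrame) && t >= a$divFrame - cF && t < a$divFrame) {
        phase <- "contracting"
        fr <- (t - (a$divFrame - cF)) / cF
        rad <- cfg@ringRadiusUm + (cfg@condensedRadiusUm -
                                     cfg@ringRadiusUm) * fr
      } else if (!is.na(a$parent) && age < reexpF) {
        phase <- "separating"
        rad <- cfg@condensedRadiusUm + (cfg@ringRadiusUm -
                                          cfg@condensedRadiusUm) * age / reexpF
      } else {
        phase <- "interphase"
        rad <- cfg@ringRadiusUm
      }
      posRows[[length(posRows) + 1L]] <- c(
        t, a$id, a$x / cfg@pixelSizeUm, a$y / cfg@pixelSizeUm,
        match(phase, c("interphase", "contracting", "separating")), rad,
        as.integer(a$x >= 0 && a$x <= fw && a$y >= 0 && a$y <= fh))
    }
  }
  for (id in names(active)) endCell(id, nF - 1L, "movie_end")

  cellsDf <- if (length(cellRows)) do.call(rbind, cellRows) else
    data.frame(cell_id = integer(0), parent_id = integer(0),
               birth_frame = integer(0), end_frame = integer(0),
               end_reason = character(0), division_frame = integer(0),
               n_vesicles = integer(0), z_planes = numeric(0))
  cellsDf <- cellsDf[order(cellsDf$cell_id), ]
  rownames(cellsDf) <- NULL
  posDf <- if (length(posRows)) {
    pm <- do.call(rbind, posRows)
    data.frame(frame = as.integer(pm[, 1]), cell_id = as.integer(pm[, 2]),
               x_px = pm[, 3], y_px = pm[, 4],
               phase = c("interphase", "contracting",
                         "separating")[pm[, 5]],
               cloud_radius_um = pm[, 6], in_field = pm[, 7] == 1)
  } else
    data.frame(frame = integer(0), cell_id = integer(0), x_px = numeric(0),
               y_px = numeric(0), phase = character(0),
               cloud_radius_um = numeric(0), in_field = logical(0))
  vesDf <- if (length(vesRows)) do.call(rbind, vesRows) else
    data.frame(vesicle_id = integer(0), cell_id = integer(0),
               start_frame = integer(0), end_frame = integer(0))
  gt <- GroundTruth(cells = cellsDf, positions = posDf, vesicles = vesDf,
                    config = cfg)
  attr(gt, "vesicleAttrs") <- if (length(attrRows)) do.call(rbind, attrRows)
    else data.frame(vesicle_id = integer(0), angle = numeric(0),
                    rfac = numeric(0), z = numeric(0), ifac = numeric(0))
  n0 <- sum(vesDf$start_frame == 0L)
  attr(gt, "spotAmplitude") <- .spotAmplitude(cfg, n0)
  gt
}

#' True vesicle spot positions of one frame
#'
#' The jittered per-frame spot coordinates used by the renderer, exposed so
#' tests and analyses can compare detected elements with the exact rendered
#' truth. Coordinates are 0-based pixels.
#'
#' @param truth a [GroundTruth].
#' @param frame frame index (0-based).
#' @return data.frame: `cell_id`, `vesicle_id`, `x_px`, `y_px`, `z_planes`,
#'   `intensity_factor`.
#' @export
trueSpots <- function(truth, frame) {
  cfg <- truth@config
  vattr <- attr(truth, "vesicleAttrs")
  set.seed(.subSeed(cfg@rngSeed, frame + 1L))
  pos <- truth@positions
  pos <- pos[pos$frame == frame, , drop = FALSE]
  pos <- pos[order(pos$cell_id), , drop = FALSE]
  ves <- truth@vesicles
  cells <- list(); vids <- list()
  for (i in seq_len(nrow(pos))) {
    cid <- pos$cell_id[i]
    vIds <- sort(ves$vesicle_id[ves$cell_id == cid & ves$start_frame <= frame &
                                  (is.na(ves$end_frame) |
                                     ves$end_frame >= frame)])
    if (length(vIds) == 0L) next
    cells[[length(cells) + 1L]] <- rep(cid, length(vIds))
    vids[[length(vids) + 1L]] <- vIds
  }
  if (length(vids) == 0L)
    return(data.frame(cell_id = integer(0), vesicle_id = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      z_planes = numeric(0), intensity_factor = numeric(0)))
  cellId <- unlist(cells)
  vid <- unlist(vids)
  va <- vattr[match(vid, vattr$vesicle_id), ]
  pi <- match(cellId, pos$cell_id)
  radPx <- pos$cloud_radius_um[pi] / cfg@pixelSizeUm
  jitPx <- cfg@ringJitterUm / cfg@pixelSizeUm *
    pmin(1, pos$cloud_radius_um[pi] / cfg@ringRadiusUm)
  n <- length(vid)
  # draw order (angles, then x jitter, then y jitter) is part of the
  # reproducibility contract for a given seed and frame
  ang <- va$angle + stats::rnorm(n, 0, 0.05)
  vx <- pos$x_px[pi] + radPx * va$rfac * cos(ang) + stats::rnorm(n, 0, 1) *
    jitPx
  vy <- pos$y_px[pi] + radPx * va$rfac * sin(ang) + stats::rnorm(n, 0, 1) *
    jitPx
  cz <- truth@cells$z_planes[match(cellId, truth@cells$cell_id)]
  zv <- pmin(pmax(cz + va$z, 0), cfg@nPlanes - 1)
  data.frame(cell_id = cellId, vesicle_id = vid, x_px = vx, y_px = vy,
             z_planes = zv, intensity_factor = va$ifac)
}

#' Render one synthetic frame
#'
#' Deterministically renders the focal-plane stack of one timepoint from a
#' [GroundTruth]: each vesicle becomes a 2-D Gaussian spot placed on its
#' cell's (possibly contracted) perinuclear ring with per-frame jitter, its
#' intensity distributed across planes by a Gaussian z-profile (normalized so
#' the nearest plane carries the full amplitude); Gaussian background noise is
#' added and intensities are rounded to integer detector units. The per-frame
#' random stream is derived from the configured seed and the frame index, so
#' any frame can be rendered independently and reproducibly.
#'
#' @param truth a [GroundTruth] from [simulateGroundTruth()].
#' @param frame frame index (0-based).
#' @return a [FrameStack].
#' @export
renderFrame <- function(truth, frame) {
  cfg <- truth@config
  px <- .fieldPx(cfg)
  W <- px[1]; H <- px[2]
  sigPx <- cfg@spotSigmaUm / cfg@pixelSizeUm
  amp <- attr(truth, "spotAmplitude")
  spots <- trueSpots(truth, frame)   # also positions the per-frame RNG stream
  half <- as.integer(ceiling(3 * sigPx))
  zPlanes <- seq_len(cfg@nPlanes) - 1
  inField <- spots$x_px >= 0 & spots$x_px <= W - 1 &
    spots$y_px >= 0 & spots$y_px <= H - 1
  spots <- spots[inField, , drop = FALSE]
  # z-profile plane weights, normalized so the nearest plane is full strength
  prof <- outer(spots$z_planes, zPlanes,
                function(z, p) exp(-(p - z)^2 / (2 * cfg@zProfileSdPlanes^2)))
  if (nrow(spots) > 0L) prof <- prof / apply(prof, 1, max)
  # interior spots: one vectorized scatter-add per plane
  interior <- spots$x_px >= half & spots$x_px <= W - 1 - half &
    spots$y_px >= half & spots$y_px <= H - 1 - half
  off <- -half:half
  nOff <- length(off)
  gy <- rep(off, times = nOff)            # patch row offsets (column-major)
  gx <- rep(off, each = nOff)
  si <- which(interior)
  if (length(si) > 0L) {
    fy <- spots$y_px[si] - floor(spots$y_px[si])
    fx <- spots$x_px[si] - floor(spots$x_px[si])
    # squared distance of each patch pixel from the true sub-pixel centre
    d2 <- outer(gy, fy, "-")^2 + outer(gx, fx, "-")^2
    base <- amp * spots$intensity_factor[si]
    patch0 <- exp(-d2 / (2 * sigPx^2))    # (nOff^2) x nspots
    idx <- rep((floor(spots$x_px[si])) * H + floor(spots$y_px[si]) + 1L,
               each = nOff * nOff) +
      rep.int(gx * H + gy, length(si))
  }
  planes <- vector("list", cfg@nPlanes)
  for (p in seq_len(cfg@nPlanes)) {
    m <- cfg@backgroundMean + matrix(stats::rnorm(H * W, 0, cfg@backgroundSd),
                                     H, W)
    if (length(si) > 0L) {
      w <- base * prof[si, p]
      keep <- w > 0.05 * amp
      if (any(keep)) {
        kcol <- rep(keep, each = nOff * nOff)
        vals <- as.vector(sweep(patch0[, keep, drop = FALSE], 2, w[keep],
                                "*"))
        ii <- idx[kcol]
        agg <- rowsum(vals, ii)           # overlapping spots accumulate
        ai <- as.integer(rownames(agg))
        m[ai] <- m[ai] + agg[, 1]
      }
    }
    # boundary spots: slow path
    for (k in which(!interior)) {
      f <- prof[k, p]
      if (amp * spots$intensity_factor[k] * f <= 0.05 * amp) next
      vx <- spots$x_px[k]; vy <- spots$y_px[k]
      r0 <- max(1L, floor(vy) + 1L - half)
      r1 <- min(H, floor(vy) + 1L + half)
      c0 <- max(1L, floor(vx) + 1L - half)
      c1 <- min(W, floor(vx) + 1L + half)
      if (r0 > r1 || c0 > c1) next
      ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
      m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] +
        amp * spots$intensity_factor[k] * f *
          exp(-(outer((ys - vy)^2, (xs - vx)^2, "+")) / (2 * sigPx^2))
    }
    planes[[p]] <- round(pmax(m, 0))
  }
  FrameStack(planes = planes, frameIndex = as.integer(frame),
             timestampMin = frame * cfg@frameIntervalMin,
             pixelSizeUm = cfg@pixelSizeUm)
}

#' Simulate a full movie
#'
#' Convenience wrapper: ground truth plus all rendered [FrameStack]s. For
#' long or large movies prefer [frameGenerator()], which renders frames on
#' demand.
#'
#' @param config a [SimConfig].
#' @return list with `stacks` (list of [FrameStack]) and `truth`
#'   ([GroundTruth]).
#' @export
simulateMovie <- function(config) {
  truth <- simulateGroundTruth(config)
  stacks <- lapply(seq_len(config@nFrames) - 1L, renderFrame, truth = truth)
  list(stacks = stacks, truth = truth)
}

#' Streaming frame source for a synthetic movie
#'
#' @param config a [SimConfig].
#' @return list with `truth`, `nFrames`, and `getFrame(frame)` rendering the
#'   requested 0-based frame.
#' @export
frameGenerator <- function(config) {
  truth <- simulateGroundTruth(config)
  list(truth = truth, nFrames = config@nFrames,
       getFrame = function(frame) renderFrame(truth, frame))
}

#' Write a synthetic movie to disk as a pipeline-readable fixture
#'
#' Writes one multi-page 16-bit grayscale TIFF per timepoint
#' (`frame_0000.tif`, ...), the ground truth as CSV (`truth_cells.csv`,
#' `truth_positions.csv`, `truth_vesicles.csv`), and the configuration as
#' YAML (`sim_config.yaml`).
#'
#' @param config a [SimConfig].
#' @param outDir output directory (created if needed).
#' @return invisibly, the list of TIFF paths.
#' @export
renderFixture <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  gen <- frameGenerator(config)
  paths <- character(gen$nFrames)
  for (t in seq_len(gen$nFrames) - 1L) {
    fs <- gen$getFrame(t)
    paths[t + 1L] <- file.path(outDir, sprintf("frame_%04d.tif", t))
    ok <- try(tiff::writeTIFF(lapply(fs@planes, function(p)
      pmin(p, 65535) / 65535), paths[t + 1L], bits.per.sample = 16L),
      silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write TIFF at ", paths[t + 1L], ": ",
           attr(ok, "condition")$message)
  }
  tr <- gen$truth
  utils::write.csv(tr@cells, file.path(outDir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tr@positions, file.path(outDir, "truth_positions.csv"),
                   row.names = FALSE)
  utils::write.csv(tr@vesicles, file.path(outDir, "truth_vesicles.csv"),
                   row.names = FALSE)
  writeSimConfig(config, file.path(outDir, "sim_config.yaml"))
  invisible(paths)
}
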