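test_that("no cells means empty truth and a pure-noise movie", {
  cfg <- simConfig(fieldUm = c(32, 32), pixelSizeUm = 0.5, nFrames = 2L,
                   initialCells = 0L, nPlanes = 2L, domainMarginUm = 0,
                   rngSeed = 1L)
  tr <- simulateGroundTruth(cfg)
  expect_equal(nrow(cells(tr)), 0L)
  fs <- renderFrame(tr, 0)
  expect_equal(length(planes(fs)), 2L)
  expect_lt(abs(mean(planes(fs)[[1]]) - 400), 3)
})

test_that("the same seed reproduces bit-identical pixels and truth", {
  cfg <- simConfig(fieldUm = c(48, 48), pixelSizeUm = 0.5, nFrames = 3L,
                   initialCells = 2L, nPlanes = 2L, domainMarginUm = 0,
                   vesiclesPerCell = c(8L, 12L), minInitialSeparationUm = 20,
                   rngSeed = 77L)
  a <- simulateMovie(cfg)
  b <- simulateMovie(cfg)
  expect_identical(cells(a$truth), cells(b$truth))
  for (f in 1:3)
    expect_identical(planes(a$stacks[[f]]), planes(b$stacks[[f]]))
  # frames render identically regardless of evaluation order
  tr <- simulateGroundTruth(cfg)
  f2 <- renderFrame(tr, 2)
  expect_identical(planes(f2), planes(a$stacks[[3]]))
})

test_that("a newborn cell with a 23 h cycle divides once in a 40 h movie", {
  cfg <- simConfig(fieldUm = c(64, 64), pixelSizeUm = 0.5, nFrames = 480L,
                   initialCells = 1L, nPlanes = 1L, imtHours = 23,
                   imtSdHours = 0.5, initialAgeMode = "zero",
                   domainMarginUm = 0, motilityUmPerH = 2, rngSeed = 3L)
  tr <- simulateGroundTruth(cfg)
  tc <- cells(tr)
  div <- tc$division_frame[!is.na(tc$division_frame)]
  expect_length(div, 1L)
  expect_lt(abs(div * 5 / 60 - 23), 1.5)  # within per-seed jitter
})

test_that("vesicles are conserved and partitioned at division", {
  cfg <- simConfig(fieldUm = c(64, 64), pixelSizeUm = 0.5, nFrames = 60L,
                   initialCells = 1L, nPlanes = 1L, imtHours = 2,
                   imtSdHours = 0.1, initialAgeMode = "zero",
                   domainMarginUm = 0, motilityUmPerH = 2, rngSeed = 4L)
  tr <- simulateGroundTruth(cfg)
  tc <- cells(tr)
  mother <- tc[!is.na(tc$division_frame), ][1, ]
  kids <- tc[!is.na(tc$parent_id) & tc$parent_id == mother$cell_id, ]
  expect_equal(nrow(kids), 2L)
  expect_equal(sum(kids$n_vesicles), mother$n_vesicles)
  ves <- tr@vesicles
  mv <- ves$vesicle_id[ves$cell_id == mother$cell_id]
  kv <- ves$vesicle_id[ves$cell_id %in% kids$cell_id]
  expect_setequal(kv, mv)                      # same vesicles, repartitioned
  expect_equal(anyDuplicated(kv), 0L)          # a vesicle goes to one daughter
  expect_equal(kids$birth_frame, rep(mother$division_frame, 2))
})

test_that("population growth is monotone without exits", {
  cfg <- simConfig(fieldUm = c(200, 200), pixelSizeUm = 0.5, nFrames = 120L,
                   initialCells = 4L, nPlanes = 1L, imtHours = 4,
                   imtSdHours = 0.3, motilityUmPerH = 2, domainMarginUm = 0,
                   minInitialSeparationUm = 40, rngSeed = 6L)
  tr <- simulateGroundTruth(cfg)
  pos <- tr@positions
  n <- vapply(0:119, function(f) sum(pos$frame == f), integer(1))
  expect_true(all(diff(n) >= 0L))
  expect_gt(n[120], n[1])
})

test_that("rendered spot peaks over the realized threshold match the configured SNR", {
  cfg <- simConfig(fieldUm = c(168, 128), pixelSizeUm = 0.5, nFrames = 1L,
                   initialCells = 10L, nPlanes = 2L, snr = 2.5,
                   zSdPlanes = 0.2, minInitialSeparationUm = 24,
                   domainMarginUm = 0, rngSeed = 8L)
  tr <- simulateGroundTruth(cfg)
  amp <- attr(tr, "spotAmplitude")
  fs <- renderFrame(tr, 0)
  comp <- fuseFocalPlanes(fs, 32)
  theta <- computeThreshold(comp)
  sp <- trueSpots(tr, 0)
  ok <- sp$x_px > 3 & sp$x_px < 332 & sp$y_px > 3 & sp$y_px < 252
  # isolated spots only: overlapping neighbours inflate the apparent peak
  dmin <- apply(as.matrix(stats::dist(cbind(sp$x_px, sp$y_px))) +
                  diag(Inf, nrow(sp)), 1, min)
  ok <- ok & dmin > 6
  # per-spot amplitude estimate: subtract the background, undo the spot's
  # intensity factor and the z-profile factor of the plane the fusion chose
  # for its block, then put the mean rendered peak over the realized theta
  sigPx <- cfg@spotSigmaUm / cfg@pixelSizeUm
  ampHat <- vapply(which(ok), function(k) {
    r <- round(sp$y_px[k]); cc <- round(sp$x_px[k])
    pk <- intensity(comp)[r + 1, cc + 1]
    d2 <- (r - sp$y_px[k])^2 + (cc - sp$x_px[k])^2
    plane <- sourcePlane(comp)[r + 1, cc + 1]
    prof <- exp(-((seq_len(cfg@nPlanes) - 1) - sp$z_planes[k])^2 /
                  (2 * cfg@zProfileSdPlanes^2))
    f <- prof[plane] / max(prof)
    (pk - cfg@backgroundMean) /
      (sp$intensity_factor[k] * f * exp(-d2 / (2 * sigPx^2)))
  }, numeric(1))
  renderedPeak <- mean(ampHat) + cfg@backgroundMean
  expect_lt(abs(renderedPeak / theta - cfg@snr) / cfg@snr, 0.05)
})

test_that("a fixture round-trips through TIFF with counts near vesicle truth", {
  outDir <- file.path(tempdir(), "mldfix")
  cfg <- simConfig(fieldUm = c(72, 72), pixelSizeUm = 0.5, nFrames = 2L,
                   initialCells = 3L, nPlanes = 2L, snr = 4,
                   vesiclesPerCell = c(10L, 14L), minInitialSeparationUm = 22,
                   domainMarginUm = 0, zSdPlanes = 0.2, rngSeed = 9L)
  paths <- renderFixture(cfg, outDir)
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
  mv <- simulateMovie(cfg)
  fs <- readFrameStack(paths[1], frameIndex = 0L, pixelSizeUm = 0.5)
  expect_equal(length(planes(fs)), 2L)
  expect_equal(planes(fs)[[1]], planes(mv$stacks[[1]])[[1]])
  cfg2 <- readSimConfig(file.path(outDir, "sim_config.yaml"))
  expect_equal(cfg2@snr, 4)
  expect_equal(cfg2@vesiclesPerCell, c(10L, 14L))
  # element counts per cell within Poisson-scale error of the vesicle counts
  bem <- detectElements(fs)
  sp <- trueSpots(mv$truth, 0)
  el <- elements(bem)
  for (cid in unique(sp$cell_id)) {
    s <- sp[sp$cell_id == cid, ]
    nTrue <- nrow(s)
    nDet <- sum(sqrt((el[, 1] - mean(s$x_px))^2 +
                       (el[, 2] - mean(s$y_px))^2) < 24)
    expect_gte(nDet, nTrue - 3 * sqrt(nTrue))
    expect_lte(nDet, nTrue + 3)
  }
})

test_that("an unattainable SNR at extreme density fails loudly", {
  cfg <- simConfig(fieldUm = c(24, 24), pixelSizeUm = 0.5, nFrames = 1L,
                   initialCells = 6L, vesiclesPerCell = c(50L, 50L),
                   minInitialSeparationUm = 5, domainMarginUm = 0,
                   rngSeed = 10L)
  expect_error(simulateGroundTruth(cfg), "unattainable")
})
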