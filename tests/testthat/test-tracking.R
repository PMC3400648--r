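mkState <- function(coords, frame, ids = seq_len(nrow(coords)), px = 0.25) {
  # one singleton element per centroid keeps linkage geometry exact
  ClusterState(
    frameIndex = as.integer(frame),
    elements = matrix(coords, ncol = 2, dimnames = list(NULL, c("x", "y"))),
    centroids = data.frame(id = ids, x = coords[, 1], y = coords[, 2],
                           n_elements = 1L, mean_separation_um = 0,
                           mean_centroid_dist_um = 0),
    assignment = as.integer(ids), silhouetteMean = 0, pixelSizeUm = px)
}

test_that("identical centroid sets map to the identity with no candidates", {
  co <- cbind(c(10, 100, 200), c(10, 100, 50))
  lk <- linkFrames(mkState(co, 0), mkState(co, 1), linkRadiusUm = 10)
  expect_equal(lk$pairs$from, lk$pairs$to)
  expect_length(lk$division_candidates, 0)
  expect_length(lk$new_progenitors, 0)
})

test_that("two close children flag a division candidate; far centroids are progenitors", {
  a <- mkState(cbind(100, 100), 0)
  b <- mkState(cbind(c(85, 115), c(100, 100)), 1, ids = 1:2)
  lk <- linkFrames(a, b, linkRadiusUm = 10)  # both within 40 px = 10 um
  expect_equal(sort(lk$pairs$to), 1:2)
  expect_equal(lk$division_candidates, 1L)
  # a centroid 40 um from everything becomes a new progenitor
  c2 <- mkState(cbind(c(100, 260), c(100, 100)), 1, ids = 1:2)
  lk2 <- linkFrames(a, c2, linkRadiusUm = 10)
  expect_equal(lk2$pairs$to, 1L)
  expect_equal(lk2$new_progenitors, 2L)
  # a third nearby child is disallowed
  d3 <- mkState(cbind(c(90, 100, 110), c(100, 100, 100)), 1, ids = 1:3)
  lk3 <- linkFrames(a, d3, linkRadiusUm = 10)
  expect_equal(nrow(lk3$pairs), 2L)
  expect_length(lk3$new_progenitors, 1L)
})

test_that("greedy ascending matching equals brute-force sequential assignment", {
  set.seed(13)
  for (rep in 1:30) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- data.frame(id = seq_len(na), x = runif(na, 0, 120),
                    y = runif(na, 0, 120))
    b <- data.frame(id = seq_len(nb), x = runif(nb, 0, 120),
                    y = runif(nb, 0, 120))
    lk <- linkFrames(mkState(cbind(a$x, a$y), 0, a$id),
                     mkState(cbind(b$x, b$y), 1, b$id), linkRadiusUm = 10)
    ref <- bruteGreedyMatch(a, b, 40)
    got <- lk$pairs[order(lk$pairs$from, lk$pairs$to), c("from", "to")]
    if (is.null(ref)) {
      expect_equal(nrow(got), 0L)
    } else {
      ref <- ref[order(ref$from, ref$to), c("from", "to")]
      rownames(got) <- rownames(ref) <- NULL
      expect_equal(got, ref)
    }
  }
})

test_that("track assembly yields paths, division bifurcations, and valid graphs", {
  # one cell over five frames: a single track
  sts <- lapply(0:4, function(f) mkState(cbind(100 + f, 100), f))
  lks <- lapply(1:4, function(f) linkFrames(sts[[f]], sts[[f + 1]], 10))
  tg <- buildTrackGraph(lks, sts)
  expect_equal(nrow(tracks(tg)), 1L)
  expect_equal(tracks(tg)$start_frame, 0L)
  expect_equal(tracks(tg)$end_frame, 4L)
  # a division at frame 2 gives a binary tree of three tracks
  sts2 <- list(mkState(cbind(100, 100), 0), mkState(cbind(100, 100), 1),
               mkState(cbind(c(90, 110), c(100, 100)), 2, 1:2),
               mkState(cbind(c(85, 115), c(100, 100)), 3, 1:2))
  lks2 <- lapply(1:3, function(f) linkFrames(sts2[[f]], sts2[[f + 1]], 10))
  tg2 <- buildTrackGraph(lks2, sts2)
  tr <- tracks(tg2)
  expect_equal(nrow(tr), 3L)
  expect_equal(sum(is.na(tr$parent_track_id)), 1L)
  expect_true(validObject(tg2))
  # non-consecutive link records error
  expect_error(buildTrackGraph(lks2[c(1, 3)], sts2[c(1, 2, 4)]),
               "consecutive")
})

test_that("links are 100% identity-preserving on a well-separated simulation", {
  cfg <- simConfig(fieldUm = c(160, 120), pixelSizeUm = 0.5, nFrames = 40L,
                   initialCells = 6L, nPlanes = 1L, imtHours = 400,
                   minInitialSeparationUm = 32, domainMarginUm = 0,
                   motilityUmPerH = 10, rngSeed = 14L)
  tr <- simulateGroundTruth(cfg)
  res <- runPipeline(frameGenerator(cfg), pipelineConfig(pixelSizeUm = 0.5),
                     seeds = truthSeeds(tr))
  tt <- tracks(res$trackGraph)
  expect_equal(nrow(tt), 6L)
  expect_true(all(tt$start_frame == 0L & tt$end_frame == 39L))
  # every track stays on its own true cell
  nd <- trackNodes(res$trackGraph)
  pos <- tr@positions
  for (tid in tt$track_id) {
    own <- vapply(which(nd$track_id == tid), function(i) {
      p <- pos[pos$frame == nd$frame[i], ]
      p$cell_id[which.min((p$x_px - nd$x[i])^2 + (p$y_px - nd$y[i])^2)]
    }, numeric(1))
    expect_length(unique(own), 1)
  }
})
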