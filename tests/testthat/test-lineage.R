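mkGraph <- function(trk, nodes, px = 0.25, dt = 5) {
  TrackGraph(nodes = nodes, tracks = trk, pixelSizeUm = px,
             frameIntervalMin = dt)
}

# a track graph with one progenitor and two rounds of division
twoRounds <- function() {
  trk <- data.frame(
    track_id = 1:7,
    parent_track_id = c(NA, 1, 1, 2, 2, 3, 3),
    start_frame = c(0, 10, 10, 20, 20, 22, 22),
    end_frame = c(9, 19, 21, 30, 30, 30, 30))
  nodes <- do.call(rbind, lapply(1:7, function(i) {
    f <- trk$start_frame[i]:trk$end_frame[i]
    data.frame(frame = f, centroid_id = i, track_id = i,
               x = 10 * i + f, y = 5 * i)
  }))
  div <- data.frame(parent_track = c(1, 2, 3), daughter_a = c(2, 4, 6),
                    daughter_b = c(3, 5, 7), frame_min = c(8, 18, 20),
                    frame_confirmed = c(10, 20, 22), baseline_um = 6,
                    minimum_um = 1)
  list(tg = mkGraph(trk, nodes), div = div)
}

test_that("lineage with no divisions is a forest of single cells", {
  trk <- data.frame(track_id = 1:3, parent_track_id = NA_integer_,
                    start_frame = 0L, end_frame = c(30L, 30L, 12L))
  nodes <- do.call(rbind, lapply(1:3, function(i)
    data.frame(frame = trk$start_frame[i]:trk$end_frame[i], centroid_id = i,
               track_id = i, x = 10 * i, y = 10)))
  lin <- buildLineage(mkGraph(trk, nodes), NULL, lastFrame = 30L)
  cl <- cells(lin)
  expect_equal(nrow(cl), 3L)
  expect_true(all(is.na(cl$parent_id)))
  expect_equal(sort(cl$end_reason), c("lost", "movie_end", "movie_end"))
})

test_that("two division rounds give a seven-node binary tree", {
  g <- twoRounds()
  lin <- buildLineage(g$tg, g$div, lastFrame = 30L)
  cl <- cells(lin)
  expect_equal(nrow(cl), 7L)
  expect_equal(sum(is.na(cl$parent_id)), 1L)
  expect_equal(sum(cl$end_reason == "division"), 3L)
  expect_equal(sum(cl$end_reason == "movie_end"), 4L)
  kids <- table(cl$parent_id[!is.na(cl$parent_id)])
  expect_true(all(kids == 2L))
  expect_error(buildLineage(g$tg, transform(g$div, parent_track = c(1, 2, 99))),
               "absent")
})

test_that("an unconfirmed bifurcation continues the nearest child as the same cell", {
  trk <- data.frame(track_id = 1:3, parent_track_id = c(NA, 1, 1),
                    start_frame = c(0, 10, 10), end_frame = c(9, 20, 20))
  nodes <- rbind(
    data.frame(frame = 0:9, centroid_id = 1, track_id = 1, x = 100, y = 100),
    data.frame(frame = 10:20, centroid_id = 2, track_id = 2, x = 102, y = 100),
    data.frame(frame = 10:20, centroid_id = 3, track_id = 3, x = 130, y = 100))
  lin <- buildLineage(mkGraph(trk, nodes), NULL, lastFrame = 20L)
  cl <- cells(lin)
  expect_equal(nrow(cl), 2L)               # continuation + new progenitor
  expect_true(all(is.na(cl$parent_id)))
  expect_equal(sort(cl$birth_frame), c(0L, 10L))
})

test_that("motility vectors are net displacement over elapsed time", {
  # 24 um in 12 h (144 frames at 5 min) along x: 96 px at 0.25 um/px
  trk <- data.frame(track_id = 1:2, parent_track_id = NA_integer_,
                    start_frame = 0L, end_frame = 144L)
  nodes <- rbind(
    data.frame(frame = 0:144, centroid_id = 1, track_id = 1,
               x = 50 + (0:144) * 96 / 144, y = 20),
    data.frame(frame = 0:144, centroid_id = 2, track_id = 2, x = 400, y = 400))
  tg <- mkGraph(trk, nodes)
  lin <- buildLineage(tg, NULL, lastFrame = 144L)
  mv <- motilityVectors(lin, tg)
  mv <- mv[order(mv$cell_id), ]
  moving <- mv[which.max(abs(mv$vx_um_per_h)), ]
  expect_equal(moving$speed_um_per_h, 2, tolerance = 1e-9)
  expect_equal(moving$vy_um_per_h, 0)
  still <- mv[mv$speed_um_per_h == 0, ]
  expect_equal(nrow(still), 1L)
  expect_false(still$flagged)
})

test_that("net speed is below path speed for a random-walk cell", {
  set.seed(15)
  steps <- cbind(rnorm(200, 0, 2), rnorm(200, 0, 2))
  xy <- apply(steps, 2, cumsum)
  trk <- data.frame(track_id = 1L, parent_track_id = NA_integer_,
                    start_frame = 0L, end_frame = 200L)
  nodes <- data.frame(frame = 0:200, centroid_id = 1, track_id = 1,
                      x = c(0, xy[, 1]) + 500, y = c(0, xy[, 2]) + 500)
  tg <- mkGraph(trk, nodes)
  mv <- motilityVectors(buildLineage(tg, NULL, lastFrame = 200L), tg)
  expect_lt(mv$speed_um_per_h, mv$path_speed_um_per_h)
})

test_that("doubling time follows the two-point log2 formula", {
  expect_equal(doublingTime(50, 100, 24), 24)
  expect_equal(doublingTime(41, 133, 40), 40 / log2(133 / 41))
  expect_true(is.na(doublingTime(100, 90, 24)))
  # via per-frame states
  sts <- list(stateFromBlobs(list(cbind(c(1, 2), c(1, 1)))),
              stateFromBlobs(list(cbind(c(1, 2), c(1, 1)),
                                  cbind(c(50, 51), c(1, 1)))))
  sts[[2]]@frameIndex <- 12L
  ps <- populationStats(sts, frameIntervalMin = 5)
  expect_equal(ps$doublingTimeH, 1)   # doubles over 12 frames = 1 h
  expect_equal(ps$perFrame$n_centroids, c(1L, 2L))
})

test_that("newick export round-trips through ape with branch lengths in hours", {
  skip_if_not_installed("ape")
  g <- twoRounds()
  lin <- buildLineage(g$tg, g$div, lastFrame = 30L)
  nwk <- lineageNewick(lin)
  expect_length(nwk, 1L)
  tree <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tree), 4L)
  expect_equal(tree$Nnode, 3L)
  # root cell lived 10 frames = 50 min; leaves end at frame 30
  cl <- cells(lin)
  leafIds <- as.integer(sub("c", "", tree$tip.label))
  lens <- tree$edge.length[match(seq_len(ape::Ntip(tree)), tree$edge[, 2])]
  expect_equal(lens,
               (cl$end_frame - cl$birth_frame)[match(leafIds, cl$cell_id)] *
                 5 / 60, tolerance = 1e-5)
  js <- lineageJSON(lin)
  expect_length(js, 1L)
  expect_equal(length(js[[1]]$daughters), 2L)
})

test_that("centroid count bookkeeping matches births and losses per frame", {
  g <- twoRounds()
  lin <- buildLineage(g$tg, g$div, lastFrame = 30L)
  cl <- cells(lin)
  nodes <- trackNodes(g$tg)
  for (f in c(0, 5, 15, 25, 30)) {
    alive <- sum(cl$birth_frame <= f & cl$end_frame >= f)
    expect_equal(alive, sum(nodes$frame == f))
  }
})
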