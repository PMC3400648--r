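test_that("k-means fixed points and degenerate inputs", {
  el <- matrix(rep(c(10, 20), each = 6), ncol = 2)
  st <- kmeansAssign(el, matrix(c(50, 50), ncol = 2), quiet = TRUE)
  expect_equal(centroids(st)$x, 10)
  expect_equal(centroids(st)$y, 20)
  expect_error(kmeansAssign(matrix(numeric(0), ncol = 2), cbind(1, 1)),
               "no elements")
  # seeds already at the converged centroids stay put
  set.seed(2)
  blobA <- cbind(rnorm(10, 20, 2), rnorm(10, 20, 2))
  blobB <- cbind(rnorm(10, 120, 2), rnorm(10, 20, 2))
  el <- rbind(blobA, blobB)
  seeds <- data.frame(id = 1:2, x = c(mean(blobA[, 1]), mean(blobB[, 1])),
                      y = c(mean(blobA[, 2]), mean(blobB[, 2])))
  st <- kmeansAssign(el, seeds, quiet = TRUE)
  expect_equal(centroids(st)$x, seeds$x, tolerance = 1e-12)
  expect_equal(centroids(st)$y, seeds$y, tolerance = 1e-12)
  expect_equal(centroids(st)$n_elements, c(10L, 10L))
})

test_that("two separated blobs converge to the blob means", {
  set.seed(4)
  blobA <- cbind(rnorm(10, 0, 3), rnorm(10, 0, 3))
  blobB <- cbind(rnorm(10, 100, 3), rnorm(10, 0, 3))
  st <- kmeansAssign(rbind(blobA, blobB),
                     data.frame(id = 1:2, x = c(10, 90), y = c(5, -5)),
                     quiet = TRUE)
  ce <- centroids(st)
  expect_equal(ce$x[1], mean(blobA[, 1]), tolerance = 1e-9)
  expect_equal(ce$y[1], mean(blobA[, 2]), tolerance = 1e-9)
  expect_equal(ce$x[2], mean(blobB[, 1]), tolerance = 1e-9)
  expect_equal(ce$y[2], mean(blobB[, 2]), tolerance = 1e-9)
})

test_that("k-means agrees with a brute-force Lloyd loop on random instances", {
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(5:50, 1); k <- sample(1:5, 1)
    el <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    seeds <- data.frame(id = seq_len(k), x = runif(k, 0, 200),
                        y = runif(k, 0, 200))
    st <- suppressWarnings(kmeansAssign(el, seeds, quiet = TRUE))
    ref <- bruteKmeans(el, seeds)
    expect_equal(centroids(st)$id, ref$centroids$id)
    expect_equal(centroids(st)$x, ref$centroids$x, tolerance = 1e-9)
    expect_equal(centroids(st)$y, ref$centroids$y, tolerance = 1e-9)
    expect_equal(assignment(st), as.integer(ref$assignment))
  }
})

test_that("the within-cluster objective never increases across iterations", {
  objective <- function(el, cent, assign) {
    s <- 0
    for (j in seq_len(nrow(cent))) {
      mem <- el[assign == cent$id[j], , drop = FALSE]
      s <- s + sum((mem[, 1] - cent$x[j])^2 + (mem[, 2] - cent$y[j])^2)
    }
    s
  }
  set.seed(21)
  for (rep in 1:10) {
    el <- cbind(runif(40, 0, 100), runif(40, 0, 100))
    seeds <- data.frame(id = 1:4, x = runif(4, 0, 100), y = runif(4, 0, 100))
    # objective of the initial assignment to raw seeds
    d <- as.matrix(stats::dist(rbind(cbind(seeds$x, seeds$y), el)))
    near <- apply(d[-(1:4), 1:4, drop = FALSE], 1, which.min)
    obj0 <- objective(el, seeds, seeds$id[near])
    st <- suppressWarnings(kmeansAssign(el, seeds, quiet = TRUE))
    obj1 <- objective(el, centroids(st), assignment(st))
    expect_lte(obj1, obj0 + 1e-9)
  }
})

test_that("silhouette matches the hand-computed four-point example", {
  el <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  s <- silhouetteScores(el, c(1, 1, 2, 2))
  b <- mean(c(10, sqrt(101)))
  expect_equal(s$scores, rep((b - 1) / b, 4), tolerance = 1e-12)
  expect_equal(s$meanScore, (b - 1) / b, tolerance = 1e-12)
})

test_that("silhouette limits: tight distant clusters near 1, shuffled labels <= 0", {
  set.seed(5)
  a <- cbind(rnorm(15, 0, 0.5), rnorm(15, 0, 0.5))
  b <- cbind(rnorm(15, 500, 0.5), rnorm(15, 500, 0.5))
  s <- silhouetteScores(rbind(a, b), rep(1:2, each = 15))
  expect_gt(s$meanScore, 0.99)
  # one physical cluster with interleaved labels fits badly
  s2 <- silhouetteScores(a, rep(1:2, length.out = 15))
  expect_lte(s2$meanScore, 0)
  expect_warning(silhouetteScores(a, rep(1, 15)), "single cluster")
})

test_that("silhouette agrees with cluster::silhouette and the brute force", {
  skip_if_not_installed("cluster")
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(6:40, 1); k <- sample(2:4, 1)
    el <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    lab <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- silhouetteScores(el, lab)
    expect_equal(s$scores, bruteSilhouette(el, lab), tolerance = 1e-12)
    sil <- cluster::silhouette(lab, stats::dist(el))
    if (!is.matrix(sil)) next
    ref <- sil[, "sil_width"]
    # cluster:: gives singletons 0 as well
    expect_equal(s$scores, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("seed update spawns beyond 120 px and removes beyond 50 px", {
  prev <- data.frame(id = 1L, x = 0, y = 0)
  # element at 121 px spawns a second seed at its own position
  sds <- updateSeeds(prev, rbind(c(0, 5), c(121, 0)), pixelSizeUm = 0.25)
  expect_equal(nrow(sds), 2L)
  expect_equal(sds$x[2], 121)
  # at 119 px no spawn
  sds2 <- updateSeeds(prev, rbind(c(0, 5), c(119, 0)), pixelSizeUm = 0.25)
  expect_equal(nrow(sds2), 1L)
  # a seed whose nearest element is 51 px away is removed
  sds3 <- updateSeeds(data.frame(id = 1:2, x = c(0, 300), y = c(0, 0)),
                      rbind(c(0, 0), c(300, 51)), pixelSizeUm = 0.25)
  expect_equal(sds3$id, 1L)
  # identical elements reproduce the previous centroids
  st <- stateFromBlobs(list(cbind(c(9, 11), c(10, 10))))
  sds4 <- updateSeeds(st, elements(st), pixelSizeUm = 0.25)
  expect_equal(sds4$x, centroids(st)$x)
  # spawned seeds count for subsequent elements; the original seed (no
  # element within 50 px) is then removed
  sds5 <- updateSeeds(prev, rbind(c(130, 0), c(150, 0)), pixelSizeUm = 0.25)
  expect_equal(nrow(sds5), 1L)   # one spawned seed serves both elements
  expect_equal(sds5$x, 130)
})

test_that("split test divides a completed division and leaves tight clusters alone", {
  set.seed(8)
  # two 10-element sub-blobs 30 um (120 px) apart under one centroid; the
  # mean pairwise separation (~15.5 um) just exceeds the 1.5-diameter rule
  a <- cbind(rnorm(10, 100, 3), rnorm(10, 100, 3))
  b <- cbind(rnorm(10, 220, 3), rnorm(10, 100, 3))
  st <- stateFromBlobs(list(rbind(a, b)))
  expect_gt(centroids(st)$mean_separation_um, 15)
  st2 <- splitTest(st)
  expect_equal(nrow(centroids(st2)), 2L)
  ce <- centroids(st2)[order(centroids(st2)$x), ]
  expect_lt(abs(ce$x[1] - mean(a[, 1])), 1)
  expect_lt(abs(ce$x[2] - mean(b[, 1])), 1)
  # a tight cluster (3 um spread) is never tested
  tight <- stateFromBlobs(list(cbind(rnorm(12, 50, 4), rnorm(12, 50, 4))))
  expect_lt(centroids(tight)$mean_separation_um, 15)
  expect_identical(centroids(splitTest(tight)), centroids(tight))
})

test_that("a split that worsens the silhouette is rejected", {
  set.seed(9)
  # two tight, well-separated clusters plus one diffuse single-cell cluster
  # whose mean separation exceeds the trigger: splitting the diffuse cloud
  # in half lowers its members' silhouette (sibling halves are too close)
  t1 <- cbind(rnorm(12, 0, 2), rnorm(12, 0, 2))
  t2 <- cbind(rnorm(12, 0, 2), rnorm(12, 800, 2))
  diffuse <- cbind(runif(30, 700, 860), runif(30, 300, 460))  # ~16 um spread
  st <- stateFromBlobs(list(t1, t2, diffuse))
  expect_gt(centroids(st)$mean_separation_um[3], 15)
  st2 <- splitTest(st, centroidId = 3L)
  expect_equal(nrow(centroids(st2)), 3L)
  expect_identical(centroids(st2), centroids(st))
})

test_that("assignment is a partition and centroids localize the true cloud", {
  cfg <- simConfig(fieldUm = c(96, 96), pixelSizeUm = 0.25, nFrames = 1L,
                   initialCells = 4L, nPlanes = 1L, backgroundSd = 0.001,
                   vesiclesPerCell = c(8L, 12L), minInitialSeparationUm = 30,
                   domainMarginUm = 0, rngSeed = 12L)
  mv <- simulateMovie(cfg)
  bem <- detectElements(mv$stacks[[1]], theta = 500)
  st <- kmeansAssign(elements(bem), truthSeeds(mv$truth), pixelSizeUm = 0.25,
                     quiet = TRUE)
  expect_equal(sum(centroids(st)$n_elements), nrow(elements(bem)))
  sp <- trueSpots(mv$truth, 0)
  ce <- centroids(st)
  W <- 96 / 0.25
  for (cid in unique(sp$cell_id)) {
    s <- sp[sp$cell_id == cid, ]
    # only fully visible, fully resolvable clouds: a spot clipped by the
    # border is not rendered, and spots closer than the peak window merge --
    # both shift the observable centroid away from the true cloud mean
    if (any(s$x_px < 8 | s$x_px > W - 8 | s$y_px < 8 | s$y_px > W - 8)) next
    if (nrow(s) > 1 && min(stats::dist(cbind(s$x_px, s$y_px))) <= 5) next
    mu <- colMeans(s[, c("x_px", "y_px")])
    j <- which.min((ce$x - mu[1])^2 + (ce$y - mu[2])^2)
    expect_lt(sqrt((ce$x[j] - mu[1])^2 + (ce$y[j] - mu[2])^2), 2)
  }
})

test_that("automatic seeding groups elements by the 30 um linking radius", {
  el <- rbind(cbind(runif(10, 0, 20), runif(10, 0, 20)),
              cbind(runif(10, 300, 320), runif(10, 300, 320)))
  sds <- autoSeeds(el, linkRadiusUm = 30, pixelSizeUm = 0.25)
  expect_equal(nrow(sds), 2L)
  expect_equal(nrow(autoSeeds(matrix(numeric(0), ncol = 2))), 0L)
})
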