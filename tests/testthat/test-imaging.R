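test_that("single-plane and identical-plane stacks fuse to the input", {
  set.seed(1)
  p <- matrix(runif(256, 0, 100), 16, 16)
  comp <- fuseFocalPlanes(FrameStack(planes = list(p)), regionPx = 8)
  expect_equal(intensity(comp), p)
  expect_true(all(sourcePlane(comp) == 1L))
  comp2 <- fuseFocalPlanes(FrameStack(planes = list(p, p)), regionPx = 8)
  expect_equal(intensity(comp2), p)
  expect_true(all(sourcePlane(comp2) == 1L))  # ties break to the lower plane
})

test_that("the sharpest plane wins its block; uniform blocks tie to plane 1", {
  p1 <- matrix(5, 32, 32)
  p2 <- matrix(5, 32, 32)
  p2[24, 24] <- 500
  comp <- fuseFocalPlanes(FrameStack(planes = list(p1, p2)), regionPx = 16)
  expect_true(all(sourcePlane(comp)[17:32, 17:32] == 2L))
  expect_true(all(sourcePlane(comp)[1:16, 1:16] == 1L))
  expect_equal(intensity(comp)[24, 24], 500)
})

test_that("fusion matches a brute-force gradient evaluation block by block", {
  set.seed(7)
  for (rep in 1:4) {
    nr <- sample(20:64, 1); nc <- sample(20:64, 1)
    block <- sample(c(5L, 8L, 16L), 1)
    planes <- lapply(1:3, function(i) matrix(rnorm(nr * nc), nr, nc))
    comp <- fuseFocalPlanes(FrameStack(planes = planes), block)
    for (br in seq_len(ceiling(nr / block))) {
      rows <- ((br - 1) * block + 1):min(br * block, nr)
      for (bc in seq_len(ceiling(nc / block))) {
        cols <- ((bc - 1) * block + 1):min(bc * block, nc)
        sums <- vapply(planes, bruteBlockGradient, numeric(1),
                       rows = rows, cols = cols)
        best <- which.max(sums)   # which.max ties to the lowest index
        expect_true(all(sourcePlane(comp)[rows, cols] == best))
        expect_equal(intensity(comp)[rows, cols], planes[[best]][rows, cols])
      }
    }
  }
})

test_that("fusion edge cases error or warn as specified", {
  expect_error(FrameStack(planes = list()), "at least one plane")
  p <- matrix(1, 8, 8)
  expect_warning(fuseFocalPlanes(FrameStack(planes = list(p, p)), 64),
                 "single whole-image region")
})

test_that("mu + sigma threshold uses the population standard deviation", {
  expect_equal(computeThreshold(matrix(7, 5, 5)), 7)
  expect_equal(computeThreshold(matrix(c(0, 0, 0, 4), 2, 2)), 1 + sqrt(3))
  set.seed(11)
  img <- matrix(rnorm(1e6, 400, 100), 1000, 1000)
  expect_equal(computeThreshold(img), 500, tolerance = 1e-3)
})

test_that("threshold step function is a strict cut with clamping at zero", {
  m <- matrix(1:16, 4, 4)
  expect_true(all(applyThreshold(m, 16) == 0L))
  expect_true(all(applyThreshold(m, -1) == 1L))  # clamped to 0, all positive
  counts <- vapply(0:16, function(th) sum(applyThreshold(m, th)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("peak finder locates isolated spots and respects the mask", {
  m <- matrix(0, 40, 40)
  spot <- function(m, cx, cy, a) {
    for (y in 1:40) for (x in 1:40)
      m[y, x] <- m[y, x] + a * exp(-((x - cx)^2 + (y - cy)^2) / 8)
    m
  }
  m <- spot(m, 12, 15, 100)
  bem <- detectPeaks(m, applyThreshold(m, 10), 5)
  expect_equal(nrow(elements(bem)), 1L)
  expect_equal(unname(elements(bem)[1, ]), c(12 - 1, 15 - 1))
  m2 <- spot(m, 30, 32, 80)
  bem2 <- detectPeaks(m2, applyThreshold(m2, 10), 5)
  expect_equal(nrow(elements(bem2)), 2L)
  d <- sqrt((elements(bem2)[, 1] - c(11, 29))^2 +
              (elements(bem2)[, 2] - c(14, 31))^2)
  expect_true(all(d <= sqrt(2)))
  expect_equal(nrow(elements(detectPeaks(m2, matrix(0L, 40, 40), 5))), 0L)
})

test_that("peak finder agrees with exhaustive local-max search; one element per plateau", {
  set.seed(3)
  for (rep in 1:4) {
    m <- matrix(sample(0:50, 30 * 30, replace = TRUE), 30, 30)
    mask <- applyThreshold(m, 40)
    bem <- detectPeaks(m, mask, 5)
    ref <- bruteLocalMax(m, mask, 2L)
    # every detected element is a brute-force local max
    if (nrow(elements(bem)) > 0) {
      key <- paste(elements(bem)[, 1], elements(bem)[, 2])
      expect_true(all(key %in% paste(ref[, 1], ref[, 2])))
    }
    # brute maxima with a unique intensity cannot be plateau-suppressed and
    # must be detected exactly (tied maxima may collapse along plateaus)
    if (!is.null(ref)) {
      uniq <- ref[!(ref[, 3] %in% ref[duplicated(ref[, 3]), 3]), ,
                  drop = FALSE]
      if (nrow(uniq) > 0) {
        key <- paste(elements(bem)[, 1], elements(bem)[, 2])
        expect_true(all(paste(uniq[, 1], uniq[, 2]) %in% key))
      }
    }
  }
  # an exact plateau collapses to its first pixel in raster order
  m <- matrix(0, 11, 11)
  m[5:6, 5:6] <- 9
  bem <- detectPeaks(m, applyThreshold(m, 1), 5)
  expect_equal(nrow(elements(bem)), 1L)
  expect_equal(unname(elements(bem)[1, ]), c(4, 4))
})

test_that("element count is non-increasing in the threshold on a synthetic frame", {
  cfg <- simConfig(fieldUm = c(64, 64), pixelSizeUm = 0.5, nFrames = 1L,
                   initialCells = 3L, nPlanes = 2L, vesiclesPerCell = c(10L, 20L),
                   minInitialSeparationUm = 18, domainMarginUm = 0,
                   rngSeed = 5L)
  mv <- simulateMovie(cfg)
  comp <- fuseFocalPlanes(mv$stacks[[1]], 32)
  ths <- seq(380, 1200, by = 60)
  counts <- vapply(ths, function(th)
    nrow(elements(detectPeaks(comp, applyThreshold(comp, th), 5))), integer(1))
  expect_true(all(diff(counts) <= 0L))
})
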