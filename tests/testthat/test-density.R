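test_that("BIF classification labels isotropic spots as blobs", {
  n <- 41L; ctr <- 21
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
  bright <- 0.2 + 0.6 * exp(-d2 / (2 * 4^2))
  dark <- 0.8 - 0.6 * exp(-d2 / (2 * 4^2))
  bm <- classMap(bifClassify(bright, sigmaBif = 4, epsFlat = 0))
  dm <- classMap(bifClassify(dark, sigmaBif = 4, epsFlat = 0))
  expect_equal(bifClassNames()[bm[ctr, ctr]], "bright_blob")
  expect_equal(bifClassNames()[dm[ctr, ctr]], "dark_blob")
})

test_that("a zero flatness threshold never produces flat pixels", {
  set.seed(51)
  I <- matrix(runif(32 * 32), 32, 32)
  expect_false(any(classMap(bifClassify(I, 4, 0)) == 1L))
  ph <- generatePhantom(phantomSpec(shape = c(128, 128), nCells = 1,
                                    radiusRange = c(18, 24),
                                    haloWidthRange = c(8, 12), seed = 52))
  expect_false(any(classMap(bifClassify(phantomImage(ph), 4, 0)) == 1L))
  # even a perfectly constant image is not flat at eps = 0
  expect_false(any(classMap(bifClassify(matrix(0.5, 16, 16), 4, 0)) == 1L))
})

test_that("BIF class frequencies ignore a constant intensity offset", {
  # derivative filters kill the DC term; tiny floating-point residuals can
  # flip near-tie pixels, so compare class frequencies, not the exact map
  set.seed(53)
  I <- matrix(runif(900, 0.1, 0.6), 30, 30)
  a <- classMap(bifClassify(I, 3, 0))
  b <- classMap(bifClassify(I + 0.3, 3, 0))
  expect_gt(mean(a == b), 0.99)
  expect_lt(max(abs(tabulate(a, 7) - tabulate(b, 7))), 0.01 * length(a))
})

test_that("blob centroids are component means gated by the cell mask", {
  cls <- matrix(7L, 12, 12)
  cls[5:7, 5:7] <- 3L                       # one 3x3 bright-blob block
  bif <- new("BIFMap", classes = cls, sigma = 4, epsFlat = 0)
  inMask <- matrix(TRUE, 12, 12)
  expect_equal(blobCentroids(bif, inMask),
               cbind(row = 6L, col = 6L), ignore_attr = TRUE)
  # centroid pixel outside the mask is discarded
  outMask <- matrix(TRUE, 12, 12); outMask[6, 6] <- FALSE
  expect_equal(nrow(blobCentroids(bif, outMask)), 0L)
  # no bright blobs at all
  none <- new("BIFMap", classes = matrix(7L, 5, 5), sigma = 4, epsFlat = 0)
  expect_equal(nrow(blobCentroids(none, matrix(TRUE, 5, 5))), 0L)
})

test_that("mean centroid distance matches the brute-force oracle", {
  expect_equal(meanCentroidDistance(cbind(1, 1:3), c(1, 3)), 0)
  expect_equal(meanCentroidDistance(cbind(1, 1), c(1, 3)), 1)  # {0,1,2}/3
  set.seed(54)
  for (i in 1:5) {
    k <- sample(1:6, 1)
    cents <- cbind(sample(32, k, TRUE), sample(32, k, TRUE))
    cents <- unique(cents)
    expect_equal(meanCentroidDistance(cents, c(32, 32)),
                 bruteMeanCentroidDistance(cents, c(32, 32)),
                 tolerance = 1e-12)
  }
  expect_error(meanCentroidDistance(matrix(0, 0, 2), c(8, 8)), "centroid")
})

test_that("PCC is the confluency over the blob spacing", {
  expect_equal(pcc(0, 10), 0)
  expect_equal(pcc(0.5, 10), 0.05)
  expect_equal(pcc(0.5, 20), 0.025)
  expect_error(pcc(0.5, 0), "> 0")
  expect_error(pcc(1.5, 10), "\\[0, 1\\]")
})

test_that("density calibration recovers a noiseless line exactly", {
  pv <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  dens <- 2 * pv + 5
  m <- calibrateDensity(pv, dens)
  co <- calibrationCoef(m)
  expect_equal(unname(co["slope"]), 2, tolerance = 1e-9)
  expect_equal(unname(co["intercept"]), 5, tolerance = 1e-9)
  expect_equal(m@adjR2, 1, tolerance = 1e-9)
  expect_equal(m@nrmse, 0, tolerance = 1e-9)
  expect_equal(predictDensity(m, 0.1), 5.2, tolerance = 1e-9)
  expect_error(calibrateDensity(rep(0.2, 4), 1:4), "constant")
  expect_error(calibrateDensity(pv[1:2], dens[1:2]), "at least 3")
  expect_error(densityNRMSE(c(1, 2), c(3, 3)), "zero range")
})

test_that("planted nucleus-like blobs are recovered inside the mask", {
  recovered <- vapply(0:2, function(s) {
    ph <- standardSuiteBundle(s)
    mask <- segmentPCM(phantomImage(ph), suiteParams())
    cents <- blobCentroids(bifClassify(phantomImage(ph)), mask)
    pl <- cellCenters(ph)
    if (nrow(cents) == 0L) return(0)
    mean(apply(pl, 1, function(q)
      min(sqrt((cents[, 1] - q[1])^2 + (cents[, 2] - q[2])^2)) <= 8))
  }, numeric(1))
  expect_gte(mean(recovered), 0.8)
})
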