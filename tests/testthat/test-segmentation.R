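test_that("local contrast matches the brute-force windowed std/mean", {
  set.seed(21)
  for (i in 1:5) {
    I <- matrix(runif(81, 0.1, 1), 9, 9)
    expect_equal(localContrast(I, 1), bruteLocalContrast(I, 1),
                 tolerance = 1e-12)
  }
  # single bright pixel, the spec's canonical small case
  I <- matrix(0.2, 9, 9); I[5, 5] <- 0.9
  expect_equal(localContrast(I, 1), bruteLocalContrast(I, 1),
               tolerance = 1e-12)
})

test_that("local contrast is zero on constant images and scale-invariant", {
  expect_true(all(localContrast(matrix(0.5, 12, 12), 1.2) == 0))
  set.seed(22)
  I <- matrix(runif(100, 0.2, 1), 10, 10)
  expect_equal(localContrast(I, 1.5), localContrast(0.5 * I, 1.5),
               tolerance = 1e-10)
  expect_error(localContrast(I, 0), "positive")
})

test_that("contrast thresholding is an elementwise strict comparison", {
  C <- matrix(c(0.01, 0.20, 0.08, 0.03), 2, 2)
  expect_equal(thresholdContrast(C, 0.05),
               matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(thresholdContrast(C, 0), C > 0)
  expect_false(any(thresholdContrast(C, 1)))
  # monotone: larger epsilon gives a subset
  set.seed(23)
  Cm <- matrix(runif(400), 20, 20)
  m1 <- thresholdContrast(Cm, 0.3)
  m2 <- thresholdContrast(Cm, 0.6)
  expect_true(all(m2 <= m1))
})

test_that("hole filling fills only small interior background components", {
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE
  ring[4, 4] <- FALSE
  filled <- fillHoles(ring, 5)
  expect_true(filled[4, 4])
  expect_equal(sum(filled) - sum(ring), 1)
  # area equal to the bound is not filled (strict inequality)
  m <- matrix(FALSE, 8, 8)
  m[2:7, 2:7] <- TRUE
  m[4:5, 4:5] <- FALSE           # hole of area 4
  expect_equal(fillHoles(m, 4), m)
  expect_false(identical(fillHoles(m, 5), m))
  # border-touching background is never filled
  edge <- matrix(TRUE, 5, 5); edge[1, 3] <- FALSE
  expect_equal(fillHoles(edge, 100), edge)
  # fMax = 0 is the identity; filling is idempotent
  expect_equal(fillHoles(ring, 0), ring)
  expect_equal(fillHoles(filled, 5), filled)
})

test_that("small-object removal respects area bound and 8-connectivity", {
  m <- matrix(FALSE, 9, 9)
  m[2, 2] <- TRUE               # isolated pixel
  m[5:7, 5:7] <- TRUE           # 9-px block
  out <- removeSmallObjects(m, 5)
  expect_false(out[2, 2])
  expect_equal(sum(out), 9)
  # object of exactly the bound area is kept
  expect_equal(sum(removeSmallObjects(m, 9)), 9)
  # two diagonally adjacent pixels form one object of area 2
  dg <- matrix(FALSE, 5, 5); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_equal(removeSmallObjects(dg, 2), dg)
  expect_false(any(removeSmallObjects(dg, 3)))
  # rMax = 0 identity; idempotence
  expect_equal(removeSmallObjects(m, 0), m)
  expect_equal(removeSmallObjects(out, 5), out)
})

test_that("an all-background phantom segments to an empty mask", {
  ph <- generatePhantom(phantomSpec(shape = c(128, 128), nCells = 0,
                                    seed = 3))
  mask <- segmentPCM(phantomImage(ph), segParams())
  expect_false(any(mask))
  expect_equal(imageConfluency(mask), 0)
})

test_that("halo correction only removes pixels from the thresholded mask", {
  ph <- generatePhantom(phantomSpec(shape = c(256, 256), nCells = 2,
                                    radiusRange = c(20, 28),
                                    haloWidthRange = c(10, 16), seed = 5))
  off <- segmentPCM(phantomImage(ph), suiteParams(haloCorrection = FALSE))
  on <- segmentPCM(phantomImage(ph), suiteParams())
  expect_true(all(on <= off))
  expect_lt(sum(on), sum(off))
})

test_that("segmentation is translation-equivariant away from borders", {
  big <- generatePhantom(phantomSpec(shape = c(300, 300), nCells = 1,
                                     radiusRange = c(25, 32),
                                     haloWidthRange = c(10, 14), seed = 7))
  I <- phantomImage(big)
  dy <- 6L; dx <- 9L
  w <- 220L
  I1 <- I[21:(20 + w), 21:(20 + w)]
  I2 <- I[(21 + dy):(20 + w + dy), (21 + dx):(20 + w + dx)]
  p <- suiteParams()
  m1 <- segmentPCM(I1, p)
  m2 <- segmentPCM(I2, p)
  mg <- ceiling(4 * 1.2) + 1L
  inner1 <- m1[(1 + dy + mg):(w - mg), (1 + dx + mg):(w - mg)]
  inner2 <- m2[(1 + mg):(w - dy - mg), (1 + mg):(w - dx - mg)]
  expect_gt(mean(inner1 == inner2), 0.999)
})
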