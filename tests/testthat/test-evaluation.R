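test_that("confusion counts tally pixels with cell as positive", {
  truth <- matrix(FALSE, 10, 10); truth[1:2, 1:5] <- TRUE   # 10 cell px
  cc <- countValues(confusionCounts(truth, truth))
  expect_equal(cc, c(tp = 10, fp = 0, tn = 90, fn = 0))
  cc2 <- countValues(confusionCounts(!truth, truth))
  expect_equal(cc2[["tp"]], 0); expect_equal(cc2[["tn"]], 0)
  truth30 <- matrix(FALSE, 10, 10); truth30[1:3, ] <- TRUE
  cc3 <- countValues(confusionCounts(matrix(TRUE, 10, 10), truth30))
  expect_equal(cc3, c(tp = 30, fp = 70, tn = 0, fn = 0))
  expect_error(confusionCounts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "same shape")
})

test_that("metrics match hand-evaluated closed forms", {
  m <- rocMetrics(new("ConfusionCounts", tp = 40, fp = 10, tn = 45, fn = 5))
  v <- metricValues(m)
  expect_equal(v[["accuracy"]], 0.85)
  expect_equal(v[["precision"]], 0.8)
  expect_equal(v[["recall"]], 8 / 9)
  expect_equal(v[["f_score"]], 80 / 95)
  expect_equal(v[["mcc"]], (40 * 45 - 10 * 5) /
                 sqrt(50 * 45 * 55 * 50))
  expect_equal(v[["seg_error"]], 1 - v[["mcc"]])
})

test_that("metrics agree with brute-force recomputation on random masks", {
  set.seed(71)
  for (i in 1:100) {
    pred <- matrix(runif(256) < runif(1), 16, 16)
    truth <- matrix(runif(256) < runif(1), 16, 16)
    got <- metricValues(rocMetrics(confusionCounts(pred, truth)))
    want <- bruteMetrics(pred, truth)
    expect_identical(unname(got[names(want)]), unname(want))
  }
})

test_that("MCC hits its endpoints and is label-swap symmetric", {
  truth <- matrix(c(TRUE, FALSE), 8, 8)
  expect_equal(metricValues(rocMetrics(confusionCounts(truth,
                                                       truth)))[["mcc"]], 1)
  expect_equal(metricValues(rocMetrics(confusionCounts(!truth,
                                                       truth)))[["mcc"]], -1)
  # swapping tp<->tn and fp<->fn leaves mcc unchanged
  a <- rocMetrics(new("ConfusionCounts", tp = 12, fp = 7, tn = 30, fn = 3))
  b <- rocMetrics(new("ConfusionCounts", tp = 30, fp = 3, tn = 12, fn = 7))
  expect_equal(a@mcc, b@mcc)
  # degenerate marginals give the random-equivalent value 0
  z <- rocMetrics(new("ConfusionCounts", tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(z@mcc, 0)
  expect_equal(z@precision, 0)
  expect_equal(z@recall, 0)
})

test_that("estimation precision decomposes rmse into bias and spread", {
  x <- c(0.2, 0.4, 0.6)
  p0 <- estimationPrecision(x, x)
  expect_equal(c(p0@rmse, p0@bias, p0@precision), c(0, 0, 0))
  pd <- estimationPrecision(x + 0.05, x)
  expect_equal(pd@rmse, 0.05)
  expect_equal(pd@bias, 0.05)
  expect_equal(pd@precision, 0)
  pm <- estimationPrecision(c(0.5 + 0.02, 0.5 - 0.02), c(0.5, 0.5))
  expect_equal(pm@bias, 0)
  expect_equal(pm@rmse, 0.02)
  expect_equal(pm@precision, 0.02)
  # identity on random inputs
  set.seed(72)
  for (i in 1:25) {
    est <- runif(10); tr <- runif(10)
    s <- estimationPrecision(est, tr)
    expect_equal(s@rmse^2, s@bias^2 + s@precision^2, tolerance = 1e-12)
  }
  expect_error(estimationPrecision(1:3, 1:2), "equal length")
})

test_that("survey statistics separate intra and inter variability", {
  # identical repeats: all variability is inter
  em <- matrix(c(10, 30, 20, 40), 2, 2)
  s <- surveyStats(em, cbind(c(15, 25), c(15, 25)))
  expect_equal(s@vIntra, 0)
  expect_equal(s@vInter, s@vBoth)
  # all raters agreeing exactly: no variability at all
  s2 <- surveyStats(matrix(c(10, 30, 10, 30), 2, 2), cbind(1, 1))
  expect_equal(s2@vBoth, 0)
  # clamping when repeats are noisier than the pool
  s3 <- surveyStats(matrix(c(10, 30, 10.1, 30.1), 2, 2),
                    cbind(c(0, 0), c(20, 20)))
  expect_equal(s3@vInter, 0)
  expect_error(surveyStats(matrix(1:4, 4, 1), cbind(1, 2)), "2 raters")
})

test_that("precision components combine in quadrature", {
  expect_equal(combinePrecision(c(3, 4)), 5)
  expect_equal(combinePrecision(c(0, 7)), 7)
  expect_equal(combinePrecision(2.5), 2.5)
  expect_error(combinePrecision(c(1, -2)), ">= 0")
})

test_that("grid search selects dominant parameters and scores LOOCV", {
  phs <- lapply(80:82, function(s)
    generatePhantom(phantomSpec(shape = c(160, 160), nCells = 1,
                                radiusRange = c(22, 30),
                                haloWidthRange = c(10, 14), seed = s)))
  images <- lapply(phs, phantomImage)
  truths <- lapply(phs, truthMask)
  # single-point grid returns that point
  g1 <- gridSearchParams(images, truths, list(epsilon = 0.03))
  expect_equal(g1$best@epsilon, 0.03)
  expect_equal(g1$loocvError, mean(g1$errors))
  # an absurd threshold (empty masks) is dominated by a sensible one
  g2 <- gridSearchParams(images, truths,
                         list(epsilon = c(0.03, 0.9), aRatio = 0.85))
  expect_equal(g2$best@epsilon, 0.03)
  expect_true(all(g2$errors[1, ] < g2$errors[2, ]))
  expect_lt(g2$loocvError, 1)
  expect_error(gridSearchParams(images, truths, list()), "non-empty")
  expect_error(gridSearchParams(images[1], truths[1],
                                list(epsilon = 0.03)), ">= 2")
})
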