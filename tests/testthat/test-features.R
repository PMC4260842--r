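test_that("image confluency counts cell pixels", {
  expect_equal(imageConfluency(matrix(FALSE, 10, 10)), 0)
  expect_equal(imageConfluency(matrix(TRUE, 10, 10)), 1)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(imageConfluency(m), 0.25)
  # subadditivity of the union
  set.seed(41)
  m1 <- matrix(runif(100) < 0.3, 10, 10)
  m2 <- matrix(runif(100) < 0.3, 10, 10)
  expect_lte(imageConfluency(m1 | m2),
             imageConfluency(m1) + imageConfluency(m2))
})

test_that("culture confluency averages images and flags undersampling", {
  masks20 <- replicate(20, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2),
                       simplify = FALSE)
  r <- cultureConfluency(masks20)
  expect_equal(cultureMean(r), 0.5)
  expect_equal(cultureSEM(r), 0)
  expect_false(r@undersampled)
  two <- list(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
              matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  expect_warning(r2 <- cultureConfluency(two), "20")
  expect_equal(cultureMean(r2), 0.5)
  expect_true(r2@undersampled)
  expect_error(cultureConfluency(list()), "non-empty")
})

test_that("object extraction excludes border objects and is 8-connected", {
  m <- matrix(FALSE, 10, 10)
  m[4:6, 4:6] <- TRUE          # interior square
  m[3:5, 1] <- TRUE            # touches left border
  obj <- extractObjects(m)
  expect_equal(nrow(obj), 1L)
  expect_equal(obj$area, 9)
  expect_equal(attr(obj, "nBorderExcluded"), 1L)
  expect_equal(nrow(extractObjects(m, includeBorder = TRUE)), 2L)
  expect_equal(nrow(extractObjects(matrix(FALSE, 5, 5))), 0L)
  dg <- matrix(FALSE, 6, 6); dg[3, 3] <- TRUE; dg[4, 4] <- TRUE
  expect_equal(nrow(extractObjects(dg)), 1L)
})

test_that("form factor matches closed forms and the digital-disk band", {
  r <- 10
  expect_equal(formFactor(pi * r^2, 2 * pi * r), 1.0)
  a <- 7
  expect_equal(formFactor(a^2, 4 * a), pi / 4)
  expect_error(formFactor(10, 0), "> 0")
  expect_error(formFactor(0.5, 4), ">= 1")
  # rasterized disk with the chain-code perimeter estimator
  obj <- extractObjects(diskMask(30))
  expect_equal(nrow(obj), 1L)
  expect_gte(obj$formFactor, 0.90)
  expect_lte(obj$formFactor, 1.05)
})

test_that("chain perimeter of an axis-aligned square is 4(a-1)", {
  for (a in c(3L, 5L, 9L)) {
    m <- matrix(FALSE, a + 4L, a + 4L)
    m[3:(a + 2L), 3:(a + 2L)] <- TRUE
    obj <- extractObjects(m)
    expect_equal(obj$perimeter, 4 * (a - 1))
    expect_equal(obj$solidity, 1.0)
  }
})

test_that("solidity agrees with a brute-force pixel-square hull", {
  expect_equal(solidity(12, 12), 1.0)
  expect_equal(solidity(1, 1), 1.0)
  expect_error(solidity(10, 8), "at least")
  # plus-sign pentomino: hull of the five unit squares is the 3x3 square
  # with its four corner triangles cut off, area 9 - 4*(1/2) = 7
  m <- matrix(FALSE, 7, 7)
  m[4, 3:5] <- TRUE
  m[3:5, 4] <- TRUE
  obj <- extractObjects(m)
  expect_equal(obj$area, 5)
  expect_equal(obj$convexArea, 7)
  expect_equal(obj$solidity, 5 / 7)
  # convex rasterized shapes stay near 1; a thin L drops well below
  expect_gte(extractObjects(diskMask(20))$solidity, 0.95)
  L <- matrix(FALSE, 14, 14)
  L[3:12, 3] <- TRUE
  L[12, 3:12] <- TRUE
  expect_lt(extractObjects(L)$solidity, 0.7)
})

test_that("morphometrics are invariant to translation and rotation", {
  set.seed(42)
  base <- diskMask(9) | rbind(matrix(FALSE, 10, 31),
                              cbind(matrix(FALSE, 21, 6),
                                    matrix(runif(21 * 25) < 0.7, 21, 25)))
  base <- phantastr:::labelComponents(base, 8L) == 1L   # keep one object
  emb <- function(m, dr, dc, n = 60L) {
    out <- matrix(FALSE, n, n)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  o1 <- extractObjects(emb(base, 5L, 8L))
  o2 <- extractObjects(emb(base, 17L, 3L))
  rot <- t(base)[ncol(base):1, ]
  o3 <- extractObjects(emb(rot, 9L, 9L))
  for (col in c("area", "perimeter", "convexArea", "solidity", "formFactor")) {
    expect_equal(o1[[col]], o2[[col]], tolerance = 1e-12)
    expect_equal(o1[[col]], o3[[col]], tolerance = 1e-12)
  }
})
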