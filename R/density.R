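#' Basic image feature (BIF) classification
#'
#' Classifies every pixel into one of seven local structure classes from
#' scale-normalized Gaussian-derivative responses
#' `s_ij = sigma^(i+j) (d^i/dx^i d^j/dy^j G_sigma * I)` up to second order.
#' With `lambda = s20 + s02` and
#' `gamma = sqrt((s20 - s02)^2 + 4 s11^2)`, the class scores are:
#' flat `epsFlat * s00`, slope `2 sqrt(s10^2 + s01^2)`, dark blob
#' `+lambda`, bright blob `-lambda`, dark line `(gamma + lambda)/sqrt(2)`,
#' bright line `(gamma - lambda)/sqrt(2)`, saddle `gamma`; the class with
#' the maximal score wins.  With `epsFlat = 0` the flat score is zero, so
#' no pixel is labelled flat (the flat class wins only with a strictly
#' larger score than every alternative).
#'
#' Kernels are truncated at 4 sigma; borders use replicate padding.
#'
#' @param I numeric matrix of intensities in `[0, 1]`.
#' @param sigmaBif filter scale in pixels (default 4).
#' @param epsFlat flatness threshold (default 0).
#' @return A [BIFMap-class]; class codes are documented in
#'   [bifClassNames()].
#' @export
bifClassify <- function(I, sigmaBif = 4, epsFlat = 0) {
  checkGray(I)
  if (!is.numeric(sigmaBif) || sigmaBif <= 0)
    stop("'sigmaBif' must be positive")
  if (!is.numeric(epsFlat) || epsFlat < 0) stop("'epsFlat' must be >= 0")
  k <- gaussDerivKernels(sigmaBif)
  s00 <- corrSep(I, k$g0, k$g0)
  s10 <- sigmaBif * corrSep(I, k$g0, k$g1)        # d/dx: across columns
  s01 <- sigmaBif * corrSep(I, k$g1, k$g0)        # d/dy: down rows
  s11 <- sigmaBif^2 * corrSep(I, k$g1, k$g1)
  s20 <- sigmaBif^2 * corrSep(I, k$g0, k$g2)
  s02 <- sigmaBif^2 * corrSep(I, k$g2, k$g0)
  lam <- s20 + s02
  gam <- sqrt((s20 - s02)^2 + 4 * s11^2)
  n <- length(I)
  # score columns in class-code order 2..7 (flat handled separately)
  sc <- cbind(slope = 2 * sqrt(s10^2 + s01^2)[seq_len(n)],
              bright_blob = -lam[seq_len(n)],
              dark_blob = lam[seq_len(n)],
              bright_line = ((gam - lam) / sqrt(2))[seq_len(n)],
              dark_line = ((gam + lam) / sqrt(2))[seq_len(n)],
              saddle = gam[seq_len(n)])
  best <- max.col(sc, ties.method = "first")
  bestScore <- sc[cbind(seq_len(n), best)]
  cls <- best + 1L                      # codes 2..7
  cls[epsFlat * s00[seq_len(n)] > bestScore] <- 1L  # flat only if dominant
  new("BIFMap", classes = matrix(as.integer(cls), nrow(I), ncol(I)),
      sigma = sigmaBif, epsFlat = epsFlat)
}

#' Centroids of bright-blob regions inside the cell mask
#'
#' Connected components (8-connectivity) of bright-blob pixels are reduced
#' to their centroids (mean pixel coordinates rounded to the nearest
#' pixel); centroids whose pixel falls outside the cell mask are discarded,
#' since blob-like texture outside cell regions cannot correspond to
#' nuclei.
#'
#' @param bif a [BIFMap-class].
#' @param cellMask logical matrix of the same shape (from [segmentPCM()]).
#' @return integer matrix with columns `row`, `col`; zero rows if there are
#'   no retained blobs.
#' @export
blobCentroids <- function(bif, cellMask) {
  stopifnot(is(bif, "BIFMap"))
  checkMask(cellMask, "cellMask")
  sameShape(bif@classes, cellMask, "BIF map", "mask")
  bright <- bif@classes == 3L
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (!any(bright)) return(out)
  lab <- labelComponents(bright, connectivity = 8L)
  idx <- which(lab > 0L)
  R <- nrow(lab)
  rows <- ((idx - 1L) %% R) + 1L
  cols <- ((idx - 1L) %/% R) + 1L
  l <- lab[idx]
  cr <- as.integer(round(tapply(rows, l, mean)))
  cc <- as.integer(round(tapply(cols, l, mean)))
  keep <- cellMask[cbind(cr, cc)]
  cbind(row = cr[keep], col = cc[keep])
}

#' Mean distance to the nearest centroid
#'
#' Builds a binary image that is true at the centroid pixels, applies the
#' exact Euclidean distance transform, and returns the mean distance over
#' all pixels of the image.  This is the packing term of the PCC: it
#' shrinks as nucleus-like features crowd together.
#'
#' @param centroids two-column (row, col) matrix with at least one row.
#' @param shape integer vector (rows, cols) of the image.
#' @return mean distance in pixels.
#' @export
meanCentroidDistance <- function(centroids, shape) {
  if (!is.matrix(centroids) || ncol(centroids) != 2L ||
      nrow(centroids) == 0L)
    stop("PCC is not computable without at least one centroid")
  if (length(shape) != 2L || any(shape < 1))
    stop("'shape' must be positive (rows, cols)")
  if (any(centroids[, 1] < 1 | centroids[, 1] > shape[1] |
          centroids[, 2] < 1 | centroids[, 2] > shape[2]))
    stop("centroids must lie inside the image")
  cm <- matrix(1, shape[1], shape[2])
  cm[centroids] <- 0
  if (!any(cm == 1)) return(0)
  mean(EBImage::distmap(cm, metric = "euclidean"))
}

#' Packing-corrected confluency (PCC)
#'
#' Image confluency divided by the mean distance to the nearest bright-blob
#' centroid.  Confluency alone is a poor predictor of cell density for
#' colony-forming cells whose area per cell varies during a culture;
#' dividing by the blob spacing corrects for packing and yields a quantity
#' that scales with cell density (units 1/pixel; a linear calibration
#' absorbs the units).
#'
#' @param confluency fraction of cell pixels in `[0, 1]`.
#' @param meanDistance mean nearest-centroid distance in pixels (> 0).
#' @return PCC value (1/pixels).
#' @export
pcc <- function(confluency, meanDistance) {
  if (any(confluency < 0 | confluency > 1))
    stop("'confluency' must lie in [0, 1]")
  if (any(meanDistance <= 0)) stop("'meanDistance' must be > 0")
  confluency / meanDistance
}

#' Compute the PCC of one image
#'
#' Convenience wrapper: segments (or takes a precomputed mask), classifies
#' BIFs, extracts bright-blob centroids inside the mask, and forms the PCC.
#'
#' @param I numeric matrix of intensities in `[0, 1]`.
#' @param mask optional precomputed segmentation mask; when `NULL` the
#'   image is segmented with `params`.
#' @param params a [SegmentationParams-class] used when `mask` is `NULL`.
#' @param sigmaBif,epsFlat BIF parameters (defaults 4 and 0).
#' @return A [PCCResult-class].
#' @export
imagePCC <- function(I, mask = NULL, params = segParams(), sigmaBif = 4,
                     epsFlat = 0) {
  checkGray(I)
  if (is.null(mask)) mask <- segmentPCM(I, params)
  sameShape(I, mask, "image", "mask")
  conf <- imageConfluency(mask)
  cents <- blobCentroids(bifClassify(I, sigmaBif, epsFlat), mask)
  if (nrow(cents) == 0L)
    stop("no bright-blob centroids inside the cell mask; PCC undefined")
  md <- meanCentroidDistance(cents, dim(I))
  new("PCCResult", confluency = conf, meanBlobDistance = md,
      pcc = pcc(conf, md), nBlobs = nrow(cents))
}

#' Calibrate cell density against PCC
#'
#' Ordinary least squares fit `density = slope * PCC + intercept`, with the
#' adjusted r-squared `1 - (1 - r^2)(n - 1)/(n - 2)` and the normalized
#' RMSE (RMSE divided by the observed density range) of the fit.
#'
#' @param pccValues numeric vector of PCC values (length >= 3, not
#'   constant).
#' @param densities numeric vector of matching cell densities (e.g.
#'   cells/cm^2).
#' @return A [CalibrationModel-class].
#' @export
calibrateDensity <- function(pccValues, densities) {
  if (length(pccValues) != length(densities))
    stop("'pccValues' and 'densities' must have equal length")
  if (length(pccValues) < 3L) stop("at least 3 calibration points required")
  if (stats::sd(pccValues) == 0)
    stop("degenerate fit: PCC values are constant")
  fit <- stats::lm(densities ~ pccValues)
  n <- length(densities)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((densities - mean(densities))^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  new("CalibrationModel",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      adjR2 = adj,
      nrmse = densityNRMSE(stats::fitted(fit), densities))
}

#' Predict cell density from PCC
#'
#' @param model a [CalibrationModel-class].
#' @param pccValues numeric vector of PCC values.
#' @return predicted densities.
#' @export
predictDensity <- function(model, pccValues) {
  stopifnot(is(model, "CalibrationModel"))
  model@slope * pccValues + model@intercept
}

#' Normalized root mean square error of density predictions
#'
#' RMSE divided by the range of the observed densities on the evaluation
#' data.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return NRMSE as a fraction (multiply by 100 for percent).
#' @export
densityNRMSE <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must have equal length")
  rng <- diff(range(observed))
  if (rng == 0)
    stop("NRMSE undefined: observed densities have zero range")
  sqrt(mean((predicted - observed)^2)) / rng
}
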