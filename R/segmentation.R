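#' Segmentation parameter constructor
#'
#' Defaults suit 10x PCM images of adherent cells: `sigma` of the order of
#' the cell-edge width, `epsilon` above the local contrast of a clean
#' background, and area bounds well below a single cell's footprint.  All
#' values are in pixel units.
#'
#' @param sigma Gaussian window scale of the local-contrast filter (pixels).
#' @param epsilon global local-contrast threshold.
#' @param fMax holes with area strictly below this are filled (pixels).
#' @param rMax objects with area strictly below this are removed (pixels).
#' @param haloCorrection run the gradient-tracking halo correction.
#' @param aRatio per-object cap on the area fraction removable by halo
#'   correction.
#' @return A [SegmentationParams-class].
#' @export
segParams <- function(sigma = 1.2, epsilon = 0.03, fMax = 200, rMax = 200,
                      haloCorrection = TRUE, aRatio = 0.5) {
  new("SegmentationParams", sigma = sigma, epsilon = epsilon, fMax = fMax,
      rMax = rMax, haloCorrection = haloCorrection, aRatio = aRatio)
}

# floor below which the windowed mean is treated as zero (dark regions get
# zero contrast and are classified background)
.muFloor <- 1e-6

#' Local contrast map of a grayscale image
#'
#' Local contrast is the standard deviation of the image within a soft
#' Gaussian window divided by the mean within the same window, computed by
#' convolution: with `w` a unit-sum Gaussian kernel, `mu = I * w`,
#' `m2 = I^2 * w`, `C = sqrt(max(m2 - mu^2, 0)) / mu`.  It is high in
#' textured cell regions and low on uniform background, and is invariant to
#' a multiplicative rescaling of the image.  Where `mu` falls below an
#' internal floor (1e-6) the contrast is defined as 0.
#'
#' The Gaussian window is truncated at 4 sigma and renormalized; image
#' borders are handled by replicate padding.
#'
#' @param I numeric matrix of intensities in `[0, 1]`.
#' @param sigma window scale in pixels (> 0).
#' @return numeric matrix of non-negative local contrast values.
#' @export
localContrast <- function(I, sigma) {
  checkGray(I)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) stop("'sigma' must be a single positive number")
  k <- gaussKernel(sigma)
  mu <- corrSep(I, k, k)
  m2 <- corrSep(I * I, k, k)
  v <- pmax(m2 - mu * mu, 0)
  C <- matrix(0, nrow(I), ncol(I))
  ok <- mu > .muFloor
  C[ok] <- sqrt(v[ok]) / mu[ok]
  C
}

#' Threshold a local contrast map
#'
#' @param C local contrast matrix from [localContrast()].
#' @param epsilon global threshold (>= 0); pixels with `C > epsilon` become
#'   cell pixels.
#' @return logical matrix (`TRUE` = cell).
#' @export
thresholdContrast <- function(C, epsilon) {
  if (!is.matrix(C) || !is.numeric(C)) stop("'C' must be a numeric matrix")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("'epsilon' must be a single number >= 0")
  C > epsilon
}

#' Fill small holes in a binary mask
#'
#' Background connected components (4-connectivity) that do not touch the
#' image border and whose area is strictly below `fMax` are set to cell.
#'
#' @param mask logical matrix.
#' @param fMax hole area bound in pixels; `fMax = 0` is the identity.
#' @return logical matrix containing the input mask.
#' @export
fillHoles <- function(mask, fMax) {
  checkMask(mask)
  if (fMax < 0) stop("'fMax' must be >= 0")
  if (fMax == 0 || !any(!mask)) return(mask)
  lab <- labelComponents(!mask, connectivity = 4L)
  areas <- componentAreas(lab)
  fill <- which(areas < fMax)
  fill <- setdiff(fill, borderLabels(lab))
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

#' Remove small objects from a binary mask
#'
#' Cell connected components (8-connectivity) whose area is strictly below
#' `rMax` are set to background.
#'
#' @param mask logical matrix.
#' @param rMax object area bound in pixels; `rMax = 0` is the identity.
#' @return logical matrix contained in the input mask.
#' @export
removeSmallObjects <- function(mask, rMax) {
  checkMask(mask)
  if (rMax < 0) stop("'rMax' must be >= 0")
  if (rMax == 0 || !any(mask)) return(mask)
  lab <- labelComponents(mask, connectivity = 8L)
  areas <- componentAreas(lab)
  drop <- which(areas < rMax)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

#' Segment a PCM image
#'
#' Full pipeline: local contrast, global threshold, hole filling,
#' small-object removal and (by default) halo correction, which removes the
#' bright halo flank by tracking along Kirsch gradient directions (see
#' [correctHalo()]).  Deterministic for fixed input and parameters.
#'
#' @param I numeric matrix of intensities in `[0, 1]`.
#' @param params a [SegmentationParams-class]; see [segParams()].
#' @return logical matrix (`TRUE` = cell pixel).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(128, 128), nCells = 1,
#'                                   radiusRange = c(18, 22), seed = 1))
#' mask <- segmentPCM(phantomImage(ph), segParams())
#' imageConfluency(mask)
#' @export
segmentPCM <- function(I, params = segParams()) {
  stopifnot(is(params, "SegmentationParams"))
  validObject(params)
  C <- localContrast(I, params@sigma)
  G <- thresholdContrast(C, params@epsilon)
  G <- fillHoles(G, params@fMax)
  G <- removeSmallObjects(G, params@rMax)
  if (params@haloCorrection && any(G))
    G <- correctHalo(G, I, aRatio = params@aRatio)
  G
}
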