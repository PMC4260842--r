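#' @import methods
NULL

#' Raw raster image with integer samples
#'
#' Container for an image as read from disk: integer samples (stored as
#' numerics), a bit depth, and an optional physical pixel size.  No rescaling
#' is performed at read time; use [normalizeIntensity()] to map samples to
#' the [0,1] intensity scale all downstream operations expect.
#'
#' @slot pixels numeric matrix (grayscale) or rows x cols x 3 array (RGB) of
#'   integer samples in `[0, 2^bitDepth - 1]`.
#' @slot bitDepth integer, 8 or 16.
#' @slot pixelSizeUm physical pixel size in micrometres per pixel, or `NA`.
#'   Metadata only: all computations are in pixel units.
#' @export
setClass("RasterImage",
  representation(pixels = "array", bitDepth = "integer",
                 pixelSizeUm = "numeric"),
  prototype(bitDepth = 8L, pixelSizeUm = NA_real_))

setValidity("RasterImage", function(object) {
  p <- object@pixels
  if (!(length(dim(p)) %in% c(2L, 3L)))
    return("pixels must be a 2-D matrix or a 3-plane array")
  if (length(dim(p)) == 3L && dim(p)[3] != 3L)
    return("3-D pixel arrays must have exactly 3 planes (RGB)")
  if (any(dim(p)[1:2] < 1L)) return("image must be at least 1 x 1")
  if (!(object@bitDepth %in% c(8L, 16L))) return("bitDepth must be 8 or 16")
  mx <- 2^object@bitDepth - 1
  if (any(!is.finite(p)) || any(p < 0) || any(p > mx))
    return(sprintf("samples must lie in [0, %d]", mx))
  TRUE
})

#' Parameters of the PCM segmentation pipeline
#'
#' @slot sigma Gaussian window scale (pixels) of the local-contrast filter.
#' @slot epsilon global local-contrast threshold (dimensionless).
#' @slot fMax holes smaller than this area (pixels) are filled.
#' @slot rMax objects smaller than this area (pixels) are removed.
#' @slot haloCorrection logical; run the gradient-tracking halo correction.
#' @slot aRatio maximum fraction of its area any object may lose to halo
#'   correction, in `[0, 1]`.
#' @seealso [segParams()] for the user-facing constructor with defaults.
#' @export
setClass("SegmentationParams",
  representation(sigma = "numeric", epsilon = "numeric", fMax = "numeric",
                 rMax = "numeric", haloCorrection = "logical",
                 aRatio = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0) return("sigma must be a single positive number")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon < 0) return("epsilon must be >= 0")
  if (object@fMax < 0) return("fMax must be >= 0")
  if (object@rMax < 0) return("rMax must be >= 0")
  if (length(object@haloCorrection) != 1L || is.na(object@haloCorrection))
    return("haloCorrection must be TRUE or FALSE")
  if (object@aRatio < 0 || object@aRatio > 1)
    return("aRatio must lie in [0, 1]")
  TRUE
})

#' Per-pixel gradient direction map from Kirsch filters
#'
#' Directions index the eight compass directions 0 = N, 1 = NE, 2 = E,
#' 3 = SE, 4 = S, 5 = SW, 6 = W, 7 = NW, oriented so that each points toward
#' increasing intensity.  North is decreasing row index.
#'
#' @slot directions integer matrix with entries in 0..7.
#' @slot responses numeric matrix of the maximal Kirsch response per pixel.
#' @export
setClass("DirectionMap",
  representation(directions = "matrix", responses = "matrix"))

setValidity("DirectionMap", function(object) {
  d <- object@directions
  if (!all(d %in% 0:7)) return("directions must be integers in 0..7")
  if (!identical(dim(d), dim(object@responses)))
    return("directions and responses must have the same shape")
  TRUE
})

#' Confluency of a culture from multiple images
#'
#' @slot perImage numeric vector of per-image confluency fractions.
#' @slot cultureMean mean confluency across images.
#' @slot cultureSEM standard error of the mean.
#' @slot nImages number of images.
#' @slot undersampled `TRUE` when fewer than 20 images were supplied
#'   (culture-level confluency is conventionally averaged over at least 20
#'   random fields of view).
#' @export
setClass("ConfluencyResult",
  representation(perImage = "numeric", cultureMean = "numeric",
                 cultureSEM = "numeric", nImages = "integer",
                 undersampled = "logical"))

setValidity("ConfluencyResult", function(object) {
  if (object@nImages < 1L) return("at least one image is required")
  if (any(object@perImage < 0 | object@perImage > 1))
    return("per-image confluency must lie in [0, 1]")
  TRUE
})

#' Basic image feature (BIF) classification of an image
#'
#' Per-pixel classification into seven local structure classes computed from
#' scale-normalized Gaussian-derivative responses.  Class codes: 1 flat,
#' 2 slope, 3 bright_blob, 4 dark_blob, 5 bright_line, 6 dark_line, 7 saddle.
#'
#' @slot classes integer matrix with entries in 1..7.
#' @slot sigma filter scale used (pixels).
#' @slot epsFlat flatness threshold used.
#' @export
setClass("BIFMap",
  representation(classes = "matrix", sigma = "numeric", epsFlat = "numeric"))

setValidity("BIFMap", function(object) {
  if (!all(object@classes %in% 1:7))
    return("classes must be integers in 1..7")
  TRUE
})

#' Packing-corrected confluency of one image
#'
#' @slot confluency image confluency (fraction of cell pixels).
#' @slot meanBlobDistance mean over all pixels of the Euclidean distance to
#'   the nearest bright-blob centroid (pixels).
#' @slot pcc confluency / meanBlobDistance (1/pixels).
#' @slot nBlobs number of retained bright-blob centroids.
#' @export
setClass("PCCResult",
  representation(confluency = "numeric", meanBlobDistance = "numeric",
                 pcc = "numeric", nBlobs = "integer"))

setValidity("PCCResult", function(object) {
  if (object@pcc < 0) return("pcc must be >= 0")
  if (object@meanBlobDistance < 0) return("meanBlobDistance must be >= 0")
  TRUE
})

#' Linear calibration from PCC to cell density
#'
#' @slot slope,intercept ordinary least squares coefficients of
#'   `density = slope * PCC + intercept`.
#' @slot adjR2 adjusted r-squared of the fit.
#' @slot nrmse normalized RMSE (RMSE divided by the observed density range)
#'   of the fit on its calibration data.
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 adjR2 = "numeric", nrmse = "numeric"))

#' Pixelwise confusion counts of a segmentation against ground truth
#'
#' Cell pixels are the positive class.
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric",
                 fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0) || any(v != round(v)))
    return("counts must be non-negative integers")
  TRUE
})

#' Segmentation performance metrics
#'
#' @slot accuracy,precision,recall,fScore metrics in `[0, 1]`.
#' @slot mcc Matthews correlation coefficient in `[-1, 1]`.
#' @slot segError segmentation error, `1 - mcc`.
#' @export
setClass("MetricSet",
  representation(accuracy = "numeric", precision = "numeric",
                 recall = "numeric", fScore = "numeric", mcc = "numeric",
                 segError = "numeric"))

#' Precision statistics of confluency estimation
#'
#' Satisfies `rmse^2 = bias^2 + precision^2` by construction.
#'
#' @slot rmse root mean square error against ground truth.
#' @slot bias mean signed difference (systematic error).
#' @slot precision `sqrt(rmse^2 - bias^2)` (random error).
#' @export
setClass("PrecisionStats",
  representation(rmse = "numeric", bias = "numeric", precision = "numeric"))

#' Variability statistics of a confluency survey
#'
#' @slot vBoth combined (intra plus inter) variability of the estimates.
#' @slot vIntra intra-rater variability from repeated estimates.
#' @slot vInter inter-rater variability, `sqrt(max(vBoth^2 - vIntra^2, 0))`.
#' @export
setClass("SurveyStats",
  representation(vBoth = "numeric", vIntra = "numeric", vInter = "numeric"))

#' Augmented fluorescence image (AFI)
#'
#' Class codes: 0 background, 1 negative cell, 2 low expression,
#' 3 high expression.  Non-background classes occur exactly where the
#' segmentation mask is true.
#'
#' @slot classes integer matrix with entries in 0..3.
#' @slot tLow,tHigh normalized intensity thresholds, `0 <= tLow < tHigh <= 1`.
#' @export
setClass("AFIMap",
  representation(classes = "matrix", tLow = "numeric", tHigh = "numeric"))

setValidity("AFIMap", function(object) {
  if (!all(object@classes %in% 0:3))
    return("classes must be integers in 0..3")
  if (!(object@tLow >= 0 && object@tLow < object@tHigh && object@tHigh <= 1))
    return("thresholds must satisfy 0 <= tLow < tHigh <= 1")
  TRUE
})

#' Specification of a synthetic PCM phantom
#'
#' Describes a phantom image emulating the appearance of adherent cells in
#' phase contrast microscopy: a near-uniform noisy background, cells as
#' deformed disks whose speckled interiors have background-comparable mean
#' intensity, and a bright halo band around each cell.  See
#' [phantomSpec()] for defaults and field semantics.
#'
#' @slot shape integer vector (rows, cols).
#' @slot nCells number of cells to place.
#' @slot radiusRange,haloWidthRange numeric (min, max) in pixels.
#' @slot haloGain peak halo brightness above background.
#' @slot interiorTextureSD speckle standard deviation inside cells.
#' @slot backgroundLevel,backgroundNoiseSD background mean intensity and
#'   noise SD.
#' @slot illuminationGradient amplitude of a linear shading ramp (0 = none).
#' @slot defocusSigma Gaussian blur scale applied last (0 = none).
#' @slot seed RNG seed; generation is deterministic given the spec.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", nCells = "integer",
                 radiusRange = "numeric", haloWidthRange = "numeric",
                 haloGain = "numeric", interiorTextureSD = "numeric",
                 backgroundLevel = "numeric", backgroundNoiseSD = "numeric",
                 illuminationGradient = "numeric", defocusSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 16L))
    return("shape must be (rows, cols), each >= 16")
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (any(object@radiusRange <= 0)) return("radii must be positive")
  if (any(object@haloWidthRange < 0)) return("halo widths must be >= 0")
  if (diff(object@radiusRange) < 0 || diff(object@haloWidthRange) < 0)
    return("ranges must be (min, max) with min <= max")
  TRUE
})

#' A generated phantom with its ground truth
#'
#' @slot image numeric matrix in [0,1]; the synthetic PCM image.
#' @slot truthMask logical matrix; true cell pixels (halo band excluded).
#' @slot centers two-column matrix (row, col) of planted cell centers.
#' @slot fluor numeric matrix in [0,1]; synthetic fluorescence channel with
#'   per-cell expression levels.
#' @slot spec the [PhantomSpec-class] that produced the bundle.
#' @export
setClass("PhantomBundle",
  representation(image = "matrix", truthMask = "matrix", centers = "matrix",
                 fluor = "matrix", spec = "PhantomSpec"))

setValidity("PhantomBundle", function(object) {
  if (!identical(dim(object@image), dim(object@truthMask)))
    return("image and truthMask must have the same shape")
  if (nrow(object@centers) > 0 &&
      !all(object@truthMask[object@centers]))
    return("all centers must lie inside the truth mask")
  TRUE
})
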