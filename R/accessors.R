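#' Accessors for phantastr result objects
#'
#' Slot access is discouraged; these accessors are the supported interface.
#'
#' @param object a phantastr S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @describeIn accessors per-pixel compass direction indices (0..7) of a
#'   [DirectionMap-class].
#' @export
directions <- function(object) object@directions

#' @describeIn accessors class-code matrix of a [BIFMap-class] (1..7) or an
#'   [AFIMap-class] (0..3).
#' @export
classMap <- function(object) object@classes

#' @describeIn accessors per-image confluency vector of a
#'   [ConfluencyResult-class].
#' @export
perImage <- function(object) object@perImage

#' @describeIn accessors culture mean confluency.
#' @export
cultureMean <- function(object) object@cultureMean

#' @describeIn accessors standard error of the culture mean.
#' @export
cultureSEM <- function(object) object@cultureSEM

#' @describeIn accessors packing-corrected confluency value of a
#'   [PCCResult-class].
#' @export
pccValue <- function(object) object@pcc

#' @describeIn accessors number of bright-blob centroids of a
#'   [PCCResult-class].
#' @export
nBlobs <- function(object) object@nBlobs

#' @describeIn accessors mean blob distance (pixels) of a [PCCResult-class].
#' @export
meanBlobDistance <- function(object) object@meanBlobDistance

#' @describeIn accessors coefficients of a [CalibrationModel-class] as a
#'   named vector `c(slope, intercept)`.
#' @export
calibrationCoef <- function(object)
  c(slope = object@slope, intercept = object@intercept)

#' @describeIn accessors metrics of a [MetricSet-class] as a named vector.
#' @export
metricValues <- function(object)
  c(accuracy = object@accuracy, precision = object@precision,
    recall = object@recall, f_score = object@fScore, mcc = object@mcc,
    seg_error = object@segError)

#' @describeIn accessors counts of a [ConfusionCounts-class] as a named
#'   vector.
#' @export
countValues <- function(object)
  c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn)

#' @describeIn accessors phantom image matrix of a [PhantomBundle-class].
#' @export
phantomImage <- function(object) object@image

#' @describeIn accessors ground-truth mask of a [PhantomBundle-class].
#' @export
truthMask <- function(object) object@truthMask

#' @describeIn accessors planted cell centers (row, col matrix) of a
#'   [PhantomBundle-class].
#' @export
cellCenters <- function(object) object@centers

#' @describeIn accessors synthetic fluorescence channel of a
#'   [PhantomBundle-class].
#' @export
fluorImage <- function(object) object@fluor

#' BIF class names in class-code order
#'
#' @return character vector of the seven class names; code i maps to name i.
#' @export
bifClassNames <- function()
  c("flat", "slope", "bright_blob", "dark_blob", "bright_line", "dark_line",
    "saddle")

#' AFI class names in class-code order (codes 0..3)
#'
#' @return character vector of the four class names.
#' @export
afiClassNames <- function()
  c("background", "negative_cell", "low_expression", "high_expression")
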