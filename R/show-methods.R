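setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("RasterImage: %d x %d %s, %d-bit", d[1], d[2], kind,
              object@bitDepth))
  if (!is.na(object@pixelSizeUm))
    cat(sprintf(", %.3g um/px", object@pixelSizeUm))
  cat("\n")
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:\n")
  cat(sprintf("  sigma = %g px, epsilon = %g, fMax = %g px, rMax = %g px\n",
              object@sigma, object@epsilon, object@fMax, object@rMax))
  cat(sprintf("  halo correction: %s (aRatio = %g)\n",
              if (object@haloCorrection) "on" else "off", object@aRatio))
})

setMethod("show", "DirectionMap", function(object) {
  d <- dim(object@directions)
  cat(sprintf("DirectionMap: %d x %d, compass indices 0 (N) .. 7 (NW)\n",
              d[1], d[2]))
})

setMethod("show", "ConfluencyResult", function(object) {
  cat(sprintf("ConfluencyResult: %.4f +/- %.4f (SEM) over %d image%s\n",
              object@cultureMean, object@cultureSEM, object@nImages,
              if (object@nImages == 1L) "" else "s"))
  if (object@undersampled)
    cat("  note: fewer than 20 images; culture estimate may be undersampled\n")
})

setMethod("show", "BIFMap", function(object) {
  d <- dim(object@classes)
  tab <- tabulate(object@classes, nbins = 7L)
  cat(sprintf("BIFMap: %d x %d (sigma = %g, epsFlat = %g)\n", d[1], d[2],
              object@sigma, object@epsFlat))
  cat(sprintf("  %s\n", paste(sprintf("%s:%d", bifClassNames(), tab),
                              collapse = " ")))
})

setMethod("show", "PCCResult", function(object) {
  cat(sprintf(
    "PCCResult: confluency %.4f / mean blob distance %.2f px = %.5f px^-1 (%d blobs)\n",
    object@confluency, object@meanBlobDistance, object@pcc, object@nBlobs))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: density = %.4g * PCC + %.4g\n",
              object@slope, object@intercept))
  cat(sprintf("  adjusted r^2 = %.4f, NRMSE = %.2f%%\n", object@adjR2,
              100 * object@nrmse))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %g  FP %g  TN %g  FN %g\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "MetricSet", function(object) {
  cat(sprintf(
    "MetricSet: accuracy %.4f  precision %.4f  recall %.4f  F %.4f  MCC %.4f\n",
    object@accuracy, object@precision, object@recall, object@fScore,
    object@mcc))
})

setMethod("show", "PrecisionStats", function(object) {
  cat(sprintf("PrecisionStats: RMSE %.4g  bias %.4g  precision %.4g\n",
              object@rmse, object@bias, object@precision))
})

setMethod("show", "SurveyStats", function(object) {
  cat(sprintf("SurveyStats: combined %.4g  intra %.4g  inter %.4g\n",
              object@vBoth, object@vIntra, object@vInter))
})

setMethod("show", "AFIMap", function(object) {
  d <- dim(object@classes)
  tab <- tabulate(object@classes + 1L, nbins = 4L)
  cat(sprintf("AFIMap: %d x %d (tLow = %g, tHigh = %g)\n", d[1], d[2],
              object@tLow, object@tHigh))
  cat(sprintf("  background:%d negative:%d low:%d high:%d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d, %d cells, radius [%g, %g] px, halo [%g, %g] px, seed %d\n",
    object@shape[1], object@shape[2], object@nCells, object@radiusRange[1],
    object@radiusRange[2], object@haloWidthRange[1], object@haloWidthRange[2],
    object@seed))
})

setMethod("show", "PhantomBundle", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomBundle: %d x %d, %d cells, true confluency %.4f\n",
              d[1], d[2], nrow(object@centers), mean(object@truthMask)))
})
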