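#' Pixelwise confusion counts against a ground-truth mask
#'
#' Cell pixels are the positive class.
#'
#' @param pred,truth logical matrices of the same shape.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  checkMask(pred, "pred")
  checkMask(truth, "truth")
  sameShape(pred, truth, "predicted", "truth")
  new("ConfusionCounts",
      tp = as.numeric(sum(pred & truth)), fp = as.numeric(sum(pred & !truth)),
      tn = as.numeric(sum(!pred & !truth)),
      fn = as.numeric(sum(!pred & truth)))
}

#' Segmentation performance metrics from confusion counts
#'
#' Computes accuracy `(TP + TN) / (TP + FN + FP + TN)`, precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`, the F-score
#' `2 TP / (2 TP + FP + FN)` (the harmonic mean of precision and recall)
#' and the Matthews correlation coefficient
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, plus the
#' segmentation error `1 - MCC`.
#'
#' Degenerate denominators: precision and recall are 0 when their
#' denominator is 0; MCC is 0 (random-equivalent) when any marginal is 0.
#'
#' @param counts a [ConfusionCounts-class], or a predicted mask (in which
#'   case `truth` must be given and counts are computed first).
#' @param truth optional ground-truth mask.
#' @return A [MetricSet-class].
#' @export
rocMetrics <- function(counts, truth = NULL) {
  if (!is(counts, "ConfusionCounts")) {
    if (is.null(truth))
      stop("supply ConfusionCounts, or a predicted mask plus 'truth'")
    counts <- confusionCounts(counts, truth)
  }
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion counts")
  acc <- (tp + tn) / total
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  new("MetricSet", accuracy = acc, precision = prec, recall = rec,
      fScore = f, mcc = mcc, segError = 1 - mcc)
}

#' Precision statistics of confluency estimation
#'
#' Given algorithmic estimates and ground-truth confluencies, computes the
#' root mean square error, the mean signed difference (bias; the systematic
#' component) and the precision `sqrt(rmse^2 - bias^2)` (the random
#' component).  The identity `rmse^2 = bias^2 + precision^2` holds by
#' construction.
#'
#' @param estimates,truths numeric vectors of equal length (>= 2).
#' @return A [PrecisionStats-class].
#' @export
estimationPrecision <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("'estimates' and 'truths' must have equal length")
  if (length(estimates) < 2L) stop("at least two pairs are required")
  d <- estimates - truths
  rmse <- sqrt(mean(d^2))
  bias <- mean(d)
  new("PrecisionStats", rmse = rmse, bias = bias,
      precision = sqrt(max(rmse^2 - bias^2, 0)))
}

#' Variability statistics of a confluency survey
#'
#' Quantifies how variable human confluency estimates are.  The combined
#' (intra plus inter) variability is the pooled standard deviation of the
#' estimates `e[i, j]` (image i, rater j) about the per-image means.  The
#' intra-rater variability comes from pairs of repeated estimates
#' `(r1, r2)` by the same rater of the same material:
#' `vIntra = sqrt(sum((r1 - r2)^2) / (2 n))`.  The inter-rater component is
#' obtained by subtraction in quadrature,
#' `vInter = sqrt(max(vBoth^2 - vIntra^2, 0))` (clamped at 0 when sampling
#' noise makes the intra estimate exceed the combined one).
#'
#' @param estimateMatrix numeric matrix, images in rows, raters in columns
#'   (>= 2 of each).
#' @param repeatPairs two-column numeric matrix of repeated estimates by the
#'   same rater (>= 1 row).
#' @return A [SurveyStats-class].
#' @export
surveyStats <- function(estimateMatrix, repeatPairs) {
  if (!is.matrix(estimateMatrix) || ncol(estimateMatrix) < 2L)
    stop("'estimateMatrix' needs at least 2 raters (columns)")
  if (nrow(estimateMatrix) < 2L)
    stop("'estimateMatrix' needs at least 2 images (rows)")
  if (!is.matrix(repeatPairs) || ncol(repeatPairs) != 2L ||
      nrow(repeatPairs) < 1L)
    stop("'repeatPairs' must be a two-column matrix with >= 1 row")
  dev <- estimateMatrix - rowMeans(estimateMatrix)
  m <- nrow(estimateMatrix); nr <- ncol(estimateMatrix)
  vBoth <- sqrt(sum(dev^2) / (m * (nr - 1)))
  vIntra <- sqrt(sum((repeatPairs[, 1] - repeatPairs[, 2])^2) /
                   (2 * nrow(repeatPairs)))
  new("SurveyStats", vBoth = vBoth, vIntra = vIntra,
      vInter = sqrt(max(vBoth^2 - vIntra^2, 0)))
}

#' Combine independent precision components in quadrature
#'
#' @param components numeric vector of standard-deviation-like components
#'   (all >= 0), e.g. the single-image estimation precision and the random
#'   sampling error of a multi-image survey of a culture.
#' @return `sqrt(sum(components^2))`.
#' @examples
#' combinePrecision(c(2.7, 1.74))  # overall confluency precision, percent
#' @export
combinePrecision <- function(components) {
  if (any(components < 0)) stop("components must be >= 0")
  sqrt(sum(components^2))
}

#' Grid search of segmentation parameters with LOOCV
#'
#' Scores every candidate parameter set on every image by the segmentation
#' error `1 - MCC` against ground truth.  Generalization is assessed by
#' leave-one-out cross validation: for each held-out image the candidate
#' minimizing the mean error on the remaining images is selected and the
#' held-out image's error under that candidate is recorded; the LOOCV error
#' is the mean of these.  The returned parameter set minimizes the mean
#' error over all images.  Ties are broken by lexicographic parameter
#' order.
#'
#' @param images list of intensity matrices.
#' @param truths list of matching ground-truth masks.
#' @param grid named list of candidate values per parameter (any of
#'   `sigma`, `epsilon`, `fMax`, `rMax`, `aRatio`, `haloCorrection`);
#'   omitted parameters keep the [segParams()] defaults.  All combinations
#'   are scored.
#' @return A list with `best` (a [SegmentationParams-class]), `loocvError`,
#'   `trainError` (mean error of `best` over all images), and `errors`
#'   (grid points x images matrix of segmentation errors, with the grid as
#'   `attr(, "grid")`).
#' @export
gridSearchParams <- function(images, truths, grid) {
  if (!is.list(images) || !is.list(truths) ||
      length(images) != length(truths) || length(images) < 2L)
    stop("need >= 2 image/truth pairs of equal count")
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)))
    stop("'grid' must be a non-empty named list of candidate values")
  known <- c("sigma", "epsilon", "fMax", "rMax", "aRatio", "haloCorrection")
  bad <- setdiff(names(grid), known)
  if (length(bad)) stop("unknown grid parameters: ",
                        paste(bad, collapse = ", "))
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  # lexicographic order in the declared parameter order, for tie-breaking
  pts <- pts[do.call(order, as.list(pts)), , drop = FALSE]
  rownames(pts) <- NULL
  nG <- nrow(pts); nI <- length(images)
  errors <- matrix(NA_real_, nG, nI)
  for (g in seq_len(nG)) {
    args <- as.list(pts[g, , drop = FALSE])
    p <- do.call(segParams, args)
    for (i in seq_len(nI)) {
      pred <- segmentPCM(images[[i]], p)
      errors[g, i] <- rocMetrics(confusionCounts(pred, truths[[i]]))@segError
    }
  }
  heldOut <- vapply(seq_len(nI), function(i) {
    trainMean <- rowMeans(errors[, -i, drop = FALSE])
    errors[which.min(trainMean), i]   # which.min takes the first minimum
  }, numeric(1))
  overall <- rowMeans(errors)
  bestIdx <- which.min(overall)
  attr(errors, "grid") <- pts
  list(best = do.call(segParams, as.list(pts[bestIdx, , drop = FALSE])),
       loocvError = mean(heldOut),
       trainError = overall[bestIdx],
       errors = errors)
}
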