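#' Process a directory or list of images through one pipeline command
#'
#' Thin batch driver behind the command-line interface.  Each input image
#' is processed independently; failures are logged and skipped rather than
#' aborting the run, and the number of failures is reported so callers can
#' signal a partial-failure exit status.  Output rows are deterministic for
#' fixed inputs and configuration.
#'
#' Commands: `"segment"` (writes one mask per image next to `outDir`,
#' reports confluency), `"confluency"` (reads masks, reports per-image and
#' summary confluency), `"morpho"` (reads masks, one row per object),
#' `"pcc"` (segments and reports PCC per image), `"evaluate"` (pairs
#' predicted and truth masks by position, reports metrics per image).
#'
#' @param command one of `"segment"`, `"confluency"`, `"morpho"`, `"pcc"`,
#'   `"evaluate"`.
#' @param inputs character vector of image paths (for `"evaluate"`, the
#'   predicted masks).
#' @param truths character vector of ground-truth mask paths
#'   (`"evaluate"` only).
#' @param params a [SegmentationParams-class].
#' @param outDir directory for written masks (`"segment"`); created if
#'   missing.  `NULL` disables writing.
#' @param sigmaBif,epsFlat BIF parameters for `"pcc"`.
#' @return A data.frame of per-image results; attributes `nFailed` (count
#'   of skipped inputs) and `failures` (their paths).
#' @export
runBatch <- function(command = c("segment", "confluency", "morpho", "pcc",
                                 "evaluate"),
                     inputs, truths = NULL, params = segParams(),
                     outDir = NULL, sigmaBif = 4, epsFlat = 0) {
  command <- match.arg(command)
  if (length(inputs) == 0L) stop("no input images given")
  if (command == "evaluate" &&
      (is.null(truths) || length(truths) != length(inputs)))
    stop("'evaluate' needs one truth mask per input")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  rows <- list()
  failures <- character(0)
  for (i in seq_along(inputs)) {
    path <- inputs[i]
    row <- tryCatch({
      if (command == "segment") {
        I <- normalizeIntensity(loadImage(path))
        t0 <- proc.time()[["elapsed"]]
        mask <- segmentPCM(I, params)
        dt <- proc.time()[["elapsed"]] - t0
        if (!is.null(outDir))
          writeMask(mask, file.path(outDir, paste0(
            tools::file_path_sans_ext(basename(path)), "_mask.png")))
        data.frame(image = basename(path),
                   confluency = imageConfluency(mask),
                   n_objects = max(labelComponents(mask, 8L)),
                   seconds = round(dt, 3))
      } else if (command == "confluency") {
        mask <- normalizeIntensity(loadImage(path)) > 0.5
        data.frame(image = basename(path),
                   confluency = imageConfluency(mask))
      } else if (command == "morpho") {
        mask <- normalizeIntensity(loadImage(path)) > 0.5
        obj <- extractObjects(mask)
        if (nrow(obj) == 0L) NULL
        else cbind(image = basename(path),
                   obj[, c("label", "area", "perimeter", "solidity",
                           "formFactor")])
      } else if (command == "pcc") {
        I <- normalizeIntensity(loadImage(path))
        r <- imagePCC(I, params = params, sigmaBif = sigmaBif,
                      epsFlat = epsFlat)
        data.frame(image = basename(path), confluency = r@confluency,
                   mean_blob_distance = r@meanBlobDistance, pcc = r@pcc,
                   n_blobs = r@nBlobs)
      } else {
        pred <- normalizeIntensity(loadImage(path)) > 0.5
        truth <- normalizeIntensity(loadImage(truths[i])) > 0.5
        m <- rocMetrics(confusionCounts(pred, truth))
        data.frame(image = basename(path), accuracy = m@accuracy,
                   precision = m@precision, recall = m@recall,
                   f_score = m@fScore, mcc = m@mcc,
                   seg_error = m@segError)
      }
    }, error = function(e) {
      message("skipping '", path, "': ", conditionMessage(e))
      failures <<- c(failures, path)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  attr(out, "nFailed") <- length(failures)
  attr(out, "failures") <- failures
  out
}
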