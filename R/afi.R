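#' Build an augmented fluorescence image (AFI)
#'
#' Combines a PCM segmentation mask with a same-field fluorescence image
#' into a four-class map: background where the mask is false, and among
#' cell pixels: negative where fluorescence is at or below `tLow`, low
#' expression in `(tLow, tHigh]`, and high expression above `tHigh`.
#' Thresholds are in normalized `[0, 1]` units, so they are independent of
#' the acquisition bit depth; the defaults (0.094 for GFP-positive, 0.24
#' for high expression) correspond to empirically determined background and
#' high-expression levels on 8-bit images (approximately 24/255 and
#' 60/255).
#'
#' @param mask logical matrix from [segmentPCM()].
#' @param fluor numeric matrix of fluorescence intensities in `[0, 1]`.
#' @param tLow GFP-positive threshold.
#' @param tHigh low/high expression threshold (must exceed `tLow`).
#' @return An [AFIMap-class] with codes 0 background, 1 negative cell,
#'   2 low expression, 3 high expression.
#' @export
makeAFI <- function(mask, fluor, tLow = 0.094, tHigh = 0.24) {
  checkMask(mask)
  checkGray(fluor, "fluor")
  sameShape(mask, fluor, "mask", "fluorescence image")
  if (!(tLow >= 0 && tLow < tHigh && tHigh <= 1))
    stop("thresholds must satisfy 0 <= tLow < tHigh <= 1")
  cls <- matrix(0L, nrow(mask), ncol(mask))
  cls[mask] <- 1L
  cls[mask & fluor > tLow] <- 2L
  cls[mask & fluor > tHigh] <- 3L
  new("AFIMap", classes = cls, tLow = tLow, tHigh = tHigh)
}

#' Summary statistics of an AFI
#'
#' @param afi an [AFIMap-class].
#' @param fluor the fluorescence image the AFI was built from.
#' @return A list with `fractionPositive` (fraction of cell pixels with
#'   detectable expression), `meanIntensity` (mean fluorescence over cell
#'   pixels), `confluency` (fraction of cell pixels in the image),
#'   `nCellPixels`, and `undefined` (`TRUE` when there are no cell pixels,
#'   in which case the fraction and mean are `NA`).
#' @export
afiSummaries <- function(afi, fluor) {
  stopifnot(is(afi, "AFIMap"))
  checkGray(fluor, "fluor")
  sameShape(afi@classes, fluor, "AFI", "fluorescence image")
  cell <- afi@classes > 0L
  nCell <- sum(cell)
  if (nCell == 0L)
    return(list(fractionPositive = NA_real_, meanIntensity = NA_real_,
                confluency = 0, nCellPixels = 0L, undefined = TRUE))
  list(fractionPositive = sum(afi@classes >= 2L) / nCell,
       meanIntensity = mean(fluor[cell]),
       confluency = nCell / length(cell),
       nCellPixels = as.integer(nCell),
       undefined = FALSE)
}

#' Render an AFI as an RGB array
#'
#' Black background, red negative cells, light green low expression, dark
#' green high expression.
#'
#' @param afi an [AFIMap-class].
#' @return rows x cols x 3 numeric array in `[0, 1]`, suitable for
#'   [png::writePNG()].
#' @export
renderAFI <- function(afi) {
  stopifnot(is(afi, "AFIMap"))
  cls <- afi@classes
  pal <- rbind(background = c(0, 0, 0),
               negative_cell = c(0.85, 0.1, 0.1),
               low_expression = c(0.55, 0.95, 0.55),
               high_expression = c(0, 0.5, 0))
  out <- array(0, dim = c(nrow(cls), ncol(cls), 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(pal[cls + 1L, ch], nrow(cls), ncol(cls))
  out
}
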