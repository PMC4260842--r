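#' Read a TIFF or PNG image without rescaling
#'
#' Reads an 8- or 16-bit grayscale or RGB image and returns the raw integer
#' samples together with the detected bit depth.  Intensities are not
#' rescaled; pass the result to [normalizeIntensity()] (and [toGrayscale()]
#' for RGB input) before segmentation.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixelSizeUm optional physical pixel size (micrometres per pixel),
#'   stored as metadata.
#' @return A [RasterImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(0.5, 4, 4), f)
#' loadImage(f)
#' @export
loadImage <- function(path, pixelSizeUm = NA_real_) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                   error = function(e) stop("failed to read TIFF '", path,
                                            "': ", conditionMessage(e)))
    # as.is = TRUE returns raw integer samples; bit depth from metadata
    bps <- attr(tiff::readTIFF(path, info = TRUE), "bits.per.sample")
    bd <- if (!is.null(bps)) as.integer(bps)
          else if (max(px) > 255) 16L else 8L
  } else if (ext == "png") {
    px <- tryCatch(png::readPNG(path, info = TRUE),
                   error = function(e) stop("failed to read PNG '", path,
                                            "': ", conditionMessage(e)))
    info <- attr(px, "info")
    bd <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    # readPNG scales to [0,1] by 2^depth - 1; recover exact integers
    px <- round(unclass(px) * (2^bd - 1))
  } else {
    stop("unsupported file format '", ext, "' (TIFF or PNG expected)")
  }
  if (!(bd %in% c(8L, 16L)))
    stop("unsupported bit depth ", bd, " (8 or 16 expected)")
  d <- dim(px)
  if (length(d) == 3L) {
    if (d[3] >= 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha if present
    else if (d[3] == 1L) px <- px[, , 1]
    else stop("unsupported sample format: ", d[3], " channels")
  }
  new("RasterImage", pixels = as.array(px), bitDepth = bd,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Convert an RGB image to grayscale
#'
#' Computes the weighted average `0.30 R + 0.59 G + 0.11 B` on normalized
#' planes, the standard luma weighting for PCM images acquired with color
#' cameras.
#'
#' @param img a 3-plane [RasterImage-class], or a rows x cols x 3 numeric
#'   array of intensities already in `[0, 1]`.
#' @return numeric matrix of intensities in `[0, 1]`.
#' @examples
#' rgb <- array(c(1, 0, 0), dim = c(1, 1, 3))  # pure red
#' toGrayscale(rgb)  # 0.30
#' @export
toGrayscale <- function(img) {
  if (is(img, "RasterImage")) {
    a <- normalizeIntensity(img, gray = FALSE)
  } else a <- img
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop("grayscale conversion requires a 3-plane RGB image")
  g <- 0.30 * a[, , 1] + 0.59 * a[, , 2] + 0.11 * a[, , 3]
  matrix(pmin(pmax(g, 0), 1), dim(a)[1], dim(a)[2])
}

#' Normalize integer samples to [0, 1] intensities
#'
#' Maps sample value `v` to `v / (2^bitDepth - 1)`, so 255 maps to 1.0 for
#' 8-bit images.  This convention makes intensity thresholds (for example
#' the AFI thresholds 0.094 and 0.24) independent of bit depth.
#'
#' @param img a [RasterImage-class].
#' @param gray collapse RGB input to grayscale via [toGrayscale()]
#'   (default `TRUE`).
#' @return numeric matrix in `[0, 1]` (or a 3-plane array if `gray = FALSE`
#'   and the input is RGB).
#' @export
normalizeIntensity <- function(img, gray = TRUE) {
  stopifnot(is(img, "RasterImage"))
  if (!(img@bitDepth %in% c(8L, 16L)))
    stop("unsupported bit depth ", img@bitDepth)
  a <- img@pixels / (2^img@bitDepth - 1)
  if (length(dim(a)) == 3L) {
    if (gray) return(toGrayscale(a))
    return(a)
  }
  matrix(a, dim(a)[1], dim(a)[2])
}

#' Write a binary mask as an 8-bit image
#'
#' Background pixels are written as 0 and cell pixels as 255.
#'
#' @param mask logical matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  checkMask(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path,
                                                      bits.per.sample = 8L)
  else stop("unsupported output format '", ext, "'")
  invisible(path)
}

#' Write a [0,1] intensity image to disk
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path, bits = 8L) {
  checkGray(img, "img")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  else stop("unsupported output format '", ext, "'")
  invisible(path)
}
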