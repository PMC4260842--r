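#' Image confluency
#'
#' The fraction of pixels labelled as cell.
#'
#' @param mask logical matrix (`TRUE` = cell).
#' @return fraction in `[0, 1]`.
#' @export
imageConfluency <- function(mask) {
  checkMask(mask)
  mean(mask)
}

#' Culture confluency from multiple images
#'
#' Averages per-image confluencies over fields of view sampled at random
#' locations of the culture.  At least 20 images are conventionally needed
#' for the sampling error to be negligible; fewer raise a warning and set
#' the `undersampled` flag.
#'
#' @param masks list of logical matrices.
#' @return A [ConfluencyResult-class].
#' @export
cultureConfluency <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("'masks' must be a non-empty list of logical matrices")
  per <- vapply(masks, imageConfluency, numeric(1))
  n <- length(per)
  sem <- if (n > 1L) stats::sd(per) / sqrt(n) else 0
  under <- n < 20L
  if (under)
    warning("culture confluency estimated from ", n,
            " images; at least 20 are recommended")
  new("ConfluencyResult", perImage = per, cultureMean = mean(per),
      cultureSEM = sem, nImages = as.integer(n), undersampled = under)
}

# perimeter of one object by Moore-neighbour boundary tracing: chain steps
# weigh 1 (axial) or sqrt(2) (diagonal).  `pix` is a 2-column (row, col)
# matrix of the object's pixels.  An isolated pixel has no chain; its
# perimeter is defined as 1.
chainPerimeter <- function(pix) {
  if (nrow(pix) == 1L) return(1)
  r0 <- min(pix[, 1]); c0 <- min(pix[, 2])
  B <- matrix(FALSE, max(pix[, 1]) - r0 + 3L, max(pix[, 2]) - c0 + 3L)
  B[cbind(pix[, 1] - r0 + 2L, pix[, 2] - c0 + 2L)] <- TRUE
  # start: first foreground pixel in column-major scan; its predecessor in
  # scan order (the pixel above) is background, so the first clockwise
  # search can begin at north
  start <- which(B)[1]
  R <- nrow(B)
  sr <- ((start - 1L) %% R) + 1L
  sc <- ((start - 1L) %/% R) + 1L
  # clockwise Moore neighbourhood starting north
  nb <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                 1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L), ncol = 2L, byrow = TRUE)
  stepLen <- ifelse(abs(nb[, 1]) + abs(nb[, 2]) == 2L, sqrt(2), 1)
  cr <- sr; cc <- sc
  search <- 1L
  perim <- 0
  firstMove <- NA_integer_
  moves <- 0L
  maxMoves <- 8L * nrow(pix) + 8L
  repeat {
    found <- 0L
    for (i in 0:7) {
      k <- ((search - 1L + i) %% 8L) + 1L
      if (B[cr + nb[k, 1], cc + nb[k, 2]]) { found <- k; break }
    }
    if (found == 0L) return(1)  # isolated pixel (cannot happen for n > 1)
    # Jacob's criterion: stop when positioned at the start pixel and about
    # to repeat the very first move
    if (moves > 0L && cr == sr && cc == sc && found == firstMove) break
    perim <- perim + stepLen[found]
    cr <- cr + nb[found, 1]; cc <- cc + nb[found, 2]
    moves <- moves + 1L
    if (is.na(firstMove)) firstMove <- found
    # next clockwise scan starts two steps counter-clockwise of the
    # direction of arrival (the backtrack position)
    search <- ((found - 1L + 6L) %% 8L) + 1L
    if (moves > maxMoves) break  # defensive; trace length is bounded
  }
  perim
}

# area of the convex hull of an object's pixels, with pixels treated as unit
# squares: hull over the four corner points of every pixel, shoelace area
convexHullArea <- function(pix) {
  corners <- rbind(cbind(pix[, 1] - 0.5, pix[, 2] - 0.5),
                   cbind(pix[, 1] - 0.5, pix[, 2] + 0.5),
                   cbind(pix[, 1] + 0.5, pix[, 2] - 0.5),
                   cbind(pix[, 1] + 0.5, pix[, 2] + 0.5))
  h <- grDevices::chull(corners)
  v <- corners[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 2]; y <- v[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Form factor of an object
#'
#' `4 * pi * area / perimeter^2`: exactly 1 for an ideal circle, decreasing
#' with boundary irregularity.  Values depend on the perimeter estimator;
#' [extractObjects()] uses the 8-connected boundary chain length (1 per
#' axial step, sqrt(2) per diagonal step), which makes rasterized disks
#' score slightly below 1.
#'
#' @param area object area (pixels, >= 1).
#' @param perimeter boundary length (pixels, > 0).
#' @return dimensionless score.
#' @examples
#' formFactor(pi * 10^2, 2 * pi * 10)  # circle: 1
#' formFactor(25, 20)                  # square: pi/4
#' @export
formFactor <- function(area, perimeter) {
  if (any(area < 1)) stop("'area' must be >= 1")
  if (any(perimeter <= 0)) stop("'perimeter' must be > 0")
  4 * pi * area / perimeter^2
}

#' Solidity of an object
#'
#' The ratio of the object area to the area of its convex hull; 1 for
#' convex shapes, smaller for concave ones.
#'
#' @param area object area (pixels, >= 1).
#' @param convexArea convex hull area (>= `area`).
#' @return ratio in `(0, 1]`.
#' @export
solidity <- function(area, convexArea) {
  if (any(area < 1)) stop("'area' must be >= 1")
  if (any(convexArea < area))
    stop("'convexArea' must be at least 'area'")
  area / convexArea
}

#' Extract cellular objects and their morphometrics from a mask
#'
#' Identifies 8-connected components, discards objects in contact with the
#' image border (their shape is truncated by the field of view), and
#' computes for each remaining object its area, chain-code perimeter,
#' convex hull area (hull over pixel-square corners), solidity and form
#' factor.
#'
#' Border objects are excluded from morphometry only; they still count
#' toward confluency (see [imageConfluency()]).
#'
#' @param mask logical matrix.
#' @param includeBorder keep border-touching objects in the table (their
#'   morphometrics are still computed); default `FALSE`.
#' @return A data.frame with columns `label`, `area`, `perimeter`,
#'   `convexArea`, `solidity`, `formFactor`, `touchesBorder`, one row per
#'   object; the number of excluded border objects is in
#'   `attr(, "nBorderExcluded")`.
#' @export
extractObjects <- function(mask, includeBorder = FALSE) {
  checkMask(mask)
  lab <- labelComponents(mask, connectivity = 8L)
  n <- max(lab)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), convexArea = numeric(0),
                      solidity = numeric(0), formFactor = numeric(0),
                      touchesBorder = logical(0))
  if (n == 0L) {
    attr(empty, "nBorderExcluded") <- 0L
    return(empty)
  }
  onBorder <- borderLabels(lab)
  idx <- which(lab > 0L)
  pixByLab <- split(idx, lab[idx])
  R <- nrow(mask)
  rows <- lapply(seq_len(n), function(l) {
    touches <- l %in% onBorder
    if (touches && !includeBorder) return(NULL)
    li <- pixByLab[[as.character(l)]]
    pix <- cbind(((li - 1L) %% R) + 1L, ((li - 1L) %/% R) + 1L)
    area <- nrow(pix)
    per <- chainPerimeter(pix)
    ca <- max(convexHullArea(pix), area)
    data.frame(label = l, area = area, perimeter = per, convexArea = ca,
               solidity = solidity(area, ca),
               formFactor = formFactor(area, per), touchesBorder = touches)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  rownames(out) <- NULL
  attr(out, "nBorderExcluded") <-
    if (includeBorder) 0L else length(onBorder)
  out
}
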