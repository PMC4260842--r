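# Compass geometry shared by the Kirsch direction map and the halo tracker.
# Index 0..7 = N, NE, E, SE, S, SW, W, NW; north is decreasing row index.
.compassOffsets <- matrix(c(-1L,  0L,   # N
                            -1L,  1L,   # NE
                             0L,  1L,   # E
                             1L,  1L,   # SE
                             1L,  0L,   # S
                             1L, -1L,   # SW
                             0L, -1L,   # W
                            -1L, -1L),  # NW
                          ncol = 2L, byrow = TRUE,
                          dimnames = list(c("N", "NE", "E", "SE", "S", "SW",
                                            "W", "NW"), c("dr", "dc")))

# the eight 3x3 Kirsch kernels in correlation orientation (kernel row 1 acts
# on the image row above the output pixel).  North kernel has the +5
# coefficients on its top row, so a large response means the pixels to the
# north are brighter: the argmax direction points toward increasing intensity.
kirschKernels <- function() {
  ringPos <- matrix(c(1, 2,  1, 3,  2, 3,  3, 3,  3, 2,  3, 1,  2, 1,  1, 1),
                    ncol = 2L, byrow = TRUE)  # N, NE, E, SE, S, SW, W, NW
  lapply(0:7, function(d) {
    k <- matrix(-3, 3, 3)
    k[2, 2] <- 0
    hot <- (c(d - 1, d, d + 1) %% 8) + 1
    for (p in hot) k[ringPos[p, 1], ringPos[p, 2]] <- 5
    k
  })
}

#' Kirsch gradient direction map
#'
#' Convolves the image with the eight 3x3 Kirsch kernels (four cardinal and
#' four inter-cardinal directions) and assigns every pixel the compass
#' direction of the maximal response, which points toward increasing
#' intensity.  Ties are broken toward the smallest direction index
#' (0 = north).
#'
#' @param I numeric matrix of intensities in `[0, 1]`.
#' @return A [DirectionMap-class] with direction indices 0..7 and the
#'   maximal response per pixel.
#' @export
kirschDirections <- function(I) {
  checkGray(I)
  kernels <- kirschKernels()
  n <- length(I)
  resp <- matrix(0, n, 8L)
  for (d in 1:8) resp[, d] <- as.vector(corr3x3(I, kernels[[d]]))
  best <- max.col(resp, ties.method = "first")
  new("DirectionMap",
      directions = matrix(as.integer(best - 1L), nrow(I), ncol(I)),
      responses = matrix(resp[cbind(seq_len(n), best)], nrow(I), ncol(I)))
}

#' Remove halo artifacts from a segmentation mask
#'
#' PCM images carry a bright halo band (typically 10-30 px wide) around
#' cells; contrast thresholding classifies the whole band as cell.  Starting
#' from the mask boundary, this routine tracks toward brighter intensities
#' along the Kirsch gradient direction and relabels halo pixels as
#' background until it reaches the halo/cell interface, which is marked by a
#' reversal of the gradient direction.
#'
#' For each boundary cell pixel (a cell pixel with at least one background
#' 4-neighbour) taken from a FIFO queue, the three pixels reached by
#' stepping one pixel along its gradient direction and the two adjacent
#' (+/-45 degree) directions are examined.  If at least one of the three is
#' currently a cell pixel, the location is relabelled background and those
#' candidates that are cell pixels are enqueued; otherwise it is confirmed
#' as cell.  A pixel is decided at most once.  Steps that leave the image
#' count as background.  Per connected component of the input mask, removal
#' stops once the removed area would exceed `aRatio` times the original
#' component area; remaining queued pixels of that component are confirmed.
#'
#' The output never gains pixels, and every original component keeps at
#' least a `1 - aRatio` fraction of its area.
#'
#' @param mask logical matrix to be corrected.
#' @param I numeric matrix of intensities in `[0, 1]` (same shape).
#' @param dirs optional precomputed [DirectionMap-class] of `I`.
#' @param aRatio maximum per-object area-reduction fraction in `[0, 1]`;
#'   `aRatio = 0` returns the mask unchanged.
#' @return logical matrix, a subset of `mask`.
#' @export
correctHalo <- function(mask, I, dirs = NULL, aRatio = 0.5) {
  checkMask(mask)
  checkGray(I)
  sameShape(mask, I, "mask", "image")
  if (!is.numeric(aRatio) || length(aRatio) != 1L || aRatio < 0 || aRatio > 1)
    stop("'aRatio' must be a single number in [0, 1]")
  if (aRatio == 0 || !any(mask)) return(mask)
  if (is.null(dirs)) dirs <- kirschDirections(I)
  stopifnot(is(dirs, "DirectionMap"))
  sameShape(mask, dirs@directions, "mask", "direction map")

  R <- nrow(mask); C <- ncol(mask)
  lab <- labelComponents(mask, connectivity = 8L)
  areas <- componentAreas(lab)
  budget <- floor(aRatio * areas + 1e-9)
  removed <- integer(length(areas))
  capped <- budget == 0L

  # pixel states: 0 background, 1 cell (undecided), 2 queued, 3 confirmed cell
  state <- matrix(0L, R, C)
  state[mask] <- 1L
  dirv <- as.integer(dirs@directions)

  # seed: cell pixels with a background 4-neighbour (image border counts)
  bgPad <- matrix(TRUE, R + 2L, C + 2L)
  bgPad[2:(R + 1L), 2:(C + 1L)] <- !mask
  boundary <- mask & (bgPad[1:R, 2:(C + 1L)] | bgPad[3:(R + 2L), 2:(C + 1L)] |
                      bgPad[2:(R + 1L), 1:C] | bgPad[2:(R + 1L), 3:(C + 2L)])
  queue <- integer(sum(mask))
  seed <- which(boundary)
  nSeed <- length(seed)
  if (nSeed == 0L) return(mask)
  queue[seq_len(nSeed)] <- seed
  state[seed] <- 2L
  head <- 1L; tail <- nSeed

  off <- .compassOffsets
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    comp <- lab[p]
    if (capped[comp]) { state[p] <- 3L; next }
    pr <- ((p - 1L) %% R) + 1L
    pc <- ((p - 1L) %/% R) + 1L
    d <- dirv[p]
    hit <- 0L
    cand <- integer(3L)
    for (k in c(d, (d + 1L) %% 8L, (d + 7L) %% 8L)) {
      rr <- pr + off[k + 1L, 1L]
      cc <- pc + off[k + 1L, 2L]
      if (rr < 1L || rr > R || cc < 1L || cc > C) next  # outside = background
      q <- (cc - 1L) * R + rr
      if (state[q] > 0L) {  # currently a cell pixel
        hit <- hit + 1L
        cand[hit] <- q
      }
    }
    if (hit > 0L) {
      if (removed[comp] + 1L > budget[comp]) {
        capped[comp] <- TRUE
        state[p] <- 3L
        next
      }
      state[p] <- 0L
      removed[comp] <- removed[comp] + 1L
      for (i in seq_len(hit)) {
        q <- cand[i]
        if (state[q] == 1L) {  # undecided cell: enqueue once
          state[q] <- 2L
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    } else {
      state[p] <- 3L
    }
  }
  state > 0L
}
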