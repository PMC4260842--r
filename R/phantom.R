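#' Phantom specification constructor
#'
#' Describes a synthetic PCM-like image.  The defaults emulate 10x PCM
#' images of adherent colony-forming cells: a 960 x 1280 field, cells as
#' deformed disks a few tens of pixels across whose speckled interiors
#' share the background mean intensity (the low-contrast property that
#' motivates local-contrast segmentation), and a bright halo band 10-30
#' pixels wide around each cell with smooth half-cosine shoulders, so that
#' a genuine gradient reversal exists at the halo/cell interface — the cue
#' the halo-correction tracking relies on.  A small Gaussian bump at each
#' cell center mimics the nucleus-like bright blob texture used by the PCC
#' density estimator.
#'
#' @param shape image shape (rows, cols).
#' @param nCells number of cells to place (non-overlapping, halo included).
#' @param radiusRange cell radius range (min, max) in pixels.
#' @param haloWidthRange halo band width range (min, max) in pixels.
#' @param haloGain peak halo brightness above the background level.
#' @param interiorTextureSD speckle standard deviation inside cells (before
#'   defocus blur).
#' @param backgroundLevel mean background intensity.
#' @param backgroundNoiseSD background noise standard deviation.
#' @param illuminationGradient amplitude of a linear shading ramp across
#'   columns (peak-to-peak fraction of the background level; 0 = none).
#' @param defocusSigma Gaussian blur scale applied last (pixels; 0 = none).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(960, 1280), nCells = 12,
                        radiusRange = c(25, 45), haloWidthRange = c(10, 30),
                        haloGain = 0.35, interiorTextureSD = 0.10,
                        backgroundLevel = 0.45, backgroundNoiseSD = 0.01,
                        illuminationGradient = 0, defocusSigma = 0.8,
                        seed = 0) {
  new("PhantomSpec", shape = as.integer(shape), nCells = as.integer(nCells),
      radiusRange = as.numeric(radiusRange),
      haloWidthRange = as.numeric(haloWidthRange), haloGain = haloGain,
      interiorTextureSD = interiorTextureSD,
      backgroundLevel = backgroundLevel,
      backgroundNoiseSD = backgroundNoiseSD,
      illuminationGradient = illuminationGradient,
      defocusSigma = defocusSigma, seed = as.integer(seed))
}

# evaluate the deformed-disk radius of cell `cell` at polar angles `theta`:
# a disk perturbed by low-order radial harmonics (orders 2..4), giving
# mildly non-convex outlines
.cellRadius <- function(cell, theta) {
  r <- rep(cell$radius, length(theta))
  for (k in 2:4)
    r <- r * (1 + cell$amp[k - 1] * cos(k * theta + cell$phase[k - 1]))
  r
}

#' Generate a synthetic PCM phantom with exact ground truth
#'
#' Cells are placed uniformly at random without overlap (halo band
#' included); placement failure beyond an internal retry budget signals a
#' packing error.  The image is assembled as background + interior speckle
#' + nucleus bump + halo band, optionally shaded and defocus-blurred, and
#' clipped to `[0, 1]`.  The ground-truth mask contains the cell shapes
#' only — the halo band is background, exactly the convention used when
#' scoring a segmentation.  A fluorescence channel with per-cell expression
#' levels (negative / low / high) is included; its background stays below
#' the default AFI positive threshold.
#'
#' The global RNG state is saved and restored; all randomness flows from
#' `spec@seed`, so equal specs give bit-identical bundles.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomBundle-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(spec@seed)

  R <- spec@shape[1]; C <- spec@shape[2]
  n <- spec@nCells
  cells <- list()
  if (n > 0L) {
    attempts <- 0L
    maxAttempts <- 300L * n
    placed <- 0L
    centers <- matrix(0, 0, 2)
    footprints <- numeric(0)
    while (placed < n) {
      radius <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
      halo <- stats::runif(1, spec@haloWidthRange[1], spec@haloWidthRange[2])
      amp <- stats::runif(3, 0, 0.10)
      phase <- stats::runif(3, 0, 2 * pi)
      foot <- radius * (1 + sum(amp)) + halo
      margin <- foot + 2
      repeat {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
          stop("phantom placement failed: cannot fit ", n,
               " cells of this size into a ", R, " x ", C,
               " image without overlap")
        if (margin + 1 >= R - margin || margin + 1 >= C - margin) next
        cy <- stats::runif(1, margin + 1, R - margin)
        cx <- stats::runif(1, margin + 1, C - margin)
        if (placed == 0L ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
                footprints + foot + 2)) break
      }
      placed <- placed + 1L
      centers <- rbind(centers, c(cy, cx))
      footprints <- c(footprints, foot)
      cells[[placed]] <- list(cy = cy, cx = cx, radius = radius,
                              halo = halo, amp = amp, phase = phase)
    }
  }

  img <- matrix(spec@backgroundLevel +
                  stats::rnorm(R * C, 0, spec@backgroundNoiseSD), R, C)
  truth <- matrix(FALSE, R, C)
  fluor <- matrix(0.03, R, C) +
    matrix(abs(stats::rnorm(R * C, 0, 0.008)), R, C)

  exprLevels <- c(negative = 0.05, low = 0.16, high = 0.40)
  for (cell in cells) {
    foot <- cell$radius * 1.35 + cell$halo
    rr <- max(1L, floor(cell$cy - foot)):min(R, ceiling(cell$cy + foot))
    cc <- max(1L, floor(cell$cx - foot)):min(C, ceiling(cell$cx + foot))
    dy <- outer(rr - cell$cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cell$cx)
    d <- sqrt(dy^2 + dx^2)
    th <- atan2(dx, -dy)  # angle convention is immaterial; deterministic
    rEff <- matrix(.cellRadius(cell, as.vector(th)), length(rr), length(cc))
    inside <- d <= rEff
    band <- d > rEff & d <= rEff + cell$halo
    # interior: speckle texture about the background level (low contrast
    # against background in the mean, high local variance)
    nIn <- sum(inside)
    sub <- img[rr, cc]
    sub[inside] <- spec@backgroundLevel +
      stats::rnorm(nIn, 0, spec@interiorTextureSD)
    # halo: raised band, half-cosine profile peaking at the cell edge and
    # decaying to background at the outer rim
    t <- (d[band] - rEff[band]) / cell$halo
    sub[band] <- sub[band] + spec@haloGain * 0.5 * (1 + cos(pi * t))
    # nucleus-like bright bump at the center
    sigN <- max(2, cell$radius / 3)
    sub <- sub + inside * 0.18 * exp(-d^2 / (2 * sigN^2))
    img[rr, cc] <- sub
    truth[rr, cc] <- truth[rr, cc] | inside
    lvl <- exprLevels[[sample.int(3L, 1L)]]
    fsub <- fluor[rr, cc]
    fsub[inside] <- lvl + stats::rnorm(nIn, 0, 0.012)
    fluor[rr, cc] <- fsub
  }

  if (spec@illuminationGradient != 0) {
    ramp <- spec@illuminationGradient * spec@backgroundLevel *
      (matrix(rep(seq_len(C), each = R), R, C) / C - 0.5)
    img <- img + ramp
  }
  if (spec@defocusSigma > 0) {
    k <- gaussKernel(spec@defocusSigma)
    img <- corrSep(img, k, k)
  }
  img <- pmin(pmax(img, 0), 1)
  fluor <- pmin(pmax(fluor, 0), 1)

  centerPix <- if (length(cells))
    cbind(row = as.integer(round(vapply(cells, `[[`, 0, "cy"))),
          col = as.integer(round(vapply(cells, `[[`, 0, "cx"))))
  else matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  new("PhantomBundle", image = img, truthMask = truth, centers = centerPix,
      fluor = fluor, spec = spec)
}

#' Generate a series of phantoms with planted cell counts
#'
#' One bundle per (count, seed) pair, sharing all other fields of the base
#' specification.  Used for density-calibration studies where the planted
#' count plays the role of the measured cell density.
#'
#' @param baseSpec a [PhantomSpec-class] providing all fields except
#'   `nCells` and `seed`.
#' @param nCellsList integer vector of planted counts.
#' @param seeds integer vector of seeds, same length.
#' @return list of [PhantomBundle-class] objects.
#' @export
generateSeries <- function(baseSpec, nCellsList, seeds) {
  stopifnot(is(baseSpec, "PhantomSpec"))
  if (length(nCellsList) != length(seeds))
    stop("'nCellsList' and 'seeds' must have equal length")
  lapply(seq_along(nCellsList), function(i) {
    s <- baseSpec
    s@nCells <- as.integer(nCellsList[i])
    s@seed <- as.integer(seeds[i])
    generatePhantom(s)
  })
}
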