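# Independent oracles and shared fixtures, kept deliberately naive: direct
# sliding-window and pairwise computations that do not share code paths with
# the package internals.

# brute-force local contrast: for every pixel, extract the full window from a
# replicate-padded copy and compute the weighted std / mean directly
bruteLocalContrast <- function(I, sigma, muFloor = 1e-6) {
  h <- max(1L, ceiling(4 * sigma))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  W <- outer(g, g)
  R <- nrow(I); C <- ncol(I)
  P <- I[c(rep(1, h), 1:R, rep(R, h)), c(rep(1, h), 1:C, rep(C, h))]
  out <- matrix(0, R, C)
  for (r in 1:R) for (c in 1:C) {
    win <- P[r:(r + 2 * h), c:(c + 2 * h)]
    mu <- sum(W * win)
    v <- max(sum(W * win^2) - mu^2, 0)
    out[r, c] <- if (mu > muFloor) sqrt(v) / mu else 0
  }
  out
}

# brute-force mean nearest-centroid distance: O(pixels x centroids)
bruteMeanCentroidDistance <- function(centroids, shape) {
  total <- 0
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2]))
    total <- total + min(sqrt((centroids[, 1] - r)^2 +
                              (centroids[, 2] - c)^2))
  total / prod(shape)
}

# brute-force metrics from raw pixel vectors
bruteMetrics <- function(pred, truth) {
  p <- as.vector(pred); t <- as.vector(truth)
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(accuracy = (tp + tn) / length(p),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0)
}

# rasterized disk mask of radius r centred in a square image
diskMask <- function(r, pad = 6L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  d <= r
}

# mean distance from the boundary pixels of `mask` to the boundary of `truth`
meanBoundaryDisplacement <- function(mask, truth) {
  boundaryOf <- function(m) {
    R <- nrow(m); C <- ncol(m)
    pad <- matrix(FALSE, R + 2L, C + 2L)
    pad[2:(R + 1L), 2:(C + 1L)] <- m
    inner <- pad[1:R, 2:(C + 1L)] & pad[3:(R + 2L), 2:(C + 1L)] &
      pad[2:(R + 1L), 1:C] & pad[2:(R + 1L), 3:(C + 2L)]
    m & !inner
  }
  bm <- boundaryOf(mask); bt <- boundaryOf(truth)
  if (!any(bm) || !any(bt)) return(NA_real_)
  dt <- EBImage::distmap(matrix(as.numeric(!bt), nrow(bt), ncol(bt)))
  mean(dt[bm])
}

# study conditions of the standard segmentation phantom suite: 20 fields with
# colony-sized cells and the full 10-30 px halo width range
standardSuiteBundle <- function(i)
  generatePhantom(phantomSpec(shape = c(512, 512), nCells = 5,
                              radiusRange = c(25, 45),
                              haloWidthRange = c(10, 30), seed = i))

# segmentation parameters used by the suite: defaults except (a) the halo
# removal budget, which must exceed the geometric halo area fraction (up to
# ~0.8 for these radii and widths), and (b) the hole-fill bound, raised to
# colony scale so that enclosed sub-threshold rings at the halo crest are
# filled before correction (still below the smallest cell footprint scale)
suiteParams <- function(...) segParams(fMax = 2500, aRatio = 0.85, ...)

# study conditions of the density series: 12 fields of small cells at
# planted counts spanning 10-400
densitySeries <- function(seedBase = 0L) {
  counts <- round(seq(10, 400, length.out = 12))
  base <- phantomSpec(shape = c(720, 960), radiusRange = c(4, 7),
                      haloWidthRange = c(6, 9), seed = 0)
  list(counts = counts,
       bundles = generateSeries(base, counts, seeds = seedBase + seq_len(12)))
}

densityParams <- function() segParams(fMax = 30, rMax = 30, aRatio = 0.85)
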