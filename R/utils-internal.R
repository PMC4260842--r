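# Internal raster utilities: replicate-padded correlation and connected
# component labelling.  Kernels are applied as correlations (no flip); all
# user-facing kernels are either symmetric or defined directly in correlation
# orientation.

# 1-D correlation along rows (k applied down the row index), replicate padding
corrRows <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  R <- nrow(m)
  mp <- m[c(rep(1L, h), seq_len(R), rep(R, h)), , drop = FALSE]
  out <- matrix(0, R, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[seq_len(R) + (i - 1L), , drop = FALSE]
  out
}

corrCols <- function(m, k) t(corrRows(t(m), k))

# separable correlation: kr down rows, kc across columns
corrSep <- function(m, kr, kc) corrCols(corrRows(m, kr), kc)

# full 3x3 correlation with replicate padding; k is a 3x3 matrix whose row 1
# corresponds to the row above (north of) the output pixel
corr3x3 <- function(m, k) {
  R <- nrow(m); C <- ncol(m)
  mp <- m[c(1L, seq_len(R), R), c(1L, seq_len(C), C), drop = FALSE]
  out <- matrix(0, R, C)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + k[dr + 1L, dc + 1L] *
      mp[seq_len(R) + dr, seq_len(C) + dc, drop = FALSE]
  out
}

# unit-sum sampled Gaussian, truncated at 4*sigma
gaussKernel <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# sampled Gaussian derivative kernels of order 0..2 (analytic derivatives of
# the unit-sum sampled Gaussian)
gaussDerivKernels <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  x <- seq(-h, h)
  g0 <- exp(-x^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  list(g0 = g0,
       g1 = g0 * (-x / sigma^2),
       g2 = g0 * ((x^2 - sigma^2) / sigma^4))
}

# connected component labelling of a logical matrix.  EBImage::bwlabel is
# 4-connected; for 8-connectivity, labels that touch diagonally are merged
# with a union-find pass.
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n < 2L) return(lab)
  R <- nrow(lab); C <- ncol(lab)
  dr <- lab[-R, -C]; se <- lab[-1, -1]   # down-right diagonal neighbours
  ne <- lab[-R, -1]; sw <- lab[-1, -C]   # down-left diagonal neighbours
  pairs <- rbind(cbind(as.vector(dr), as.vector(se)),
                 cbind(as.vector(ne), as.vector(sw)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- findRoot(pairs[r, 1]); b <- findRoot(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# component areas as a vector indexed by label
componentAreas <- function(lab) tabulate(lab[lab > 0L], nbins = max(lab, 1L))

# labels of components touching the image border
borderLabels <- function(lab) {
  R <- nrow(lab); C <- ncol(lab)
  b <- c(lab[1, ], lab[R, ], lab[, 1], lab[, C])
  sort(unique(b[b > 0L]))
}

checkMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg))
  if (any(dim(mask) < 1L)) stop(sprintf("'%s' must be non-empty", arg))
  invisible(mask)
}

checkGray <- function(I, arg = "I") {
  if (!is.matrix(I) || !is.numeric(I))
    stop(sprintf("'%s' must be a numeric matrix", arg))
  if (any(!is.finite(I)) || any(I < 0) || any(I > 1))
    stop(sprintf("'%s' must contain finite intensities in [0, 1]", arg))
  invisible(I)
}

sameShape <- function(a, b, na = "first", nb = "second") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s and %s inputs must have the same shape", na, nb))
  invisible(TRUE)
}
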