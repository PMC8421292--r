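# Low-level array utilities: separable convolution (FFT and direct),
# mirror padding, pyramid decimation, binary erosion, Euclidean distance
# transform. All operate on plain 3D arrays in voxel units.

.mirrorIndices <- function(n, pad) {
  # reflect about the edge sample (edge not duplicated): c b | a b c ... y | z y
  if (n == 1L) return(rep(1L, n + 2L * pad))
  if (n > pad) {
    left <- (pad + 1L):2L
    right <- (n - 1L):(n - pad)
  } else {
    # axis shorter than the pad: tile the reflected sequence
    period <- c(seq_len(n), (n - 1L):2L)
    wrap <- function(k) period[(k - 1L) %% length(period) + 1L]
    left <- wrap((1L - pad):0L)
    right <- wrap(n + seq_len(pad))
  }
  c(left, seq_len(n), right)
}

.padMirror1 <- function(a, axis, pad) {
  # mirror-pad a 3D array along one axis
  idx <- .mirrorIndices(dim(a)[axis], pad)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

.axisFirst <- function(a, axis) {
  if (axis == 1L) a else aperm(a, switch(axis, NULL, c(2L, 1L, 3L), c(3L, 1L, 2L)))
}

.axisBack <- function(a, axis) {
  if (axis == 1L) a else aperm(a, switch(axis, NULL, c(2L, 1L, 3L), c(2L, 3L, 1L)))
}

#' Separable 1D convolution along one axis of a 3D array
#'
#' Convolves with a short symmetric/antisymmetric kernel whose taps are at
#' offsets \code{-(p) .. p} (odd length). Boundaries are mirror-padded
#' (reflection about the edge sample). The FFT path pads before transforming
#' so circular wrap-around never touches the interior, and matches the direct
#' spatial path to floating-point accuracy.
#'
#' @param a 3D numeric array.
#' @param kernel odd-length numeric kernel, taps at offsets -p..p.
#' @param axis 1, 2 or 3.
#' @param method "fft" (default) or "direct".
#' @return array of the same dimension, \code{out(x) = sum_m k(m) a(x - m)}.
#' @export
convolveAxis <- function(a, kernel, axis, method = c("fft", "direct")) {
  method <- match.arg(method)
  nk <- length(kernel)
  stopifnot(nk %% 2L == 1L)
  p <- (nk - 1L) %/% 2L
  if (p == 0L) return(a * kernel)
  d <- dim(a)
  ap <- .padMirror1(a, axis, p)
  ap <- .axisFirst(ap, axis)
  m <- dim(ap)[1L]
  dimp <- dim(ap)
  dim(ap) <- c(m, prod(dimp[2:3]))
  if (method == "fft") {
    kc <- numeric(m)
    for (off in -p:p) kc[(off %% m) + 1L] <- kernel[off + p + 1L]
    out <- Re(mvfft(mvfft(ap) * as.vector(fft(kc)), inverse = TRUE)) / m
  } else {
    out <- matrix(0, m, ncol(ap))
    for (off in -p:p) {
      k <- kernel[off + p + 1L]
      if (k == 0) next
      src <- seq_len(m) - off
      src <- pmin(pmax(src, 1L), m)   # only central rows are kept below
      out <- out + k * ap[src, , drop = FALSE]
    }
  }
  dim(out) <- dimp
  out <- out[(p + 1L):(m - p), , , drop = FALSE]
  .axisBack(out, axis)
}

#' Pyramid extent arithmetic
#'
#' Extent of a grid axis after \code{levels} resolution doublings: per level
#' the extent halves with round-half-to-even arithmetic, which reproduces the
#' 731 x 665 x 532 to 183 x 166 x 133 mapping of a two-level pyramid.
#'
#' @param n integer vector of axis extents.
#' @param levels number of doublings (>= 0).
#' @return integer vector of coarse extents.
#' @examples pyramidDim(c(731, 665, 532), 2)
#' @export
pyramidDim <- function(n, levels) {
  stopifnot(levels >= 0)
  n <- as.numeric(n)
  for (i in seq_len(levels)) {
    n <- round(n / 2)
    if (any(n < 1)) stop("pyramid level reduces an axis below one voxel")
  }
  as.integer(n)
}

.decimateIndices <- function(n) {
  m <- as.integer(round(n / 2))
  seq(1L, by = 2L, length.out = m)   # even 0-based indices, first m kept
}

#' Decimate a 3D array consistently with the binomial pyramid
#'
#' Keeps the samples at even (0-based) indices that the resolution pyramid
#' retains, so masks, depth and label maps computed at fine resolution can be
#' transported to the coarse tensor grid. No filtering is applied (intended
#' for masks and slowly varying fields).
#'
#' @param a 3D array. @param levels number of doublings.
#' @return decimated array with extents \code{pyramidDim(dim(a), levels)}.
#' @export
decimateArray <- function(a, levels) {
  for (i in seq_len(levels)) {
    a <- a[.decimateIndices(dim(a)[1]),
           .decimateIndices(dim(a)[2]),
           .decimateIndices(dim(a)[3]), drop = FALSE]
  }
  a
}

#' Binary erosion with the 6-connected cross
#'
#' @param mask logical 3D array.
#' @param steps number of one-voxel erosions.
#' @return eroded logical array.
#' @export
erodeMask <- function(mask, steps = 1L) {
  d <- dim(mask)
  shift <- function(m, axis, by) {
    idx <- seq_len(d[axis]) + by
    pad <- idx < 1L | idx > d[axis]
    idx[pad] <- 1L
    out <- switch(axis, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                  m[, , idx, drop = FALSE])
    # out-of-range neighbours count as background
    if (any(pad)) {
      sel <- which(pad)
      if (axis == 1L) out[sel, , ] <- FALSE
      if (axis == 2L) out[, sel, ] <- FALSE
      if (axis == 3L) out[, , sel] <- FALSE
    }
    out
  }
  for (s in seq_len(steps)) {
    m <- mask
    for (ax in 1:3) for (by in c(-1L, 1L)) m <- m & shift(mask, ax, by)
    mask <- m
  }
  mask
}

# one lower-envelope (Felzenszwalb) squared-EDT pass along the rows of a
# matrix of 1D problems; f holds squared distances (Inf where no seed yet)
.edt1d <- function(fmat) {
  n <- nrow(fmat); L <- ncol(fmat)
  out <- matrix(Inf, n, L)
  v <- integer(n); zl <- numeric(n + 1L)
  for (l in seq_len(L)) {
    f <- fmat[, l]
    if (!any(is.finite(f))) next
    k <- 1L; v[1] <- 1L; zl[1] <- -Inf; zl[2] <- Inf
    for (q in 2:n) {
      fq <- f[q]
      if (!is.finite(fq)) next
      repeat {
        p <- v[k]
        s <- ((fq + q * q) - (f[p] + p * p)) / (2 * (q - p))
        if (s <= zl[k]) { k <- k - 1L; if (k == 0L) break } else break
      }
      k <- k + 1L
      v[k] <- q; zl[k] <- s; zl[k + 1L] <- Inf
    }
    k2 <- 1L
    for (q in seq_len(n)) {
      while (zl[k2 + 1L] < q) k2 <- k2 + 1L
      p <- v[k2]
      out[q, l] <- (q - p)^2 + f[p]
    }
  }
  out
}

.edt3d <- function(target) {
  d2 <- array(ifelse(target, 0, Inf), dim(target))
  for (axis in 1:3) {
    d2 <- .axisFirst(d2, axis)
    dd <- dim(d2)
    dim(d2) <- c(dd[1L], prod(dd[2:3]))
    d2 <- .edt1d(d2)
    dim(d2) <- dd
    d2 <- .axisBack(d2, axis)
  }
  sqrt(d2)
}

#' Euclidean distance transform to a target region
#'
#' Exact Euclidean distance (separable lower-envelope algorithm, one pass
#' per axis) from every voxel centre to the nearest voxel centre of
#' \code{target}. With \code{upsample > 1} the target mask is replicated
#' onto a finer grid first and the distance at each original voxel centre is
#' read back by averaging the surrounding sub-voxel values: this halves (at
#' \code{upsample = 2}) the staircase quantization of the region boundary,
#' which dominates the error close to a curved surface.
#'
#' @param target logical 3D array of target voxels.
#' @param voxelSize voxel edge length; distances are returned in the same
#'   unit per 1000 (i.e. micrometre spacing yields millimetres).
#' @param upsample integer sub-voxel refinement factor (1 = none).
#' @return numeric 3D array of distances (mm for micrometre spacing).
#' @export
distanceTransform <- function(target, voxelSize = 1000, upsample = 1L) {
  if (!any(target)) stop("distance transform target is empty")
  upsample <- as.integer(upsample)
  h <- voxelSize / 1000
  if (upsample <= 1L) return(.edt3d(target) * h)
  d <- dim(target)
  up <- target[rep(seq_len(d[1]), each = upsample),
               rep(seq_len(d[2]), each = upsample),
               rep(seq_len(d[3]), each = upsample)]
  dist <- .edt3d(up) * (h / upsample)
  # original centre = corner shared by the central sub-voxels: average the
  # surrounding block (the distance field has |gradient| = 1, so the mean of
  # a symmetric neighbourhood is the centre value to first order)
  ctr <- if (upsample %% 2L == 0L)
    c(upsample %/% 2L, upsample %/% 2L + 1L) else (upsample + 1L) %/% 2L
  out <- array(0, d)
  cnt <- 0L
  for (ox in ctr) for (oy in ctr) for (oz in ctr) {
    out <- out + dist[seq(ox, by = upsample, length.out = d[1]),
                      seq(oy, by = upsample, length.out = d[2]),
                      seq(oz, by = upsample, length.out = d[3])]
    cnt <- cnt + 1L
  }
  out / cnt
}

# unit-normalize rows of an n x 3 matrix; rows of ~zero norm become NA
.normalizeRows <- function(m, tol = 1e-12) {
  nrm <- sqrt(rowSums(m^2))
  bad <- !is.finite(nrm) | nrm < tol
  m <- m / nrm
  m[bad, ] <- NA_real_
  m
}

# cross product of rows of two n x 3 matrices
.crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# world coordinates (mm) of voxel centres for a grid
.voxelCoords <- function(dim, voxelSize, origin = c(0, 0, 0)) {
  h <- voxelSize / 1000
  list(x = origin[1] + (seq_len(dim[1]) - 1) * h,
       y = origin[2] + (seq_len(dim[2]) - 1) * h,
       z = origin[3] + (seq_len(dim[3]) - 1) * h)
}
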