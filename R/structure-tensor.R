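# Structure-tensor imaging branch: matched 5-tap derivative templates,
# 3D intensity gradients by separable (FFT) convolution, gradient outer
# products, binomial resolution pyramid, eigenanalysis with the laminar
# role convention, and intensity masking.

# Interpolator-matched 5-tap pair (Farid & Simoncelli optimal 5-tap design).
# The derivative taps are rescaled so the template is exact on linear ramps
# (unit response to I = x in voxel units); the prefilter is normalized to
# unit DC gain. Offsets run -2..+2.
.FS_PREFILTER <- local({
  p <- c(0.037659, 0.249153, 0.426375, 0.249153, 0.037659)
  p / sum(p)
})
.FS_DERIV <- local({
  d <- c(-0.109604, -0.276691, 0, 0.276691, 0.109604)
  # convolution response to a ramp is -sum(m * d(m)); force it to 1
  d / -sum((-2:2) * d)
})

#' Matched 5-tap derivative and prefilter kernels
#'
#' Returns the separable pair from which the 5 x 5 x 5 derivative template is
#' assembled: an antisymmetric 5-tap derivative (taps sum to zero, exact unit
#' response on linear ramps) and a symmetric 5-tap smoothing prefilter (unit
#' DC gain). The 3D derivative along axis k applies the derivative kernel on
#' axis k and the prefilter on the two remaining axes; at 150 um voxels the
#' template footprint spans a 750 x 750 x 750 um neighbourhood.
#'
#' @return list with elements \code{derivative} and \code{prefilter}
#'   (numeric length 5, taps at offsets -2..2).
#' @examples
#' k <- derivativeTemplates()
#' sum(k$derivative)   # 0: a constant image has zero derivative
#' sum(k$prefilter)    # 1: smoothing preserves the mean
#' @export
derivativeTemplates <- function() {
  list(derivative = .FS_DERIV, prefilter = .FS_PREFILTER)
}

#' 3D intensity gradient via the separable 5 x 5 x 5 template
#'
#' Each gradient component is the response of the matched derivative template
#' (derivative kernel along its own axis, prefilter along the other two),
#' computed by 1D FFT convolution with mirror boundary padding. Units are
#' intensity per voxel; increasing array index is the positive direction.
#'
#' @param vol a \linkS4class{ScalarVolume} (every axis at least 5 voxels).
#' @param method "fft" (default) or "direct" (spatial-domain reference path).
#' @return 4D array (nx, ny, nz, 3) of gradient components.
#' @export
imageGradient <- function(vol, method = c("fft", "direct")) {
  method <- match.arg(method)
  a <- values3d(vol)
  if (any(dim(a) < 5L))
    stop("imageGradient requires at least 5 voxels along every axis")
  k <- derivativeTemplates()
  g <- array(0, c(dim(a), 3L))
  for (axis in 1:3) {
    comp <- a
    for (ax2 in 1:3) {
      kern <- if (ax2 == axis) k$derivative else k$prefilter
      comp <- convolveAxis(comp, kern, ax2, method = method)
    }
    g[, , , axis] <- comp
  }
  g
}

#' Per-voxel structure tensor from a gradient field
#'
#' The structure tensor is the outer product of the intensity gradient with
#' itself, T = g g'; before any smoothing it is rank one with trace |g|^2.
#'
#' @param grad 4D array (nx, ny, nz, 3) as returned by
#'   \code{\link{imageGradient}}.
#' @param voxelSize micrometres. @param origin mm triple.
#' @return a \linkS4class{TensorField}.
#' @export
structureTensorField <- function(grad, voxelSize, origin = c(0, 0, 0)) {
  d <- dim(grad)
  stopifnot(length(d) == 4L, d[4L] == 3L)
  gx <- grad[, , , 1]; gy <- grad[, , , 2]; gz <- grad[, , , 3]
  comps <- array(0, c(d[1:3], 6L))
  comps[, , , 1] <- gx * gx
  comps[, , , 2] <- gy * gy
  comps[, , , 3] <- gz * gz
  comps[, , , 4] <- gx * gy
  comps[, , , 5] <- gx * gz
  comps[, , , 6] <- gy * gz
  TensorField(comps, voxelSize, origin)
}

.BINOMIAL4 <- c(1, 4, 6, 4, 1) / 16

#' Binomial resolution pyramid for tensor fields
#'
#' Per resolution doubling, every tensor component is convolved separably
#' with the order-4 binomial low-pass kernel (1,4,6,4,1)/16 (mirror
#' boundaries) and decimated by two per axis; the voxel size doubles and the
#' axis extent follows \code{\link{pyramidDim}}. Two levels take a 150 um
#' tensor grid to the 600 um analysis resolution. Positive semi-definiteness
#' is preserved (the kernel is a convex average).
#'
#' @param tensors a \linkS4class{TensorField}.
#' @param levels number of resolution doublings (>= 0).
#' @return a \linkS4class{TensorField} at the coarser resolution.
#' @export
binomialPyramid <- function(tensors, levels) {
  stopifnot(levels >= 0)
  comps <- tensorComps(tensors)
  vs <- voxelSize(tensors)
  org <- origin(tensors)
  for (lev in seq_len(levels)) {
    d <- dim(comps)[1:3]
    if (any(round(d / 2) < 1)) stop("pyramid level reduces an axis below one voxel")
    dn <- as.integer(round(d / 2))
    out <- array(0, c(dn, 6L))
    for (cc in 1:6) {
      a <- comps[, , , cc]
      for (ax in 1:3) a <- convolveAxis(a, .BINOMIAL4, ax)
      out[, , , cc] <- a[.decimateIndices(d[1]), .decimateIndices(d[2]),
                         .decimateIndices(d[3]), drop = FALSE]
    }
    comps <- out
    vs <- vs * 2
  }
  TensorField(comps, vs, org)
}

# symmetric 3x3 eigen-decomposition for masked voxels of a component array;
# returns values (n x 3 descending), vectors (n x 3 x 3), degenerate flag
.eigSymMasked <- function(comps, idx) {
  n <- length(idx)
  vals <- matrix(NA_real_, n, 3)
  vecs <- array(NA_real_, c(n, 3, 3))
  degen <- logical(n)
  m <- matrix(0, 3, 3)
  flat <- matrix(comps, ncol = 6L)
  for (i in seq_len(n)) {
    v6 <- flat[idx[i], ]
    if (any(!is.finite(v6))) next
    m[1, 1] <- v6[1]; m[2, 2] <- v6[2]; m[3, 3] <- v6[3]
    m[1, 2] <- m[2, 1] <- v6[4]
    m[1, 3] <- m[3, 1] <- v6[5]
    m[2, 3] <- m[3, 2] <- v6[6]
    e <- eigen(m, symmetric = TRUE)      # descending eigenvalues
    vals[i, ] <- e$values
    V <- e$vectors
    # deterministic sign: positive z, then x, then y component
    for (j in 1:3) {
      v <- V[, j]
      s <- if (abs(v[3]) > 1e-6) sign(v[3]) else
           if (abs(v[1]) > 1e-6) sign(v[1]) else sign(v[2] + (v[2] == 0))
      V[, j] <- v * s
    }
    vecs[i, , ] <- V
    scale <- max(abs(e$values[1]), .Machine$double.xmin)
    degen[i] <- (e$values[1] - e$values[3]) / scale < 1e-6
  }
  list(values = vals, vectors = vecs, degenerate = degen)
}

.eigenFieldFrom <- function(tensors, mask, roles) {
  comps <- tensorComps(tensors)
  d <- dim(comps)[1:3]
  if (!identical(dim(mask), d))
    stop("mask grid does not match the tensor grid")
  idx <- which(mask)
  eg <- .eigSymMasked(comps, idx)
  nonfinite <- sum(is.na(eg$values[, 1]))
  if (nonfinite > 0)
    message(sprintf("eigenanalysis: %d masked voxels had non-finite tensors and were dropped",
                    nonfinite))
  values <- array(NA_real_, c(d, 3L))
  vectors <- array(NA_real_, c(d, 3L, 3L))
  degenerate <- array(FALSE, d)
  nvox <- prod(d)
  for (j in 1:3) {
    tmp <- array(NA_real_, d)
    tmp[idx] <- eg$values[, j]
    values[, , , j] <- tmp
    for (cc in 1:3) {
      tmp <- array(NA_real_, d)
      tmp[idx] <- eg$vectors[, cc, j]
      vectors[, , , cc, j] <- tmp
    }
  }
  degenerate[idx] <- eg$degenerate
  new("EigenField", values = values, vectors = vectors,
      roles = roles, degenerate = degenerate,
      voxelSize = voxelSize(tensors), origin = origin(tensors))
}

#' Eigenanalysis of a structure-tensor field (STI role convention)
#'
#' Decomposes each masked tensor; eigenvalues are sorted descending and the
#' STI anatomical convention is applied: the first eigenvector (largest
#' eigenvalue, direction of strongest intensity variation) is the
#' sheetlet/lamina normal, the second the sheet-in-plane direction, and the
#' third (least intensity variation) the myocyte (fiber) orientation. Voxels
#' with relative eigenvalue gap (l1 - l3)/l1 < 1e-6 are flagged degenerate;
#' unmasked or non-finite voxels carry NA.
#'
#' @param tensors a \linkS4class{TensorField} (smoothed structure tensors).
#' @param mask logical 3D array on the same grid.
#' @return an \linkS4class{EigenField} with roles
#'   \code{sheetNormal = 1, sheetInPlane = 2, fiber = 3}.
#' @export
stEigenanalysis <- function(tensors, mask) {
  .eigenFieldFrom(tensors, mask,
                  c(fiber = 3L, sheetInPlane = 2L, sheetNormal = 1L))
}

#' Intensity-threshold binary mask
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param low,high inclusive cutoffs (low < high).
#' @return logical 3D array; the retained voxel count is reported via
#'   \code{message}, and an empty mask raises a warning.
#' @export
intensityMask <- function(vol, low, high) {
  stopifnot(low < high)
  v <- values3d(vol)
  mask <- !is.na(v) & v >= low & v <= high
  message(sprintf("intensityMask: retained %d of %d voxels",
                  sum(mask), length(mask)))
  if (!any(mask)) warning("intensityMask: mask is empty")
  mask
}
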