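# Diffusion-tensor branch: log-linear least-squares tensor fit from b0 +
# multi-direction DWI, FA/trace scalar maps, eigenanalysis with the DTI role
# convention, and the FA/trace/intensity tissue mask.

# design row for direction g and b value: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
.dtiDesign <- function(gradients, bvalues) {
  w <- bvalues > 0
  g <- gradients[w, , drop = FALSE]
  b <- bvalues[w]
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  X <- X * b
  sv <- svd(X)
  if (min(sv$d) < max(sv$d) * 1e-10)
    stop("gradient scheme is rank-deficient: the six tensor components are not identifiable")
  list(X = X, weighted = w)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Multiple b0 volumes are averaged arithmetically; for each masked voxel the
#' model \eqn{\ln(S_g/\bar S_0) = -b\, g' D g} is solved for the six unique
#' components of the symmetric tensor D by ordinary least squares over the
#' weighted volumes. Voxels with any non-positive signal are excluded (NA)
#' and counted in a message. Negative eigenvalues are never clamped; they
#' surface in \code{\link{dtiScalars}} and the degenerate flags downstream.
#'
#' @param dwi a \linkS4class{DWISet}.
#' @param mask logical 3D array (default: all voxels).
#' @return a \linkS4class{TensorField} in mm^2/s.
#' @export
fitDTI <- function(dwi, mask = NULL) {
  d <- gridDim(dwi)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask grid does not match the DWI grid")
  des <- .dtiDesign(dwi@gradients, dwi@bvalues)
  vol <- dwi@volumes
  nb0 <- which(!des$weighted)
  s0 <- apply(vol[, , , nb0, drop = FALSE], 1:3, mean)
  idx <- which(mask)
  nw <- sum(des$weighted)
  S <- matrix(0, nw, length(idx))
  wi <- which(des$weighted)
  for (k in seq_along(wi)) S[k, ] <- vol[, , , wi[k]][idx]
  ok <- s0[idx] > 0 & colSums(S <= 0) == 0L
  nbad <- sum(!ok)
  if (nbad > 0)
    message(sprintf("fitDTI: %d masked voxels had non-positive signal and were excluded",
                    nbad))
  Y <- -log(sweep(S[, ok, drop = FALSE], 2, s0[idx][ok], `/`))
  beta <- qr.solve(des$X, Y)           # 6 x n
  comps <- array(NA_real_, c(d, 6L))
  for (cc in 1:6) {
    tmp <- array(NA_real_, d)
    tmp[idx[ok]] <- beta[cc, ]
    comps[, , , cc] <- tmp
  }
  TensorField(comps, voxelSize(dwi), origin(dwi))
}

#' Fractional anisotropy and trace maps
#'
#' trace = l1 + l2 + l3;
#' FA = sqrt(3/2) * sqrt(sum((li - lbar)^2)) / sqrt(sum(li^2)), defined as 0
#' for the zero tensor. Both are rotation invariants of the tensor.
#'
#' @param tensor a \linkS4class{TensorField} (diffusion tensors, mm^2/s).
#' @return list of two \linkS4class{ScalarVolume}s, \code{FA} and
#'   \code{trace}.
#' @export
dtiScalars <- function(tensor) {
  comps <- tensorComps(tensor)
  d <- dim(comps)[1:3]
  idx <- which(apply(is.finite(comps), 1:3, all))
  eg <- .eigSymMasked(comps, idx)
  tr <- array(NA_real_, d)
  fa <- array(NA_real_, d)
  lam <- eg$values
  tr[idx] <- rowSums(lam)
  lbar <- rowSums(lam) / 3
  num <- rowSums((lam - lbar)^2)
  den <- rowSums(lam^2)
  f <- sqrt(1.5 * num / den)
  f[den == 0] <- 0
  fa[idx] <- f
  list(FA = ScalarVolume(fa, voxelSize(tensor), origin(tensor)),
       trace = ScalarVolume(tr, voxelSize(tensor), origin(tensor)))
}

#' Eigenanalysis of a diffusion-tensor field (DTI role convention)
#'
#' As \code{\link{stEigenanalysis}} but with the DTI anatomical convention:
#' the first eigenvector (largest diffusivity) is the myocyte (fiber)
#' orientation, the second the sheet-in-plane direction, and the third
#' (smallest diffusivity) the sheet normal.
#'
#' @param tensor a \linkS4class{TensorField}.
#' @param mask logical 3D array on the same grid.
#' @return an \linkS4class{EigenField} with roles
#'   \code{fiber = 1, sheetInPlane = 2, sheetNormal = 3}.
#' @export
dtiEigenanalysis <- function(tensor, mask) {
  .eigenFieldFrom(tensor, mask,
                  c(fiber = 1L, sheetInPlane = 2L, sheetNormal = 3L))
}

#' Tissue mask from FA, trace and b0 intensity cutoffs
#'
#' A voxel is retained iff all three channels lie within their inclusive
#' [low, high] windows. Cutoff values are study-specific configuration; the
#' defaults admit everything.
#'
#' @param scalars list with \code{FA} and \code{trace}
#'   (\code{\link{dtiScalars}} output).
#' @param b0 a \linkS4class{ScalarVolume} (mean or first b0).
#' @param faCutoffs,traceCutoffs,b0Cutoffs numeric length-2 (low, high).
#' @return logical 3D array; empty masks raise a warning.
#' @export
dtiMask <- function(scalars, b0,
                    faCutoffs = c(-Inf, Inf),
                    traceCutoffs = c(-Inf, Inf),
                    b0Cutoffs = c(-Inf, Inf)) {
  for (cut in list(faCutoffs, traceCutoffs, b0Cutoffs))
    stopifnot(length(cut) == 2L, cut[1] < cut[2])
  inWin <- function(v, cut) !is.na(v) & v >= cut[1] & v <= cut[2]
  mask <- inWin(values3d(scalars$FA), faCutoffs) &
          inWin(values3d(scalars$trace), traceCutoffs) &
          inWin(values3d(b0), b0Cutoffs)
  message(sprintf("dtiMask: retained %d of %d voxels", sum(mask), length(mask)))
  if (!any(mask)) warning("dtiMask: mask is empty")
  mask
}
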