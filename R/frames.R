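# Cardiac coordinate frames and architecture angles. The frame at each voxel
# is (circumferential, longitudinal, radial): long = the LV long axis (+z
# toward the base after alignment), radial = outward in-plane unit vector
# from the per-slice cavity centroid, circ = long x radial. Angles are
# computed with the principal-value arctangent of component ratios (axial
# quantities with a 180 deg period), wrapped into [-90, 90] degrees.
#
# Sign conventions (documented, fixed): HA > 0 when the tangent-plane
# projection of the fiber tilts toward +long (the base); TA > 0 when it
# tilts outward (+radial); SE > 0 toward +long; SA > 0 toward +circ. The
# pole case (zero reference component) is canonicalized to +90.

.ANGLE_EPS <- 1e-9

.axialAngle <- function(num, den) {
  # principal-value atan(num/den) in degrees, pole canonicalized to +90,
  # undefined (both ~0) -> NA
  out <- atan(num / den) * 180 / pi
  pole <- abs(den) < .ANGLE_EPS
  out[pole] <- 90
  out[pole & abs(num) < .ANGLE_EPS] <- NA_real_
  out
}

#' Helix and transverse angles of a fiber vector
#'
#' With components (c, l, r) of the (axial) fiber vector in the local frame:
#' HA = atan(l/c) is the angle between the short-axis plane and the fiber's
#' projection onto the wall tangent plane; TA = atan(r/c) the angle between
#' the tangent plane and the projection onto the short-axis plane. Both lie
#' in [-90, 90] degrees and are invariant under v -> -v.
#'
#' @param v n x 3 matrix of unit vectors (world coordinates).
#' @param frame a \linkS4class{FrameField} flattened to the same n voxels,
#'   or a list with n x 3 matrices \code{circ}, \code{long}, \code{radial}.
#' @return data.frame with columns HA and TA (degrees; NA where the frame is
#'   invalid or the angle undefined).
#' @export
fiberAngles <- function(v, frame) {
  fr <- .frameMatrices(frame)
  v <- matrix(v, ncol = 3)
  cc <- rowSums(v * fr$circ)
  ll <- rowSums(v * fr$long)
  rr <- rowSums(v * fr$radial)
  data.frame(HA = .axialAngle(ll, cc), TA = .axialAngle(rr, cc))
}

#' Sheetlet elevation and azimuth angles of a sheet-normal vector
#'
#' With components (c, l, r) of the sheet-normal vector in the local frame:
#' SE = atan(l/r) is the elevation of its projection onto the
#' radial-longitudinal plane above the short-axis plane; SA = atan(c/r) the
#' in-plane deviation of its short-axis projection from the radial direction.
#'
#' @inheritParams fiberAngles
#' @return data.frame with columns SE and SA (degrees).
#' @export
sheetAngles <- function(v, frame) {
  fr <- .frameMatrices(frame)
  v <- matrix(v, ncol = 3)
  cc <- rowSums(v * fr$circ)
  ll <- rowSums(v * fr$long)
  rr <- rowSums(v * fr$radial)
  data.frame(SE = .axialAngle(ll, rr), SA = .axialAngle(cc, rr))
}

.frameMatrices <- function(frame) {
  if (is(frame, "FrameField"))
    return(list(circ = matrix(frame@circ, ncol = 3),
                long = matrix(frame@long, ncol = 3),
                radial = matrix(frame@radial, ncol = 3)))
  stopifnot(is.list(frame), all(c("circ", "long", "radial") %in% names(frame)))
  frame
}

#' Build per-voxel cardiac frames from the long axis and cavity centroids
#'
#' Assumes the LV long axis is aligned with +z (apply
#' \code{\link{longAxisTransform}} first for real data). The radial vector is
#' the in-plane unit vector from the slice centroid to the voxel, the
#' longitudinal vector is +z, and the circumferential vector is long x
#' radial (right-handed: circ x long = radial). Voxels closer than half a
#' voxel to the centroid get an invalid (NA) frame.
#'
#' @param dim grid shape. @param voxelSize micrometres. @param origin mm.
#' @param centroids either a single (x, y) mm pair used for all slices
#'   (straight axis) or an nz x 2 matrix of per-slice cavity centroids.
#' @return a \linkS4class{FrameField}.
#' @export
buildFrames <- function(dim, voxelSize, origin = c(0, 0, 0),
                        centroids = c(0, 0)) {
  h <- voxelSize / 1000
  cc <- .voxelCoords(dim, voxelSize, origin)
  if (is.null(dim(centroids)))
    centroids <- matrix(centroids, dim[3], 2, byrow = TRUE)
  stopifnot(nrow(centroids) == dim[3])
  nxy <- dim[1] * dim[2]
  x <- rep(cc$x, times = dim[2])            # in-plane voxel coordinates
  y <- rep(cc$y, each = dim[1])
  circ <- array(NA_real_, c(dim, 3L))
  long <- array(0, c(dim, 3L)); long[, , , 3] <- 1
  radial <- array(NA_real_, c(dim, 3L))
  for (k in seq_len(dim[3])) {
    dx <- x - centroids[k, 1]
    dy <- y - centroids[k, 2]
    nrm <- sqrt(dx^2 + dy^2)
    bad <- nrm < h / 2
    rx <- dx / nrm; ry <- dy / nrm
    rx[bad] <- NA_real_; ry[bad] <- NA_real_
    zc <- ifelse(bad, NA_real_, 0)
    radial[, , k, 1] <- rx; radial[, , k, 2] <- ry; radial[, , k, 3] <- zc
    circ[, , k, 1] <- -ry;  circ[, , k, 2] <- rx;   circ[, , k, 3] <- zc
    for (cmp in 1:3) {
      tmp <- long[, , k, cmp]; tmp[bad] <- NA_real_; long[, , k, cmp] <- tmp
    }
  }
  new("FrameField", circ = circ, long = long, radial = radial,
      voxelSize = voxelSize, origin = origin)
}

#' Rigid transform aligning the LV long axis with +z
#'
#' Principal-component analysis of the mask voxel coordinates; the dominant
#' axis is mapped to +z and the centroid to the origin. The apex (the end
#' with the smaller in-plane spread about the axis) is mapped toward -z; an
#' explicit \code{apexToward} overrides the automatic choice. Near-spherical
#' masks (principal-axis anisotropy ratio < 1.2) are rejected: landmarks
#' must then be supplied by the user.
#'
#' @param mask logical 3D array.
#' @param voxelSize micrometres. @param origin mm.
#' @param apexToward optional unit 3-vector: world direction pointing from
#'   base to apex, used to orient the axis instead of the spread heuristic.
#' @return list with \code{rotation} (3 x 3, world -> aligned),
#'   \code{translation} (mm; aligned coords = rotation %*% p + translation),
#'   \code{axis} (unit vector, base direction in world coordinates) and
#'   \code{anisotropy}.
#' @export
longAxisTransform <- function(mask, voxelSize, origin = c(0, 0, 0),
                              apexToward = NULL) {
  stopifnot(any(mask))
  cc <- .voxelCoords(dim(mask), voxelSize, origin)
  idx <- which(mask, arr.ind = TRUE)
  P <- cbind(cc$x[idx[, 1]], cc$y[idx[, 2]], cc$z[idx[, 3]])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  e <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  aniso <- sqrt(e$values[1] / e$values[2])
  if (aniso < 1.2)
    stop("mask is near-spherical (anisotropy ratio ", round(aniso, 3),
         " < 1.2): supply explicit landmarks")
  axis <- e$vectors[, 1]
  proj <- Pc %*% axis
  if (is.null(apexToward)) {
    # apex = smaller-cross-section end; map it to -z
    inplane <- sqrt(rowSums((Pc - proj %*% t(axis))^2))
    spreadPos <- mean(inplane[proj > 0])
    spreadNeg <- mean(inplane[proj < 0])
    if (spreadPos < spreadNeg) axis <- -axis    # put the fat end at +z
  } else {
    if (sum(axis * apexToward) > 0) axis <- -axis
  }
  # rotation taking `axis` to +z (Rodrigues about axis x z)
  zhat <- c(0, 0, 1)
  v <- c(axis[2] * zhat[3] - axis[3] * zhat[2],
         axis[3] * zhat[1] - axis[1] * zhat[3],
         axis[1] * zhat[2] - axis[2] * zhat[1])
  s <- sqrt(sum(v^2)); cth <- sum(axis * zhat)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  list(rotation = R, translation = as.vector(-R %*% ctr), axis = axis,
       anisotropy = aniso)
}

#' Angle maps from an eigen-decomposition and cardiac frames
#'
#' Selects the fiber-role and sheet-normal-role eigenvectors according to
#' the source convention (STI: fiber = third eigenvector, sheet normal =
#' first; DTI: fiber = first, sheet normal = third), then computes HA/TA
#' from the fiber vector and SE/SA from the sheet normal. Output voxels are
#' valid only where both the eigen-decomposition and the frame are.
#'
#' @param eigen an \linkS4class{EigenField}.
#' @param frames a \linkS4class{FrameField} on the same grid.
#' @param roleSource "STI" or "DTI".
#' @param excludeDegenerate drop voxels flagged degenerate (default TRUE).
#' @return an \linkS4class{AngleMaps}.
#' @export
angleMaps <- function(eigen, frames, roleSource = c("STI", "DTI"),
                      excludeDegenerate = TRUE) {
  roleSource <- match.arg(roleSource)
  d <- gridDim(eigen)
  if (!identical(d, gridDim(frames)))
    stop("eigen field and frames are on different grids")
  roles <- if (roleSource == "STI")
    c(fiber = 3L, sheetNormal = 1L) else c(fiber = 1L, sheetNormal = 3L)
  fib <- matrix(eigen@vectors[, , , , roles[["fiber"]]], ncol = 3)
  shn <- matrix(eigen@vectors[, , , , roles[["sheetNormal"]]], ncol = 3)
  ft <- fiberAngles(fib, frames)
  st <- sheetAngles(shn, frames)
  bad <- !is.finite(rowSums(fib))
  if (excludeDegenerate) bad <- bad | as.vector(eigen@degenerate)
  ft[bad, ] <- NA_real_
  st[bad, ] <- NA_real_
  new("AngleMaps",
      HA = array(ft$HA, d), TA = array(ft$TA, d),
      SE = array(st$SE, d), SA = array(st$SA, d),
      voxelSize = voxelSize(eigen), origin = origin(eigen))
}
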