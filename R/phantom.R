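# Synthetic left-ventricle phantom: an annular-cylinder wall (axis = z) with
# a linear transmural helix-angle law, imposed transverse angle and sheet
# tilt, a laminar + striation texture for the STI branch, and tensor-model
# DWI signals with Rician noise for the DTI branch. Both branches are
# co-registered by construction and every recovered quantity has an analytic
# ground truth.

.DUAL_GRADIENT_6 <- matrix(c(
  1,  1, 0,
  1, -1, 0,
  1,  0, 1,
  1,  0, -1,
  0,  1, 1,
  0,  1, -1), ncol = 3, byrow = TRUE) / sqrt(2)

#' Construct a phantom specification
#'
#' Defaults describe the reference validation phantom: a 96^3 grid at 150 um
#' (14.4 mm field of view) holding an annular wall of inner radius 2.4 mm and
#' outer radius 6.0 mm (3.6 mm wall, 24 voxels), helix angle running linearly
#' from +60 deg at the endocardium to -60 deg at the epicardium (slope
#' -120 deg per unit transmural depth), zero transverse angle and untilted
#' laminae (beta = 0). The texture superimposes a laminar cosine (wavelength
#' 600 um) and a weaker sheet-in-plane striation component; DWI uses b =
#' 1000 s/mm^2 with three b0 volumes and the six dual-gradient directions,
#' tensor eigenvalues (1.5, 0.6, 0.4) x 10^-3 mm^2/s on the fiber /
#' sheet-in-plane / sheet-normal axes, and optional Rician noise.
#'
#' @param dim integer length-3 grid shape.
#' @param voxelSize isotropic voxel size, micrometres.
#' @param innerRadius,outerRadius wall radii, mm.
#' @param axialExtent wall extent along z, mm.
#' @param haEndo,haEpi helix angle at depth 0 / 1, degrees, in [-90, 90].
#' @param taConst imposed transverse angle, degrees.
#' @param beta sheet-normal tilt about the fiber axis, degrees (positive
#'   tilts the normal toward +z at zero helix angle).
#' @param betaBimodal if TRUE the tilt is +/-beta with random sign per voxel
#'   (two perpendicular sheet populations).
#' @param textureWavelength laminar texture wavelength, um (>= 2 voxels).
#' @param textureAmplitude laminar cosine amplitude, a.u.
#' @param textureOffset additive wall intensity offset, a.u.
#' @param backgroundIntensity intensity outside the wall, a.u.
#' @param fiberTextureFraction striation RMS amplitude as a fraction of
#'   \code{textureAmplitude} (0 disables the striation component).
#' @param fiberTextureWavelength striation wavelength, um.
#' @param gaborSigmaRadial,gaborSigmaTransverse envelope widths of the
#'   striation kernels, um: narrow across the sheet (radial) so each kernel
#'   stays within one laminar plane, wide within it.
#' @param gaborDensity mean kernels per envelope-volume cell.
#' @param diffusivities length-3, mm^2/s, descending, assigned to fiber /
#'   sheet-in-plane / sheet-normal.
#' @param backgroundDiffusivity isotropic diffusivity outside the wall.
#' @param S0 unweighted signal level, a.u.
#' @param ricianSigma Rician noise sigma, a.u. (0 = noiseless).
#' @param bValue diffusion weighting, s/mm^2.
#' @param directions matrix of unit gradient directions (>= 6 rows).
#' @param nB0 number of b0 volumes.
#' @param dwiLevels DWI grid = phantom grid decimated this many pyramid
#'   levels (2 maps 150 um texture resolution to 600 um DWI resolution).
#' @param rvInsertionAngle reference angle (degrees) for AHA sectorisation.
#' @param seed integer seed driving texture placement and noise.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(dim = c(96L, 96L, 96L), voxelSize = 150,
                        innerRadius = 2.4, outerRadius = 6.0,
                        axialExtent = 13.2,
                        haEndo = 60, haEpi = -60, taConst = 0,
                        beta = 0, betaBimodal = FALSE,
                        textureWavelength = 600, textureAmplitude = 40,
                        textureOffset = 130, backgroundIntensity = 130,
                        fiberTextureFraction = 0.7,
                        fiberTextureWavelength = 450,
                        gaborSigmaRadial = 100, gaborSigmaTransverse = 600,
                        gaborDensity = 3,
                        diffusivities = c(1.5e-3, 0.6e-3, 0.4e-3),
                        backgroundDiffusivity = 2.0e-3,
                        S0 = 100, ricianSigma = 0, bValue = 1000,
                        directions = .DUAL_GRADIENT_6, nB0 = 3L,
                        dwiLevels = 2L, rvInsertionAngle = 0, seed = 1L) {
  new("PhantomSpec",
      dim = as.integer(dim), voxelSize = voxelSize,
      innerRadius = innerRadius, outerRadius = outerRadius,
      axialExtent = axialExtent, haEndo = haEndo, haEpi = haEpi,
      taConst = taConst, beta = beta, betaBimodal = betaBimodal,
      textureWavelength = textureWavelength,
      textureAmplitude = textureAmplitude, textureOffset = textureOffset,
      backgroundIntensity = backgroundIntensity,
      fiberTextureFraction = fiberTextureFraction,
      fiberTextureWavelength = fiberTextureWavelength,
      gaborSigmaRadial = gaborSigmaRadial,
      gaborSigmaTransverse = gaborSigmaTransverse,
      gaborDensity = gaborDensity, diffusivities = diffusivities,
      backgroundDiffusivity = backgroundDiffusivity, S0 = S0,
      ricianSigma = ricianSigma, bValue = bValue,
      directions = directions, nB0 = as.integer(nB0),
      dwiLevels = as.integer(dwiLevels),
      rvInsertionAngle = rvInsertionAngle, seed = as.integer(seed))
}

.phantomOrigin <- function(spec, level = 0L) {
  # grid centred on the cylinder axis; decimation keeps even 0-based indices,
  # so the origin (centre of the first voxel) is level-independent
  h <- spec@voxelSize / 1000
  -(spec@dim - 1) / 2 * h
}

# per-voxel beta (degrees): fixed, or random +/- for the bimodal option
.betaField <- function(spec, n, seedOffset = 17L) {
  if (!spec@betaBimodal) return(rep(spec@beta, n))
  set.seed(spec@seed + seedOffset)
  spec@beta * sample(c(-1, 1), n, replace = TRUE)
}

#' Analytic cardiac frame, fiber and sheet vectors at arbitrary points
#'
#' Evaluates the phantom's ground-truth model at world coordinates (mm):
#' the cardiac frame (circumferential, longitudinal, radial) from the z axis
#' and the radial direction, the normalized transmural depth
#' x = (r - r_in)/(r_out - r_in), the fiber direction with helix angle
#' HA(x) = haEndo + (haEpi - haEndo) x and transverse angle taConst, and the
#' sheet normal: the radial direction (orthogonalized against the fiber)
#' rotated by beta about the fiber axis. Points outside the wall return NA
#' rows.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param points n x 3 matrix of world coordinates, mm.
#' @param betaDeg optional per-point sheet tilt override (degrees).
#' @return list with n x 3 matrices \code{circ}, \code{long}, \code{radial},
#'   \code{fiber}, \code{sheetNormal}, \code{sheetInPlane}, vector
#'   \code{depth}, and logical \code{inside}.
#' @export
analyticFrameAndFibers <- function(spec, points, betaDeg = NULL) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  r <- sqrt(x^2 + y^2)
  inside <- r >= spec@innerRadius & r <= spec@outerRadius &
            abs(z) <= spec@axialExtent / 2 & r > 1e-9
  depth <- (r - spec@innerRadius) / (spec@outerRadius - spec@innerRadius)
  radial <- cbind(x / r, y / r, 0)
  long <- cbind(0 * r, 0 * r, 1 + 0 * r)
  circ <- .crossRows(long, radial)            # (-y, x, 0)/r
  ha <- (spec@haEndo + (spec@haEpi - spec@haEndo) * depth) * pi / 180
  ta <- spec@taConst * pi / 180
  # components chosen so atan(l/c) = HA and atan(r/c) = TA exactly
  fc <- cos(ha); fl <- sin(ha); fr <- tan(ta) * cos(ha)
  fiber <- .normalizeRows(circ * fc + long * fl + radial * fr)
  if (is.null(betaDeg)) betaDeg <- .betaField(spec, n)
  b <- betaDeg * pi / 180
  dotrf <- rowSums(radial * fiber)
  s0 <- .normalizeRows(radial - fiber * dotrf)
  sheetNormal <- s0 * cos(b) + .crossRows(s0, fiber) * sin(b)
  sheetInPlane <- .crossRows(sheetNormal, fiber)
  out <- list(circ = circ, long = long, radial = radial, fiber = fiber,
              sheetNormal = sheetNormal, sheetInPlane = sheetInPlane,
              depth = depth, inside = inside)
  for (nm in c("circ", "long", "radial", "fiber", "sheetNormal",
               "sheetInPlane"))
    out[[nm]][!inside, ] <- NA_real_
  out$depth[!inside] <- NA_real_
  out
}

.analyticAngles <- function(haDeg, taDeg, betaDeg) {
  har <- haDeg * pi / 180
  b <- betaDeg * pi / 180
  list(HA = haDeg,
       TA = rep(taDeg, length.out = length(haDeg)),
       SE = atan(tan(b) * cos(har)) * 180 / pi,
       SA = atan(-tan(b) * sin(har)) * 180 / pi)
}

#' Ground-truth fields of the phantom on a voxel grid
#'
#' Evaluates the analytic model at every voxel centre of the phantom grid
#' decimated by \code{level} pyramid levels (level 0 = the texture grid,
#' \code{spec@dwiLevels} = the DWI grid; both grids share voxel centres by
#' construction, so the branches are co-registered). The truth mask is the
#' wall mask eroded by two voxels and trimmed by the derivative/binomial
#' filter support (8 fine-grid voxels, scaled per level) at the axial
#' field-of-view ends, so statistics never sample partial-volume or edge
#' voxels.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param level pyramid level of the target grid (0 = finest).
#' @return a \linkS4class{GroundTruth}.
#' @export
phantomGroundTruth <- function(spec, level = 0L) {
  d <- pyramidDim(spec@dim, level)
  h <- spec@voxelSize * 2^level
  org <- .phantomOrigin(spec)
  cc <- .voxelCoords(d, h, org)
  pts <- cbind(rep(cc$x, times = d[2] * d[3]),
               rep(rep(cc$y, each = d[1]), times = d[3]),
               rep(cc$z, each = d[1] * d[2]))
  betaDeg <- .betaField(spec, nrow(pts))
  tr <- analyticFrameAndFibers(spec, pts, betaDeg = betaDeg)
  wall <- array(tr$inside, d)
  as4d <- function(m) array(m, c(d, 3L))
  frame <- new("FrameField", circ = as4d(tr$circ), long = as4d(tr$long),
               radial = as4d(tr$radial), voxelSize = h, origin = org)
  # axial trim: filter support near the volume/wall ends, in fine voxels
  trim <- max(1L, as.integer(ceiling(8 / 2^level)))
  zi <- abs(pts[, 3]) <= spec@axialExtent / 2 - trim * h / 1000
  erosionSteps <- max(1L, as.integer(round(2 / 2^level)))
  truthMask <- erodeMask(wall, erosionSteps) & array(zi, d)
  haDeg <- spec@haEndo + (spec@haEpi - spec@haEndo) * tr$depth
  ang <- .analyticAngles(haDeg, spec@taConst, betaDeg)
  angles <- lapply(ang, function(a) {
    a <- array(a, d); a[!wall] <- NA_real_; a
  })
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  cavity <- array(r < spec@innerRadius, d)
  background <- array(r > spec@outerRadius, d)
  labels <- aha17Labels(wall, voxelSize = h,
                        rvInsertionAngle = spec@rvInsertionAngle,
                        origin = org)
  depth <- array(tr$depth, d)
  new("GroundTruth", fiber = as4d(tr$fiber),
      sheetNormal = as4d(tr$sheetNormal),
      sheetInPlane = as4d(tr$sheetInPlane), frame = frame,
      wallMask = wall, truthMask = truthMask, depth = depth,
      cavityMask = cavity, backgroundMask = background, labels = labels,
      angles = angles, voxelSize = h, origin = org)
}

#' Plane-wave laminar texture with a fixed sheet normal
#'
#' Reference texture for globally planar laminae: intensity
#' \code{offset + amplitude * cos(2 pi (p . normal) / wavelength)}, whose
#' gradient is everywhere parallel to \code{normal}.
#'
#' @param dim grid shape. @param voxelSize micrometres.
#' @param normal unit 3-vector. @param wavelength um.
#' @param amplitude,offset intensity parameters.
#' @return a \linkS4class{ScalarVolume}.
#' @export
planeWaveTexture <- function(dim, voxelSize, normal, wavelength,
                             amplitude = 1, offset = 0) {
  if (wavelength < 2 * voxelSize)
    stop("texture wavelength below the Nyquist limit (2 voxels)")
  normal <- normal / sqrt(sum(normal^2))
  cc <- .voxelCoords(dim, voxelSize)
  phase <- outer(outer(cc$x * normal[1], cc$y * normal[2], `+`),
                 cc$z * normal[3], `+`)
  vals <- offset + amplitude * cos(2 * pi * phase / (wavelength / 1000))
  ScalarVolume(vals, voxelSize)
}

# Sparse-Gabor directional noise: a sum of Gaussian-windowed plane waves.
# Each kernel carries a single wave along `waveField` evaluated at its
# centre; the envelope is anisotropic in the local (radial, transverse)
# frame -- narrow across the laminar plane (sigmaRadial) so a kernel never
# straddles sheets with different fiber orientation, wide within it
# (sigmaTransverse). Kernel centres are Poisson-like uniform in the padded
# wall; everything is reproducible from the spec seed.
.gaborField <- function(spec, waveField, wavelength, seedOffset) {
  d <- spec@dim
  h <- spec@voxelSize / 1000
  org <- .phantomOrigin(spec)
  sR <- spec@gaborSigmaRadial / 1000
  sT <- spec@gaborSigmaTransverse / 1000
  lam <- wavelength / 1000
  r1 <- max(spec@innerRadius - h, 0); r2 <- spec@outerRadius + h
  zHalf <- spec@axialExtent / 2 + h
  vol <- pi * (r2^2 - r1^2) * 2 * zHalf
  nImp <- max(64L, as.integer(round(spec@gaborDensity * vol / (sR * sT * sT))))
  set.seed(spec@seed + seedOffset)
  rr <- sqrt(runif(nImp) * (r2^2 - r1^2) + r1^2)
  th <- runif(nImp, 0, 2 * pi)
  px <- rr * cos(th); py <- rr * sin(th)
  pz <- runif(nImp, -zHalf, zHalf)
  psi <- runif(nImp, 0, 2 * pi)
  fr <- analyticFrameAndFibersClamped(spec, cbind(px, py, pz))
  dirs <- fr[[waveField]]
  rads <- fr$radial
  out <- array(0, d)
  cc <- .voxelCoords(d, spec@voxelSize, org)
  # per-axis 2.5-sigma bounds of the rotated envelope
  hx <- 2.5 * sqrt(sR^2 * rads[, 1]^2 + sT^2 * (1 - rads[, 1]^2))
  hy <- 2.5 * sqrt(sR^2 * rads[, 2]^2 + sT^2 * (1 - rads[, 2]^2))
  hz <- 2.5 * sT
  for (j in seq_len(nImp)) {
    sj <- dirs[j, ]
    if (any(!is.finite(sj))) next
    rj <- rads[j, ]
    ix <- which(abs(cc$x - px[j]) <= hx[j])
    iy <- which(abs(cc$y - py[j]) <= hy[j])
    iz <- which(abs(cc$z - pz[j]) <= hz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx <- cc$x[ix] - px[j]; dy <- cc$y[iy] - py[j]; dz <- cc$z[iz] - pz[j]
    phase <- outer(outer(dx * sj[1], dy * sj[2], `+`), dz * sj[3], `+`)
    dr <- outer(outer(dx * rj[1], dy * rj[2], `+`), dz * rj[3], `+`)
    r2g <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    out[ix, iy, iz] <- out[ix, iy, iz] +
      exp(-dr^2 / (2 * sR^2) - pmax(r2g - dr^2, 0) / (2 * sT^2)) *
        cos(2 * pi * phase / lam + psi[j])
  }
  out
}

#' Render the phantom texture volume (STI input)
#'
#' Wall intensity = offset + laminar cosine + striation component. The
#' laminar term has exact radial phase when the sheet normal field is radial
#' (beta = 0); for tilted or bimodal laminae it is synthesized from sparse
#' Gabor kernels oriented along the local sheet normal (a helically rotating
#' plane field admits no global phase). The striation term is sparse Gabor
#' noise oriented along the local sheet-in-plane direction: it models the
#' weaker myocyte striation contrast of FLASH images and is what renders the
#' smallest-eigenvalue structure-tensor direction (the fiber) well defined.
#' Partial-volume voxels at the wall boundary get linearly mixed intensity.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param truth matching \linkS4class{GroundTruth} at level 0.
#' @return a \linkS4class{ScalarVolume}.
#' @export
renderTextureVolume <- function(spec, truth) {
  if (!identical(gridDim(truth), spec@dim))
    stop("truth must be on the level-0 phantom grid")
  if (spec@textureWavelength < 2 * spec@voxelSize ||
      spec@fiberTextureWavelength < 2 * spec@voxelSize)
    stop("texture wavelength below the Nyquist limit (2 voxels)")
  d <- spec@dim
  h <- spec@voxelSize / 1000
  org <- .phantomOrigin(spec)
  cc <- .voxelCoords(d, spec@voxelSize, org)
  r <- sqrt(outer(cc$x^2, cc$y^2, `+`))              # nx x ny
  rArr <- array(rep(r, times = d[3]), d)
  zArr <- array(rep(cc$z, each = d[1] * d[2]), d)
  wall <- truth@wallMask
  A <- spec@textureAmplitude
  lamWall <- array(0, d)
  if (A > 0) {
    if (spec@beta == 0 && !spec@betaBimodal) {
      lamWall <- A * cos(2 * pi * (rArr - spec@innerRadius) /
                           (spec@textureWavelength / 1000))
    } else {
      g <- .gaborField(spec, "sheetNormal", spec@textureWavelength,
                       seedOffset = 2L)
      rms <- sqrt(mean(g[wall]^2))
      if (rms > 0) lamWall <- g * (A / sqrt(2) / rms)
    }
    if (spec@fiberTextureFraction > 0) {
      g <- .gaborField(spec, "sheetInPlane", spec@fiberTextureWavelength,
                       seedOffset = 3L)
      rms <- sqrt(mean(g[wall]^2))
      if (rms > 0)
        lamWall <- lamWall + g * (spec@fiberTextureFraction * A / rms)
    }
  }
  wallIntensity <- spec@textureOffset + lamWall
  # linear partial-volume mixing from the signed distance to the wall surface
  sd <- pmin(rArr - spec@innerRadius, spec@outerRadius - rArr,
             spec@axialExtent / 2 - abs(zArr))
  cov <- pmin(pmax(sd / h + 0.5, 0), 1)
  vals <- spec@backgroundIntensity * (1 - cov) + wallIntensity * cov
  vals[vals < 0] <- 0
  ScalarVolume(vals, spec@voxelSize, org)
}

# analytic evaluation with depth clamped to the wall so texture kernels
# centred just outside the wall still get a direction
analyticFrameAndFibersClamped <- function(spec, points) {
  r <- sqrt(points[, 1]^2 + points[, 2]^2)
  r <- pmin(pmax(r, spec@innerRadius + 1e-9), spec@outerRadius - 1e-9)
  th <- atan2(points[, 2], points[, 1])
  z <- pmin(pmax(points[, 3], -spec@axialExtent / 2 + 1e-9),
            spec@axialExtent / 2 - 1e-9)
  analyticFrameAndFibers(spec, cbind(r * cos(th), r * sin(th), z),
                         betaDeg = rep(spec@beta, nrow(points)))
}

#' Synthesize diffusion-weighted volumes from the ground truth
#'
#' The per-voxel tensor is assembled from the truth triad,
#' D = l1 f f' + l2 s s' + l3 n n' (isotropic background diffusivity outside
#' the wall); the noiseless signal is S0 exp(-b g' D g) for each direction
#' plus \code{nB0} unweighted volumes. Rician noise is applied as
#' |S + n1 + i n2| with independent zero-mean Gaussians of sd
#' \code{ricianSigma}, reproducibly from the spec seed.
#'
#' @param truth \linkS4class{GroundTruth} on the target (DWI) grid.
#' @param spec the matching \linkS4class{PhantomSpec}.
#' @return a \linkS4class{DWISet} with \code{nB0 + nrow(directions)} volumes.
#' @export
synthesizeDWI <- function(truth, spec) {
  .dtiDesign(rbind(matrix(0, spec@nB0, 3), spec@directions),
             c(rep(0, spec@nB0), rep(spec@bValue, nrow(spec@directions))))
  d <- gridDim(truth)
  nDir <- nrow(spec@directions)
  nVol <- spec@nB0 + nDir
  lam <- spec@diffusivities
  vols <- array(0, c(d, nVol))
  wall <- which(truth@wallMask)
  f <- matrix(truth@fiber, ncol = 3)[wall, , drop = FALSE]
  s <- matrix(truth@sheetInPlane, ncol = 3)[wall, , drop = FALSE]
  n <- matrix(truth@sheetNormal, ncol = 3)[wall, , drop = FALSE]
  for (k in seq_len(spec@nB0)) vols[, , , k] <- spec@S0
  for (j in seq_len(nDir)) {
    g <- spec@directions[j, ]
    # g' D g = l1 (f.g)^2 + l2 (s.g)^2 + l3 (n.g)^2
    adc <- array(spec@backgroundDiffusivity, d)
    adc[wall] <- lam[1] * (f %*% g)^2 + lam[2] * (s %*% g)^2 +
                 lam[3] * (n %*% g)^2
    vols[, , , spec@nB0 + j] <- spec@S0 * exp(-spec@bValue * adc)
  }
  if (spec@ricianSigma > 0) {
    set.seed(spec@seed)
    n1 <- array(rnorm(length(vols), sd = spec@ricianSigma), dim(vols))
    n2 <- array(rnorm(length(vols), sd = spec@ricianSigma), dim(vols))
    vols <- sqrt((vols + n1)^2 + n2^2)
  }
  DWISet(vols,
         gradients = rbind(matrix(0, spec@nB0, 3), spec@directions),
         bvalues = c(rep(0, spec@nB0), rep(spec@bValue, nDir)),
         voxelSize = truth@voxelSize, origin = truth@origin)
}
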