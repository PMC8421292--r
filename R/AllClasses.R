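#' @import methods
#' @importFrom stats fft rnorm runif sd lm coef kruskal.test mvfft setNames
NULL

.isIso3 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

#' ScalarVolume: a 3D scalar grid with isotropic spacing
#'
#' Carrier for gray-scale (FLASH-like) volumes and derived scalar maps
#' (fractional anisotropy, trace, angle maps). Values are stored as a plain
#' 3D array; spacing is isotropic and given in micrometres, the world origin
#' (position of the centre of voxel \code{[1,1,1]}) in millimetres.
#'
#' @slot values 3D numeric array.
#' @slot voxelSize isotropic voxel edge length in micrometres.
#' @slot origin numeric length-3, millimetres.
#' @export
setClass("ScalarVolume",
  representation(values = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (!.isIso3(object@voxelSize))
      msg <- c(msg, "'voxelSize' must be a single positive number (micrometres)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be a finite length-3 numeric (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScalarVolume
#'
#' @param values 3D numeric array.
#' @param voxelSize isotropic voxel size in micrometres.
#' @param origin world position (mm) of the centre of the first voxel.
#' @return A \linkS4class{ScalarVolume}.
#' @examples
#' v <- ScalarVolume(array(0, c(8, 8, 8)), voxelSize = 150)
#' gridDim(v)
#' @export
ScalarVolume <- function(values, voxelSize, origin = c(0, 0, 0)) {
  new("ScalarVolume", values = values, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' TensorField: per-voxel symmetric 3x3 tensors
#'
#' Stores the six unique components per voxel in a 4D array whose last axis
#' is ordered \code{xx, yy, zz, xy, xz, yz}. Used for both structure tensors
#' (intensity-gradient outer products) and diffusion tensors (mm^2/s).
#'
#' @slot comps 4D numeric array, last axis length 6.
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("TensorField",
  representation(comps = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@comps)
    if (length(d) != 4L || d[4L] != 6L)
      return("'comps' must be a 4D array with 6 components on the last axis")
    if (!.isIso3(object@voxelSize)) return("'voxelSize' must be positive")
    TRUE
  })

#' @rdname TensorField-class
#' @param comps 4D array (nx, ny, nz, 6), component order xx,yy,zz,xy,xz,yz.
#' @param voxelSize micrometres. @param origin mm triple.
#' @export
TensorField <- function(comps, voxelSize, origin = c(0, 0, 0)) {
  new("TensorField", comps = comps, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' EigenField: per-voxel eigen-decomposition with anatomical roles
#'
#' Eigenvalues are sorted descending; eigenvectors are unit length and
#' sign-canonicalized (positive z component, falling back to +x then +y when
#' degenerate, so repeated runs are bit-identical; fiber and sheet vectors are
#' axial quantities, so the sign itself carries no meaning). The role map
#' records which eigenvector index carries the myocyte (fiber), sheet-in-plane
#' and sheet-normal direction: STI assigns sheet-normal to the largest
#' eigenvalue and fiber to the smallest, DTI the opposite.
#'
#' @slot values 4D array (nx, ny, nz, 3), eigenvalues descending.
#' @slot vectors 5D array (nx, ny, nz, 3 components, 3 eigenvectors).
#' @slot roles named integer (fiber, sheetInPlane, sheetNormal) -> index 1..3.
#' @slot degenerate logical 3D array: relative eigenvalue gap < 1e-6.
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("EigenField",
  representation(values = "array", vectors = "array", roles = "integer",
                 degenerate = "array", voxelSize = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    dv <- dim(object@values); dV <- dim(object@vectors)
    if (length(dv) != 4L || dv[4L] != 3L)
      return("'values' must be (nx, ny, nz, 3)")
    if (length(dV) != 5L || any(dV[4:5] != 3L))
      return("'vectors' must be (nx, ny, nz, 3, 3)")
    if (!all(c("fiber", "sheetInPlane", "sheetNormal") %in%
             names(object@roles)))
      return("'roles' must name fiber, sheetInPlane and sheetNormal")
    TRUE
  })

#' FrameField: per-voxel cardiac coordinate frame
#'
#' Right-handed orthonormal triad per voxel: circumferential \code{circ},
#' longitudinal \code{long} (the LV long axis, +z toward the base) and radial
#' \code{radial} (outward from the per-slice cavity centroid), with
#' \code{circ = long x radial}. Voxels on the axis carry NA (invalid frame).
#'
#' @slot circ,long,radial 4D arrays (nx, ny, nz, 3).
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("FrameField",
  representation(circ = "array", long = "array", radial = "array",
                 voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    for (s in c("circ", "long", "radial")) {
      d <- dim(slot(object, s))
      if (length(d) != 4L || d[4L] != 3L)
        return(sprintf("'%s' must be (nx, ny, nz, 3)", s))
    }
    TRUE
  })

#' DWISet: diffusion-weighted volumes plus gradient table
#'
#' Volumes are stored in acquisition order as a 4D array; the gradient table
#' holds one unit direction per volume (zero vector for b0) and the b value in
#' s/mm^2. At least one b0 and six non-collinear weighted directions are
#' required for the tensor to be identifiable.
#'
#' @slot volumes 4D array (nx, ny, nz, nvol).
#' @slot gradients nvol x 3 matrix of unit (or zero) directions.
#' @slot bvalues numeric nvol, s/mm^2.
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("DWISet",
  representation(volumes = "array", gradients = "matrix", bvalues = "numeric",
                 voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@volumes)
    if (length(d) != 4L) return("'volumes' must be a 4D array")
    nv <- d[4L]
    if (nrow(object@gradients) != nv || ncol(object@gradients) != 3L)
      return("'gradients' must be nvol x 3")
    if (length(object@bvalues) != nv) return("one b value per volume required")
    if (sum(object@bvalues <= 0) < 1L) return("at least one b0 volume required")
    if (sum(object@bvalues > 0) < 6L)
      return("at least six diffusion-weighted volumes required")
    TRUE
  })

#' @rdname DWISet-class
#' @param volumes 4D array. @param gradients nvol x 3 matrix.
#' @param bvalues numeric. @param voxelSize micrometres. @param origin mm.
#' @export
DWISet <- function(volumes, gradients, bvalues, voxelSize,
                   origin = c(0, 0, 0)) {
  new("DWISet", volumes = volumes, gradients = as.matrix(gradients),
      bvalues = as.numeric(bvalues), voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' AngleMaps: helix, transverse, sheetlet elevation and azimuth maps
#'
#' All four maps are in degrees, wrapped into [-90, 90] (fibers and sheet
#' normals are axial: v and -v are the same structure). NA marks voxels
#' outside the validity mask.
#'
#' @slot HA,TA,SE,SA 3D numeric arrays (degrees).
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("AngleMaps",
  representation(HA = "array", TA = "array", SE = "array", SA = "array",
                 voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@HA)
    for (s in c("TA", "SE", "SA"))
      if (!identical(dim(slot(object, s)), d))
        return("all four angle maps must share the same grid")
    rng <- suppressWarnings(
      range(c(object@HA, object@TA, object@SE, object@SA), na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -90 - 1e-9 || rng[2] > 90 + 1e-9))
      return("angles must lie in [-90, 90] degrees")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic left-ventricle phantom
#'
#' Describes an annular-cylinder LV wall (axis = z) with a linear transmural
#' helix-angle law, an imposed transverse angle, a sheet-normal tilt beta
#' about the fiber axis, the laminar/striation texture, and the diffusion
#' model used to synthesize DWI signals. See \code{\link{phantomSpec}}.
#'
#' @export
setClass("PhantomSpec",
  representation(
    dim = "integer", voxelSize = "numeric",
    innerRadius = "numeric", outerRadius = "numeric", axialExtent = "numeric",
    haEndo = "numeric", haEpi = "numeric", taConst = "numeric",
    beta = "numeric", betaBimodal = "logical",
    textureWavelength = "numeric", textureAmplitude = "numeric",
    textureOffset = "numeric", backgroundIntensity = "numeric",
    fiberTextureFraction = "numeric",
    fiberTextureWavelength = "numeric", gaborSigmaRadial = "numeric",
    gaborSigmaTransverse = "numeric", gaborDensity = "numeric",
    diffusivities = "numeric", backgroundDiffusivity = "numeric",
    S0 = "numeric", ricianSigma = "numeric", bValue = "numeric",
    directions = "matrix", nB0 = "integer", dwiLevels = "integer",
    rvInsertionAngle = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 8L))
      msg <- c(msg, "grid must be 3D with at least 8 voxels per axis")
    if (!(object@innerRadius < object@outerRadius))
      msg <- c(msg, "inner radius must be smaller than outer radius")
    lam <- object@diffusivities
    if (length(lam) != 3L || any(lam <= 0) || is.unsorted(rev(lam)))
      msg <- c(msg, "diffusivities must be three positive values, descending")
    if (any(abs(c(object@haEndo, object@haEpi)) > 90))
      msg <- c(msg, "helix angles must lie in [-90, 90] degrees")
    if (object@textureWavelength < 2 * object@voxelSize)
      msg <- c(msg, "texture wavelength below the Nyquist limit (2 voxels)")
    if (nrow(object@directions) < 6L)
      msg <- c(msg, "at least six gradient directions required")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: analytic phantom fields on a voxel grid
#'
#' All vector fields are unit length and mutually orthonormal at wall voxels;
#' outside the wall they are NA. \code{truthMask} is the wall mask eroded by
#' two voxels and trimmed at the axial field-of-view ends; quantitative
#' comparisons against the truth are restricted to it so partial-volume and
#' filter-support edge voxels never enter statistics.
#'
#' @slot fiber,sheetNormal,sheetInPlane 4D arrays (nx, ny, nz, 3).
#' @slot frame FrameField.
#' @slot wallMask,truthMask logical 3D arrays.
#' @slot depth 3D array, normalized transmural depth (0 endo, 1 epi).
#' @slot cavityMask,backgroundMask logical 3D arrays (regions inside/outside).
#' @slot labels integer 3D array, AHA segment 1-17 (NA outside wall).
#' @slot angles list of analytic HA, TA, SE, SA maps (degrees).
#' @slot voxelSize micrometres. @slot origin mm.
#' @export
setClass("GroundTruth",
  representation(fiber = "array", sheetNormal = "array",
                 sheetInPlane = "array", frame = "FrameField",
                 wallMask = "array", truthMask = "array", depth = "array",
                 cavityMask = "array", backgroundMask = "array",
                 labels = "array", angles = "list",
                 voxelSize = "numeric", origin = "numeric"))

# ---- accessors ----

#' Grid dimension, voxel size and origin accessors
#'
#' @param x a cardioTensor data object.
#' @return \code{gridDim}: integer length-3; \code{voxelSize}: micrometres;
#'   \code{origin}: mm triple.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname gridDim
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname gridDim
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname gridDim
setMethod("voxelSize", "ANY", function(x) x@voxelSize)
#' @rdname gridDim
setMethod("origin", "ANY", function(x) x@origin)
#' @rdname gridDim
setMethod("gridDim", "ScalarVolume", function(x) dim(x@values))
#' @rdname gridDim
setMethod("gridDim", "TensorField", function(x) dim(x@comps)[1:3])
#' @rdname gridDim
setMethod("gridDim", "EigenField", function(x) dim(x@values)[1:3])
#' @rdname gridDim
setMethod("gridDim", "FrameField", function(x) dim(x@circ)[1:3])
#' @rdname gridDim
setMethod("gridDim", "DWISet", function(x) dim(x@volumes)[1:3])
#' @rdname gridDim
setMethod("gridDim", "AngleMaps", function(x) dim(x@HA))
#' @rdname gridDim
setMethod("gridDim", "GroundTruth", function(x) dim(x@wallMask))
#' @rdname gridDim
setMethod("gridDim", "PhantomSpec", function(x) x@dim)

#' Extract the value array of a ScalarVolume
#' @param x a \linkS4class{ScalarVolume}.
#' @return the underlying 3D array.
#' @export
setGeneric("values3d", function(x) standardGeneric("values3d"))
#' @rdname values3d
setMethod("values3d", "ScalarVolume", function(x) x@values)

#' Tensor components of a TensorField
#' @param x a \linkS4class{TensorField}.
#' @return 4D array, last axis xx,yy,zz,xy,xz,yz.
#' @export
setGeneric("tensorComps", function(x) standardGeneric("tensorComps"))
#' @rdname tensorComps
setMethod("tensorComps", "TensorField", function(x) x@comps)

#' Eigenvalues, eigenvectors and role map of an EigenField
#' @param x an \linkS4class{EigenField}.
#' @param role one of "fiber", "sheetInPlane", "sheetNormal".
#' @return \code{eigenValues}: 4D array; \code{roleVector}: 4D array
#'   (nx, ny, nz, 3) holding the unit vector carrying that role.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname eigenValues
setMethod("eigenValues", "EigenField", function(x) x@values)

#' @rdname eigenValues
#' @export
setGeneric("roleVector", function(x, role) standardGeneric("roleVector"))
#' @rdname eigenValues
setMethod("roleVector", "EigenField", function(x, role) {
  role <- match.arg(role, c("fiber", "sheetInPlane", "sheetNormal"))
  x@vectors[, , , , x@roles[[role]], drop = TRUE]
})

#' Angle map accessor
#' @param x an \linkS4class{AngleMaps}.
#' @param which one of "HA", "TA", "SE", "SA".
#' @return 3D array of degrees.
#' @export
setGeneric("angleMap", function(x, which) standardGeneric("angleMap"))
#' @rdname angleMap
setMethod("angleMap", "AngleMaps", function(x, which) {
  slot(x, match.arg(which, c("HA", "TA", "SE", "SA")))
})

# ---- show methods ----

.dimStr <- function(d) paste(d, collapse = " x ")

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("ScalarVolume %s, %g um voxels, range [%.4g, %.4g]\n",
              .dimStr(gridDim(object)), object@voxelSize, rng[1], rng[2]))
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("TensorField %s, %g um voxels (6 components: xx,yy,zz,xy,xz,yz)\n",
              .dimStr(gridDim(object)), object@voxelSize))
})

setMethod("show", "EigenField", function(object) {
  r <- object@roles
  cat(sprintf(
    "EigenField %s, %g um voxels; roles: fiber=e%d, sheetInPlane=e%d, sheetNormal=e%d\n",
    .dimStr(gridDim(object)), object@voxelSize,
    r[["fiber"]], r[["sheetInPlane"]], r[["sheetNormal"]]))
})

setMethod("show", "FrameField", function(object) {
  cat(sprintf("FrameField %s, %g um voxels (circ, long, radial)\n",
              .dimStr(gridDim(object)), object@voxelSize))
})

setMethod("show", "DWISet", function(object) {
  cat(sprintf("DWISet %s, %d volumes (%d b0 + %d weighted), b max %g s/mm^2\n",
              .dimStr(gridDim(object)), dim(object@volumes)[4],
              sum(object@bvalues <= 0), sum(object@bvalues > 0),
              max(object@bvalues)))
})

setMethod("show", "AngleMaps", function(object) {
  cat(sprintf("AngleMaps %s, %g um voxels, %d valid voxels\n",
              .dimStr(gridDim(object)), object@voxelSize,
              sum(!is.na(object@HA))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: %s grid at %g um; wall r [%g, %g] mm, z extent %g mm\n",
    "  HA %+g (endo) to %+g (epi) deg, TA %g deg, sheet tilt beta %g deg\n",
    "  DWI: b = %g s/mm^2, %d directions + %d b0, sigma = %g, seed = %d\n"),
    .dimStr(object@dim), object@voxelSize, object@innerRadius,
    object@outerRadius, object@axialExtent, object@haEndo, object@haEpi,
    object@taConst, object@beta, object@bValue, nrow(object@directions),
    object@nB0, object@ricianSigma, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth %s, %g um voxels; wall %d voxels, truth mask %d\n",
              .dimStr(gridDim(object)), object@voxelSize,
              sum(object@wallMask), sum(object@truthMask)))
})
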