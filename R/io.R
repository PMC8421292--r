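# NIfTI readers/writers (via RNifti), the plain-text gradient table, and
# YAML pipeline configuration.

.mmPixdim <- function(voxelSize) rep(voxelSize / 1000, 3)

#' Read a 3D NIfTI scalar volume
#'
#' Requires isotropic spacing (within 1e-6 relative); the spacing is
#' converted to micrometres and the stored origin to millimetres.
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return a \linkS4class{ScalarVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim(img))   # strip the niftiImage class
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)), "D: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * mean(pd))
    stop("non-isotropic spacing (", paste(signif(pd, 6), collapse = " x "),
         " mm): resample before analysis")
  v0 <- RNifti::worldToVoxel(c(0, 0, 0), img)   # voxel index of world origin
  org <- -(v0 - 1) * pd                          # world pos of voxel [1,1,1]
  ScalarVolume(a, voxelSize = mean(pd) * 1000, origin = as.numeric(org))
}

#' Write a ScalarVolume (or raw array) as NIfTI
#'
#' @param vol a \linkS4class{ScalarVolume}, or a 3D/4D array with
#'   \code{voxelSize} given.
#' @param path output path. @param voxelSize micrometres (arrays only).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path, voxelSize = NULL) {
  if (is(vol, "ScalarVolume")) {
    a <- values3d(vol); vs <- voxelSize(vol)
  } else {
    a <- vol; vs <- voxelSize
    if (is.null(vs)) stop("voxelSize required when writing a raw array")
  }
  attr(a, "pixdim") <- rep(vs / 1000, length(dim(a)))
  img <- RNifti::asNifti(a, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a plain-text gradient table
#'
#' One row per volume, whitespace-separated: gx gy gz b, in volume order
#' (zero direction for b0 rows).
#'
#' @param path text file.
#' @return data.frame with columns gx, gy, gz, b.
#' @export
readGradientTable <- function(path) {
  tab <- utils::read.table(path, col.names = c("gx", "gy", "gz", "b"))
  w <- tab$b > 0
  nrm <- sqrt(tab$gx^2 + tab$gy^2 + tab$gz^2)
  if (any(w & abs(nrm - 1) > 1e-3))
    warning("non-unit gradient directions in ", path, "; renormalizing")
  tab[w, 1:3] <- tab[w, 1:3] / nrm[w]
  tab
}

#' @rdname readGradientTable
#' @param gradients n x 3 matrix. @param bvalues numeric n.
#' @export
writeGradientTable <- function(gradients, bvalues, path) {
  utils::write.table(cbind(gradients, bvalues), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a DWISet from per-volume NIfTI files and a gradient table
#'
#' @param paths character vector of NIfTI volume paths, in table order.
#' @param tablePath gradient table (\code{\link{readGradientTable}} format).
#' @return a \linkS4class{DWISet}.
#' @export
readDWISet <- function(paths, tablePath) {
  tab <- readGradientTable(tablePath)
  if (length(paths) != nrow(tab))
    stop("gradient table has ", nrow(tab), " rows but ", length(paths),
         " volumes were given")
  vols <- lapply(paths, readVolume)
  d <- gridDim(vols[[1]])
  arr <- array(0, c(d, length(vols)))
  for (k in seq_along(vols)) {
    if (!identical(gridDim(vols[[k]]), d)) stop("DWI volume grids differ")
    arr[, , , k] <- values3d(vols[[k]])
  }
  DWISet(arr, gradients = as.matrix(tab[, 1:3]), bvalues = tab$b,
         voxelSize = voxelSize(vols[[1]]), origin = origin(vols[[1]]))
}

#' Write the phantom inputs to disk
#'
#' Emits the texture volume, every DWI volume, the gradient table, the truth
#' vector fields (4D NIfTI, last axis length 3) and a JSON sidecar of the
#' phantom specification.
#'
#' @param spec \linkS4class{PhantomSpec}. @param truth level-0
#'   \linkS4class{GroundTruth}. @param texture \linkS4class{ScalarVolume}.
#' @param dwi \linkS4class{DWISet}. @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
writePhantom <- function(spec, truth, texture, dwi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- function(f) file.path(dir, f)
  writeVolume(texture, p("texture.nii.gz")); files <- c(files, p("texture.nii.gz"))
  for (k in seq_len(dim(dwi@volumes)[4])) {
    f <- p(sprintf("dwi_%02d.nii.gz", k))
    writeVolume(dwi@volumes[, , , k], f, voxelSize = voxelSize(dwi))
    files <- c(files, f)
  }
  writeGradientTable(dwi@gradients, dwi@bvalues, p("gradients.txt"))
  for (fld in c("fiber", "sheetNormal", "sheetInPlane")) {
    f <- p(paste0("truth_", fld, ".nii.gz"))
    writeVolume(slot(truth, fld), f, voxelSize = truth@voxelSize)
    files <- c(files, f)
  }
  sp <- sapply(slotNames(spec), function(s) slot(spec, s), simplify = FALSE)
  jsonlite::write_json(sp, p("phantom_spec.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  files <- c(files, p("gradients.txt"), p("phantom_spec.json"))
  invisible(files)
}

#' Read a YAML pipeline configuration
#'
#' Returns a validated list of pipeline settings; unknown keys are an
#' error so typos never silently fall back to defaults. See
#' \code{\link{runPipeline}} for the settings and their defaults.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("phantom", "levels", "binWidth", "rvInsertionAngle",
             "faCutoffs", "weightedFit", "outDir", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg
}
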