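# End-to-end driver: phantom -> STI branch (texture, gradients, structure
# tensors, binomial pyramid, eigenanalysis) and DTI branch (DWI synthesis,
# tensor fit, scalars, eigenanalysis) -> cardiac frames -> angle maps ->
# AHA-17 regional profiles and fits -> DTI-vs-STI agreement statistics.

#' Run the full phantom validation pipeline
#'
#' Generates the phantom at fine (texture) and coarse (DWI) resolution,
#' processes both branches to the four angle maps on the shared coarse grid,
#' computes normalized transmural depth (at fine resolution, decimated to
#' the coarse grid), AHA 17-segment labels, per-segment and pooled
#' transmural profiles with weighted linear fits, Bland-Altman agreement,
#' the 17-segment bullseye table, and Kruskal-Wallis comparisons of the two
#' modalities in transmural thirds. Deterministic given the spec seed.
#'
#' @param spec a \linkS4class{PhantomSpec}, or a config list from
#'   \code{\link{readPipelineConfig}} whose \code{phantom} entry holds
#'   \code{\link{phantomSpec}} arguments.
#' @param outDir optional directory: writes NIfTI/CSV artifacts and a JSON
#'   report; NULL (default) keeps everything in memory.
#' @param binWidth transmural profile bin width.
#' @param weightedFit weight profile fits by bin counts.
#' @param verbose emit stage messages.
#' @return list with elements \code{spec}, \code{truthFine},
#'   \code{truthCoarse}, \code{texture}, \code{sti} (eigen + angle maps),
#'   \code{dti} (tensor, scalars, eigen, angle maps), \code{depth},
#'   \code{labels}, \code{profiles}, \code{fits} (data.frame),
#'   \code{globalFits}, \code{blandAltman}, \code{bullseye},
#'   \code{kruskal}, and \code{report} (JSON-able summary).
#' @export
runPipeline <- function(spec, outDir = NULL, binWidth = 0.005,
                        weightedFit = TRUE, verbose = TRUE) {
  if (is.list(spec)) {
    cfg <- spec
    spec <- do.call(phantomSpec, c(cfg$phantom,
                                   if (!is.null(cfg$seed)) list(seed = cfg$seed)))
    if (!is.null(cfg$binWidth)) binWidth <- cfg$binWidth
    if (!is.null(cfg$weightedFit)) weightedFit <- cfg$weightedFit
    if (is.null(outDir)) outDir <- cfg$outDir
  }
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  lv <- spec@dwiLevels

  say("phantom: ground truth at levels 0 and %d", lv)
  truthFine <- phantomGroundTruth(spec, 0L)
  truthCoarse <- phantomGroundTruth(spec, lv)

  say("phantom: rendering texture volume (%s)", paste(spec@dim, collapse = "x"))
  texture <- renderTextureVolume(spec, truthFine)

  say("STI: gradients, structure tensors, %d-level binomial pyramid", lv)
  grad <- imageGradient(texture)
  st <- structureTensorField(grad, voxelSize(texture), origin(texture))
  rm(grad)
  stc <- binomialPyramid(st, lv)
  rm(st)
  maskC <- truthCoarse@truthMask
  stiEig <- stEigenanalysis(stc, maskC)

  say("DTI: synthesizing DWI and fitting tensors")
  dwi <- synthesizeDWI(truthCoarse, spec)
  wallC <- truthCoarse@wallMask
  dt <- fitDTI(dwi, wallC | truthCoarse@cavityMask | truthCoarse@backgroundMask)
  scal <- dtiScalars(dt)
  dtiEig <- dtiEigenanalysis(dt, maskC)

  say("frames and angle maps on the coarse grid")
  frames <- buildFrames(gridDim(stiEig), voxelSize(stiEig), origin(stiEig),
                        centroids = c(0, 0))
  stiAngles <- angleMaps(stiEig, frames, "STI")
  dtiAngles <- angleMaps(dtiEig, frames, "DTI")

  say("transmural depth (fine grid) and AHA-17 labels")
  depthFine <- transmuralDepth(truthFine@wallMask, truthFine@cavityMask,
                               truthFine@backgroundMask,
                               voxelSize(texture))
  depth <- decimateArray(depthFine, lv)
  labels <- aha17Labels(wallC, voxelSize = truthCoarse@voxelSize,
                        rvInsertionAngle = spec@rvInsertionAngle,
                        origin = truthCoarse@origin)

  say("profiles, fits and agreement statistics")
  angNames <- c("HA", "TA", "SE", "SA")
  sources <- list(STI = stiAngles, DTI = dtiAngles)
  profiles <- list()
  fits <- list()
  segs <- sort(unique(labels[maskC & !is.na(labels)]))
  for (src in names(sources)) {
    for (ang in angNames) {
      am <- angleMap(sources[[src]], ang)
      am[!maskC] <- NA_real_
      for (seg in segs) {
        pr <- transmuralProfile(am, depth, labels, seg, binWidth)
        key <- sprintf("%s.%s.seg%02d", src, ang, seg)
        profiles[[key]] <- pr
        ft <- tryCatch(linearFit(pr, weighted = weightedFit),
                       error = function(e) NULL)
        if (!is.null(ft))
          fits[[key]] <- data.frame(source = src, angle = ang, segment = seg,
                                    slope = ft$slope, intercept = ft$intercept,
                                    r.squared = ft$r.squared)
      }
    }
  }
  fits <- do.call(rbind, c(fits, list(make.row.names = FALSE)))

  globalFits <- list()
  for (src in names(sources)) for (ang in c("HA", "TA")) {
    am <- angleMap(sources[[src]], ang)
    am[!maskC] <- NA_real_
    pr <- transmuralProfile(am, depth, NULL, NULL, binWidth)
    globalFits[[paste(src, ang, sep = ".")]] <-
      c(list(profile = pr), linearFit(pr, weighted = weightedFit))
  }

  ba <- lapply(setNames(angNames, angNames), function(ang)
    blandAltman(angleMap(dtiAngles, ang), angleMap(stiAngles, ang), maskC))
  be <- bullseye(dtiAngles, stiAngles, labels, maskC)

  # DTI vs STI HA in transmural thirds (endo / mid / epi)
  kw <- list()
  haD <- angleMap(dtiAngles, "HA"); haS <- angleMap(stiAngles, "HA")
  for (th in 1:3) {
    sel <- maskC & !is.na(depth) & depth >= (th - 1) / 3 & depth < th / 3
    g <- list(DTI = haD[sel & is.finite(haD)], STI = haS[sel & is.finite(haS)])
    if (all(lengths(g) >= 3))
      kw[[c("endo", "mid", "epi")[th]]] <- kruskalWallis(g)
  }

  faWall <- values3d(scal$FA)[maskC]
  report <- list(
    seed = spec@seed,
    grid = list(fine = spec@dim, coarse = gridDim(stiEig),
                voxel.um = c(fine = spec@voxelSize,
                             coarse = truthCoarse@voxelSize)),
    voxels = list(wall.coarse = sum(wallC), truth.mask = sum(maskC),
                  sti.valid = sum(!is.na(angleMap(stiAngles, "HA"))),
                  dti.valid = sum(!is.na(angleMap(dtiAngles, "HA")))),
    fa = list(mean = mean(faWall, na.rm = TRUE),
              sd = sd(faWall, na.rm = TRUE)),
    ha.fit = list(
      sti = globalFits$STI.HA[c("slope", "intercept", "r.squared")],
      dti = globalFits$DTI.HA[c("slope", "intercept", "r.squared")],
      analytic.slope = spec@haEpi - spec@haEndo),
    bland.altman = lapply(ba, function(x)
      x[c("bias", "sd", "loa.low", "loa.high", "n")]),
    bullseye.ha.max.absdiff =
      max(be$absDiff[be$angle == "HA"], na.rm = TRUE),
    elapsed.s = proc.time()[["elapsed"]] - t0)

  res <- list(spec = spec, truthFine = truthFine, truthCoarse = truthCoarse,
              texture = texture,
              sti = list(tensors = stc, eigen = stiEig, angles = stiAngles),
              dti = list(dwi = dwi, tensor = dt, scalars = scal,
                         eigen = dtiEig, angles = dtiAngles),
              frames = frames, depth = depth, labels = labels,
              profiles = profiles, fits = fits, globalFits = globalFits,
              blandAltman = ba, bullseye = be, kruskal = kw,
              report = report)
  if (!is.null(outDir)) .writePipelineArtifacts(res, outDir)
  res
}

.writePipelineArtifacts <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  written <- character()
  wv <- function(obj, f, vs = NULL) {
    writeVolume(obj, p(f), voxelSize = vs); written <<- c(written, f)
  }
  wv(res$texture, "texture.nii.gz")
  vsC <- voxelSize(res$sti$angles)
  for (src in c("sti", "dti")) for (ang in c("HA", "TA", "SE", "SA"))
    wv(angleMap(res[[src]]$angles, ang),
       sprintf("%s_%s.nii.gz", src, tolower(ang)), vs = vsC)
  wv(values3d(res$dti$scalars$FA), "dti_fa.nii.gz", vs = vsC)
  wv(values3d(res$dti$scalars$trace), "dti_trace.nii.gz", vs = vsC)
  wv(res$depth, "depth.nii.gz", vs = vsC)
  lab <- res$labels; lab[is.na(lab)] <- 0L
  wv(lab, "aha_labels.nii.gz", vs = vsC)
  utils::write.csv(res$fits, p("fits.csv"), row.names = FALSE)
  utils::write.csv(res$bullseye, p("bullseye.csv"), row.names = FALSE)
  prof <- do.call(rbind, lapply(names(res$profiles), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    cbind(data.frame(source = parts[1], angle = parts[2], segment = parts[3]),
          res$profiles[[k]])
  }))
  utils::write.csv(prof, p("profiles.csv"), row.names = FALSE)
  ba <- do.call(rbind, lapply(names(res$blandAltman), function(a) {
    x <- res$blandAltman[[a]]
    data.frame(angle = a, bias = x$bias, sd = x$sd, loa.low = x$loa.low,
               loa.high = x$loa.high, n = x$n)
  }))
  utils::write.csv(ba, p("bland_altman.csv"), row.names = FALSE)
  report <- res$report
  report$files <- c(written, "fits.csv", "bullseye.csv", "profiles.csv",
                    "bland_altman.csv")
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(p("report.json"))
}
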