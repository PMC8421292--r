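# DTI-versus-STI agreement statistics: axial angular differences,
# Bland-Altman limits of agreement, 17-segment bullseye tables, and
# Kruskal-Wallis rank tests. The difference order is fixed as A - B with
# A = DTI and B = STI throughout the pipeline.

#' Axial angular difference
#'
#' Difference a - b of two axial angles (period 180 deg), wrapped into
#' (-90, 90] by +/-180 deg shifts: the shortest path on the axial circle,
#' which may run through +/-90.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return difference in degrees, in (-90, 90].
#' @examples angularDifference(80, -80)   # -20: through the +/-90 wrap
#' @export
angularDifference <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  d[!is.na(d) & d == -90] <- 90
  d
}

#' Bland-Altman agreement between two angle maps
#'
#' Per-voxel differences are computed with \code{\link{angularDifference}}
#' (A - B); bias is their arithmetic mean, and the 95% limits of agreement
#' are bias -/+ 1.96 SD. A per-voxel (mean, difference) scatter table is
#' included for plotting.
#'
#' @param mapA,mapB 3D numeric arrays (degrees), co-registered.
#' @param mask logical 3D array restricting the comparison.
#' @return list: \code{bias}, \code{sd}, \code{loa.low}, \code{loa.high},
#'   \code{n}, and \code{scatter} (data.frame with columns mean, diff).
#' @export
blandAltman <- function(mapA, mapB, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(mapA))
  sel <- mask & is.finite(mapA) & is.finite(mapB)
  if (!any(sel)) stop("Bland-Altman mask is empty")
  a <- mapA[sel]; b <- mapB[sel]
  d <- angularDifference(a, b)
  bias <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(bias = bias, sd = s,
       loa.low = bias - 1.96 * s, loa.high = bias + 1.96 * s,
       n = length(d),
       scatter = data.frame(mean = (a + b) / 2, diff = d))
}

#' 17-segment bullseye table of two sets of angle maps
#'
#' Per AHA segment and angle type: the arithmetic mean of the wrapped values
#' for each source and the absolute axial difference of the two segment
#' means. A warning is emitted when a segment has substantial mass at both
#' +90 and -90 deg, where arithmetic means of axial data become biased
#' (a circular mean would be needed there).
#'
#' @param mapsA,mapsB \linkS4class{AngleMaps} (A = DTI, B = STI by pipeline
#'   convention).
#' @param labels integer 3D array of AHA labels.
#' @param mask optional logical 3D array further restricting voxels.
#' @return data.frame: segment, angle, meanA, meanB, absDiff, nA, nB.
#' @export
bullseye <- function(mapsA, mapsB, labels, mask = NULL) {
  angles <- c("HA", "TA", "SE", "SA")
  out <- expand.grid(segment = 1:17, angle = angles,
                     stringsAsFactors = FALSE)
  out$meanA <- out$meanB <- out$absDiff <- NA_real_
  out$nA <- out$nB <- 0L
  if (is.null(mask)) mask <- array(TRUE, dim(labels))
  spreadWarned <- FALSE
  for (i in seq_len(nrow(out))) {
    seg <- out$segment[i]
    inSeg <- !is.na(labels) & labels == seg & mask
    if (!any(inSeg)) next
    va <- angleMap(mapsA, out$angle[i])[inSeg]
    vb <- angleMap(mapsB, out$angle[i])[inSeg]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (!length(va) || !length(vb)) next
    wrapHeavy <- function(v) min(mean(v > 75), mean(v < -75)) > 0.05
    if (!spreadWarned && (wrapHeavy(va) || wrapHeavy(vb))) {
      warning("segment values pile up at both +/-90 deg: arithmetic segment means of axial angles are biased near the wrap")
      spreadWarned <- TRUE
    }
    out$meanA[i] <- mean(va)
    out$meanB[i] <- mean(vb)
    out$absDiff[i] <- abs(angularDifference(out$meanA[i], out$meanB[i]))
    out$nA[i] <- length(va); out$nB[i] <- length(vb)
  }
  emptySeg <- unique(out$segment[out$nA == 0L])
  if (length(emptySeg))
    message("bullseye: no voxels in segment(s) ",
            paste(emptySeg, collapse = ", "))
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom (delegated to \code{stats::kruskal.test}). The
#' degenerate case of identical values in every group is defined as H = 0,
#' p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 5).
#' @return list: \code{H}, \code{p.value}, \code{df}, \code{stars}
#'   (significance annotation: "*" for p in (0.01, 0.05], "**" for
#'   p in (0.001, 0.01], "***" below).
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  stopifnot(all(n >= 1L), sum(n) >= 5L)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(list(H = 0, p.value = 1, df = length(groups) - 1L, stars = ""))
  }
  g <- factor(rep(seq_along(groups), times = n))
  kt <- kruskal.test(vals, g)
  p <- kt$p.value
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**" else
           if (p <= 0.05) "*" else ""
  list(H = unname(kt$statistic), p.value = p,
       df = unname(kt$parameter), stars = stars)
}
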