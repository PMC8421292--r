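# Shared fixtures and independent oracles, built once per test run.

# small phantom: same physical geometry as the default, sampled at 300 um
# (so tests stay fast); striation wavelength raised to respect Nyquist
smallSpec <- function(...) {
  phantomSpec(dim = c(48L, 48L, 48L), voxelSize = 300,
              fiberTextureWavelength = 600, gaborSigmaRadial = 200,
              dwiLevels = 1L, ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, build(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

smallTruthFine <- function() fixture("truthFine",
  function() phantomGroundTruth(smallSpec(), 0L))
smallTruthCoarse <- function() fixture("truthCoarse",
  function() phantomGroundTruth(smallSpec(), 1L))

# --- independent oracles -------------------------------------------------

# naive spatial-domain separable convolution with mirror boundary (index
# reflection about the edge sample), written with plain loops and kept
# deliberately independent of the package's convolution code
naiveConvolveAxis <- function(a, kernel, axis) {
  p <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  reflect <- function(i) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- array(0, d)
  for (off in -p:p) {
    k <- kernel[off + p + 1L]
    if (k == 0) next
    idx <- vapply(seq_len(n) - off, reflect, integer(1))
    shifted <- switch(axis, a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
    out <- out + k * shifted
  }
  out
}

naiveTemplateGradient <- function(a) {
  k <- derivativeTemplates()
  g <- array(0, c(dim(a), 3L))
  for (axis in 1:3) {
    comp <- a
    for (ax2 in 1:3) {
      kern <- if (ax2 == axis) k$derivative else k$prefilter
      comp <- naiveConvolveAxis(comp, kern, ax2)
    }
    g[, , , axis] <- comp
  }
  g
}

# brute-force tie-corrected Kruskal-Wallis H from first principles
naiveKruskalH <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  H <- 12 / (N * (N + 1)) *
    sum(mapply(function(s, e) sum(r[s:e])^2 / (e - s + 1), starts, ends)) -
    3 * (N + 1)
  ties <- table(vals)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}

# angle between two axial unit vectors, degrees
axialAngleDeg <- function(a, b) {
  d <- abs(rowSums(a * b))
  acos(pmin(d, 1)) * 180 / pi
}

randomUnitVectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# a random proper rotation matrix
randomRotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
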