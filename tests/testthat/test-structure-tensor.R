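# Structure-tensor branch: derivative templates, gradients, outer products,
# binomial pyramid, eigenanalysis, intensity masks.

test_that("matched 5-tap kernels have the defining moment properties", {
  k <- derivativeTemplates()
  expect_length(k$derivative, 5L)
  expect_length(k$prefilter, 5L)
  expect_equal(sum(k$derivative), 0)                       # kills constants
  expect_equal(sum(k$prefilter), 1)                        # unit DC gain
  expect_equal(k$derivative, -rev(k$derivative))           # antisymmetric
  expect_equal(k$prefilter, rev(k$prefilter))              # symmetric
  # exact unit response on a linear ramp (voxel units)
  expect_equal(-sum((-2:2) * k$derivative), 1)
  # 5 taps at 150 um cover a 750 um cube per axis
  expect_equal(5 * 150, 750)
})

test_that("template gradient is exact on ramps and zero on constants", {
  d <- c(9L, 8L, 7L)
  const <- ScalarVolume(array(4.2, d), 150)
  expect_equal(max(abs(imageGradient(const))), 0, tolerance = 1e-12)
  ramp <- ScalarVolume(array(rep(seq_len(d[1]), times = prod(d[2:3])), d), 150)
  g <- imageGradient(ramp)
  inner <- g[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2), ]
  expect_equal(max(abs(inner[, , , 1] - 1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(inner[, , , 2:3])), 0, tolerance = 1e-10)
})

test_that("FFT convolution path matches the naive spatial oracle", {
  set.seed(7)
  for (d in list(c(16L, 16L, 16L), c(24L, 17L, 11L))) {
    a <- array(rnorm(prod(d)), d)
    g <- imageGradient(ScalarVolume(a, 150), method = "fft")
    gd <- imageGradient(ScalarVolume(a, 150), method = "direct")
    go <- naiveTemplateGradient(a)
    scale <- max(abs(go))
    expect_lt(max(abs(g - go)), 1e-8 * scale)
    expect_lt(max(abs(gd - go)), 1e-12 * scale)
  }
})

test_that("gradient of an axial cosine is axial with the analytic profile", {
  d <- c(8L, 8L, 32L)
  lam <- 8  # voxels
  z <- seq_len(d[3])
  vol <- ScalarVolume(
    array(rep(cos(2 * pi * z / lam), each = d[1] * d[2]), d), 150)
  g <- imageGradient(vol)
  inner <- 3:(d[3] - 2)
  expect_lt(max(abs(g[, , inner, 1:2])), 1e-10)
  gz <- g[4, 4, inner, 3]
  ref <- -sin(2 * pi * z[inner] / lam)
  gain <- sum(gz * ref) / sum(ref^2)
  expect_gt(gain, 0)
  # the exact discrete transfer of the antisymmetric 5-tap at this frequency
  kd <- derivativeTemplates()$derivative
  omega <- 2 * pi / lam
  expect_equal(gain, -sum(kd * sin(omega * (-2:2))), tolerance = 1e-10)
  # and it approximates the continuum derivative gain within kernel droop
  expect_equal(gain, omega, tolerance = 0.25)
  expect_lt(max(abs(gz - gain * ref)), 1e-8)
})

test_that("gradient refuses volumes thinner than the template", {
  expect_error(imageGradient(ScalarVolume(array(0, c(4, 8, 8)), 150)),
               "at least 5")
})

test_that("structure tensor is the gradient outer product", {
  g <- array(0, c(1, 1, 1, 3))
  g[1, 1, 1, ] <- c(0, 0, 1)
  tf <- structureTensorField(g, 150)
  expect_equal(as.vector(tensorComps(tf)), c(0, 0, 1, 0, 0, 0))
  g[1, 1, 1, ] <- c(1, 1, 0) / sqrt(2)
  tf <- structureTensorField(g, 150)
  expect_equal(as.vector(tensorComps(tf)), c(0.5, 0.5, 0, 0.5, 0, 0))
  # rank-1 identity: lambda1 = |g|^2, lambda2 = lambda3 = 0
  set.seed(1)
  g[1, 1, 1, ] <- rnorm(3)
  tf <- structureTensorField(g, 150)
  eig <- stEigenanalysis(tf, array(TRUE, c(1, 1, 1)))
  ev <- as.vector(eigenValues(eig))
  expect_equal(ev[1], sum(g^2), tolerance = 1e-12)
  expect_equal(ev[2:3], c(0, 0), tolerance = 1e-12)
})

test_that("pyramid extent arithmetic reproduces the two-level grid mapping", {
  expect_identical(pyramidDim(c(731L, 665L, 532L), 2), c(183L, 166L, 133L))
  expect_identical(pyramidDim(c(96L, 96L, 96L), 2), c(24L, 24L, 24L))
  expect_identical(pyramidDim(10L, 0), 10L)
  expect_error(pyramidDim(2L, 3))
})

test_that("binomial pyramid: DC gain one, PSD and trace preserved", {
  d <- c(12L, 12L, 12L)
  comps <- array(0, c(d, 6L))
  comps[, , , 1:3] <- 2  # constant isotropic tensor field
  tf <- TensorField(comps, 150)
  out <- binomialPyramid(tf, 2L)
  expect_equal(voxelSize(out), 600)
  expect_identical(gridDim(out), c(3L, 3L, 3L))
  expect_equal(max(abs(tensorComps(out)[, , , 1:3] - 2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tensorComps(out)[, , , 4:6])), 0, tolerance = 1e-12)

  # periodic random rank-1 field: smoothing keeps tensors PSD and the
  # interior mean trace nearly unchanged
  set.seed(42)
  d <- c(16L, 16L, 16L)
  th <- array(2 * pi * sin(2 * pi * rep(seq_len(d[1]),
                                        times = prod(d[2:3])) / 16), d)
  g <- array(0, c(d, 3L))
  g[, , , 1] <- cos(th); g[, , , 2] <- sin(th)
  tf <- binomialPyramid(structureTensorField(g, 150), 1L)
  comps <- tensorComps(tf)
  n <- prod(dim(comps)[1:3])
  minEig <- vapply(seq_len(n), function(i) {
    flat <- matrix(comps, ncol = 6)[i, ]
    m <- matrix(flat[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  tr <- comps[, , , 1] + comps[, , , 2] + comps[, , , 3]
  expect_gt(min(minEig), -1e-10 * max(tr))
  expect_lt(abs(mean(tr[2:7, 2:7, 2:7]) - 1), 0.01)   # |g| = 1 everywhere
})

test_that("smoothed rank-1 tensors keep the generating direction", {
  # slowly rotating in-plane direction field
  d <- c(24L, 24L, 8L)
  x <- seq_len(d[1])
  th <- 0.03 * x  # ~1.7 deg per voxel
  g <- array(0, c(d, 3L))
  for (i in x) {
    g[i, , , 1] <- cos(th[i]); g[i, , , 2] <- sin(th[i])
  }
  sm <- binomialPyramid(structureTensorField(g, 150), 1L)
  eig <- stEigenanalysis(sm, array(TRUE, gridDim(sm)))
  v1 <- matrix(eig@vectors[, , , , 1], ncol = 3)
  keep <- seq(1, d[1], by = 2)[2:10]     # interior coarse samples
  truth <- cbind(cos(th[keep]), sin(th[keep]), 0)
  idx <- as.vector(outer(2:10, (seq_len(prod(gridDim(sm)[2:3])) - 1) *
                           gridDim(sm)[1], `+`))
  err <- axialAngleDeg(v1[idx, , drop = FALSE],
                       truth[rep(seq_len(9), times = prod(gridDim(sm)[2:3])), ])
  expect_lt(max(err), 2)
})

test_that("eigenanalysis orders, assigns STI roles and flags degeneracy", {
  comps <- array(0, c(2, 1, 1, 6))
  comps[1, 1, 1, ] <- c(3, 2, 1, 0, 0, 0)   # diag(3, 2, 1)
  comps[2, 1, 1, ] <- c(1, 1, 1, 0, 0, 0)   # isotropic
  eig <- stEigenanalysis(TensorField(comps, 600), array(TRUE, c(2, 1, 1)))
  expect_equal(eig@values[1, 1, 1, ], c(3, 2, 1))
  expect_equal(abs(eig@vectors[1, 1, 1, , 1]), c(1, 0, 0))  # sheet normal x
  expect_equal(abs(eig@vectors[1, 1, 1, , 3]), c(0, 0, 1))  # fiber z
  expect_identical(unname(eig@roles[c("fiber", "sheetNormal")]), c(3L, 1L))
  expect_true(eig@degenerate[2, 1, 1])
  expect_false(eig@degenerate[1, 1, 1])
  # orthonormality of returned triads
  V <- eig@vectors[1, 1, 1, , ]
  expect_equal(crossprod(V), diag(3), tolerance = 1e-8)
})

test_that("eigen decomposition is deterministic and masks propagate", {
  set.seed(3)
  d <- c(5L, 4L, 3L)
  g <- array(rnorm(prod(d) * 3), c(d, 3L))
  tf <- binomialPyramid(structureTensorField(g, 150), 0L)
  mask <- array(runif(prod(d)) > 0.4, d)
  e1 <- stEigenanalysis(tf, mask)
  e2 <- stEigenanalysis(tf, mask)
  expect_identical(e1@vectors, e2@vectors)
  expect_true(all(is.na(e1@values[!mask])))
  expect_true(all(is.finite(e1@values[mask])))
})

test_that("gradient and eigenvectors are equivariant under 90-deg rotation", {
  set.seed(11)
  d <- 12L
  a <- array(rnorm(d^3), c(d, d, d))
  # rotate +90 deg about z: (x, y) -> (-y, x)
  rot <- function(v) aperm(v, c(2, 1, 3))[d:1, , , drop = FALSE]
  g <- imageGradient(ScalarVolume(a, 150))
  gr <- imageGradient(ScalarVolume(rot(a), 150))
  expect_equal(gr[, , , 1], -rot(g[, , , 2]), tolerance = 1e-12)
  expect_equal(gr[, , , 2], rot(g[, , , 1]), tolerance = 1e-12)
  expect_equal(gr[, , , 3], rot(g[, , , 3]), tolerance = 1e-12)
})

test_that("intensity mask applies inclusive cutoffs and warns when empty", {
  v <- ScalarVolume(array(5, c(3, 3, 3)), 150)
  expect_message(m <- intensityMask(v, 0, 10), "27 of 27")
  expect_true(all(m))
  expect_warning(expect_message(m2 <- intensityMask(v, 6, 10)), "empty")
  expect_false(any(m2))
  expect_error(intensityMask(v, 10, 0))
  # constructed threshold case: background 0, wall in [80, 120]
  tr <- smallTruthFine()
  vals <- array(0, gridDim(tr))
  vals[tr@wallMask] <- 100
  vol <- ScalarVolume(vals, 300)
  expect_message(m3 <- intensityMask(vol, 40, 200))
  expect_identical(m3, tr@wallMask)
})
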