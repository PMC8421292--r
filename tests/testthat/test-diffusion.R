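# Diffusion-tensor branch: log-linear fit, FA/trace, DTI roles, masks,
# noise behaviour.

# build a tiny DWISet from a single known tensor replicated on a grid
.dwiFromTensor <- function(D, S0 = 100, b = 1000, d = c(3L, 3L, 3L),
                           dirs = NULL) {
  if (is.null(dirs))
    dirs <- matrix(c(1, 1, 0, 1, -1, 0, 1, 0, 1, 1, 0, -1, 0, 1, 1,
                     0, 1, -1), ncol = 3, byrow = TRUE) / sqrt(2)
  vols <- array(0, c(d, 3L + nrow(dirs)))
  for (k in 1:3) vols[, , , k] <- S0
  for (j in seq_len(nrow(dirs))) {
    g <- dirs[j, ]
    vols[, , , 3L + j] <- S0 * exp(-b * drop(t(g) %*% D %*% g))
  }
  DWISet(vols, gradients = rbind(matrix(0, 3, 3), dirs),
         bvalues = c(0, 0, 0, rep(b, nrow(dirs))), voxelSize = 600)
}

.tensorAt <- function(tf, i = 1L) {
  v6 <- matrix(tensorComps(tf), ncol = 6)[i, ]
  matrix(v6[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
}

test_that("noiseless fit recovers the generating tensor to solver precision", {
  set.seed(5)
  for (rep in 1:5) {
    R <- randomRotation()
    D <- R %*% diag(c(1.5e-3, 0.6e-3, 0.4e-3)) %*% t(R)
    fit <- fitDTI(.dwiFromTensor(D))
    expect_lt(max(abs(.tensorAt(fit) - D)), 1e-10 * max(abs(D)))
  }
  # b0-level signal in all directions: zero tensor
  dwi0 <- .dwiFromTensor(diag(0, 3))
  expect_lt(max(abs(.tensorAt(fitDTI(dwi0)))), 1e-12)
})

test_that("round trip through the phantom DWI synthesis is exact", {
  spec <- smallSpec()
  tr <- smallTruthCoarse()
  dwi <- synthesizeDWI(tr, spec)
  fit <- fitDTI(dwi, tr@wallMask)
  w <- which(tr@wallMask)
  f <- matrix(tr@fiber, ncol = 3)[w, ]
  s <- matrix(tr@sheetInPlane, ncol = 3)[w, ]
  n <- matrix(tr@sheetNormal, ncol = 3)[w, ]
  lam <- spec@diffusivities
  comps <- matrix(tensorComps(fit), ncol = 6)[w, ]
  Dtruth <- cbind(
    lam[1] * f[, 1]^2 + lam[2] * s[, 1]^2 + lam[3] * n[, 1]^2,
    lam[1] * f[, 2]^2 + lam[2] * s[, 2]^2 + lam[3] * n[, 2]^2,
    lam[1] * f[, 3]^2 + lam[2] * s[, 3]^2 + lam[3] * n[, 3]^2,
    lam[1] * f[, 1] * f[, 2] + lam[2] * s[, 1] * s[, 2] + lam[3] * n[, 1] * n[, 2],
    lam[1] * f[, 1] * f[, 3] + lam[2] * s[, 1] * s[, 3] + lam[3] * n[, 1] * n[, 3],
    lam[1] * f[, 2] * f[, 3] + lam[2] * s[, 2] * s[, 3] + lam[3] * n[, 2] * n[, 3])
  expect_lt(max(abs(comps - Dtruth)), 1e-10 * max(abs(Dtruth)))
})

test_that("FA and trace match the closed-form eigenvalue expressions", {
  mk <- function(lam) {
    comps <- array(0, c(1, 1, 1, 6)); comps[1, 1, 1, 1:3] <- lam
    TensorField(comps, 600)
  }
  s <- dtiScalars(mk(c(1.5e-3, 0.5e-3, 0.5e-3)))
  expect_equal(values3d(s$FA)[1], 0.6030, tolerance = 1e-4)
  expect_equal(values3d(s$trace)[1], 2.5e-3, tolerance = 1e-12)
  s <- dtiScalars(mk(c(2e-3, 2e-3, 2e-3)))       # isotropic
  expect_equal(values3d(s$FA)[1], 0)
  expect_equal(values3d(s$trace)[1], 6e-3)
  s <- dtiScalars(mk(c(1, 0, 0)))                # stick limit
  expect_equal(values3d(s$FA)[1], 1, tolerance = 1e-12)
  s <- dtiScalars(mk(c(0, 0, 0)))                # zero tensor: FA defined 0
  expect_equal(values3d(s$FA)[1], 0)
})

test_that("FA is invariant under tensor rotation", {
  set.seed(9)
  lam <- c(1.7e-3, 0.8e-3, 0.3e-3)
  base <- dtiScalars({
    comps <- array(0, c(1, 1, 1, 6)); comps[1, 1, 1, 1:3] <- lam
    TensorField(comps, 600)
  })
  for (rep in 1:10) {
    R <- randomRotation()
    D <- R %*% diag(lam) %*% t(R)
    comps <- array(0, c(1, 1, 1, 6))
    comps[1, 1, 1, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    s <- dtiScalars(TensorField(comps, 600))
    expect_lt(abs(values3d(s$FA)[1] - values3d(base$FA)[1]), 1e-10)
  }
})

test_that("DTI role convention mirrors the STI one on the same tensor", {
  comps <- array(0, c(1, 1, 1, 6))
  comps[1, 1, 1, 1:3] <- c(3e-4, 2e-4, 1e-4)
  tf <- TensorField(comps, 600)
  mask <- array(TRUE, c(1, 1, 1))
  dti <- dtiEigenanalysis(tf, mask)
  sti <- stEigenanalysis(tf, mask)
  expect_equal(abs(drop(roleVector(dti, "fiber"))), c(1, 0, 0))
  expect_equal(abs(drop(roleVector(dti, "sheetNormal"))), c(0, 0, 1))
  # same decomposition, swapped roles
  expect_equal(drop(roleVector(sti, "fiber")),
               drop(roleVector(dti, "sheetNormal")))
  expect_equal(drop(roleVector(sti, "sheetNormal")),
               drop(roleVector(dti, "fiber")))
})

test_that("noiseless phantom fit returns the truth fiber to < 0.1 degree", {
  spec <- smallSpec()
  tr <- smallTruthCoarse()
  fit <- fitDTI(synthesizeDWI(tr, spec), tr@wallMask)
  eig <- dtiEigenanalysis(fit, tr@truthMask)
  w <- which(tr@truthMask)
  err <- axialAngleDeg(matrix(tr@fiber, ncol = 3)[w, ],
                       matrix(roleVector(eig, "fiber"), ncol = 3)[w, ])
  expect_lt(max(err), 0.1)
})

test_that("non-positive signals are excluded and logged", {
  D <- diag(c(1.5e-3, 0.5e-3, 0.5e-3))
  dwi <- .dwiFromTensor(D, d = c(2L, 2L, 2L))
  dwi@volumes[1, 1, 1, 5] <- 0
  expect_message(fit <- fitDTI(dwi), "1 masked voxels")
  expect_true(all(is.na(tensorComps(fit)[1, 1, 1, ])))
  expect_false(anyNA(tensorComps(fit)[2, 1, 1, ]))
})

test_that("FA/trace/b0 mask windows combine and warn when empty", {
  spec <- smallSpec()
  tr <- smallTruthCoarse()
  fit <- fitDTI(synthesizeDWI(tr, spec))
  scal <- dtiScalars(fit)
  b0 <- ScalarVolume(apply(synthesizeDWI(tr, spec)@volumes[, , , 1:3],
                           1:3, mean), 600)
  # wall FA ~ 0.61, background isotropic FA ~ 0: the FA window separates them
  expect_message(m <- dtiMask(scal, b0, faCutoffs = c(0.05, 0.95)))
  expect_true(all(m[tr@truthMask]))
  expect_false(any(m[erodeMask(!tr@wallMask, 2L)]))
  expect_message(mAll <- dtiMask(scal, b0))
  expect_true(all(mAll))
  expect_warning(expect_message(mE <- dtiMask(scal, b0,
                                              faCutoffs = c(1.1, 2))),
                 "empty")
  expect_false(any(mE))
  expect_error(dtiMask(scal, b0, faCutoffs = c(0.9, 0.1)))
})

test_that("fiber angular error shrinks as SNR doubles from 10 to 40", {
  tr <- smallTruthCoarse()
  w <- which(tr@truthMask)
  expect_gt(length(w), 200)
  fT <- matrix(tr@fiber, ncol = 3)[w, ]
  med <- sapply(c(10, 20, 40), function(snr) {
    spec <- smallSpec(ricianSigma = 100 / snr, seed = 11L)
    fit <- fitDTI(synthesizeDWI(tr, spec), tr@wallMask)
    eig <- dtiEigenanalysis(fit, tr@truthMask)
    fE <- matrix(roleVector(eig, "fiber"), ncol = 3)[w, ]
    ok <- is.finite(rowSums(fE))
    median(axialAngleDeg(fT[ok, ], fE[ok, ]))
  })
  expect_true(all(diff(med) < 0))
})
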