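# Regional analysis: transmural depth, AHA-17 labels, transmural profiles
# with local unwrap, and weighted linear fits.

test_that("depth on the analytic annulus matches (r - rin)/(rout - rin)", {
  tr <- smallTruthFine()
  spec <- smallSpec()
  x <- transmuralDepth(tr@wallMask, tr@cavityMask, tr@backgroundMask,
                       spec@voxelSize)
  w <- which(tr@wallMask)
  err <- x[w] - tr@depth[w]
  halfVoxel <- (spec@voxelSize / 1000 / 2) /
    (spec@outerRadius - spec@innerRadius)
  expect_lt(max(abs(err)), halfVoxel)
  # scale accuracy: regression of computed on analytic depth is ~identity
  sc <- coef(lm(x[w] ~ tr@depth[w]))
  expect_lt(abs(sc[2] - 1), 0.02)
  expect_true(all(is.na(x[!tr@wallMask])))
})

test_that("depth is monotone along outward radial rays", {
  tr <- smallTruthFine()
  spec <- smallSpec()
  x <- transmuralDepth(tr@wallMask, tr@cavityMask, tr@backgroundMask,
                       spec@voxelSize)
  mid <- dim(x)[3] %/% 2
  ctr <- (dim(x)[1] + 1) / 2
  ray <- x[ceiling(ctr):dim(x)[1], ceiling(ctr), mid]
  ray <- ray[!is.na(ray)]
  expect_true(all(diff(ray) > -1e-12))
})

test_that("surface-layer convention pins depth to exactly 0 and 1", {
  tr <- smallTruthFine()
  spec <- smallSpec()
  wall <- tr@wallMask
  endoLayer <- wall & !erodeMask(wall | tr@cavityMask, 1L)  # inner boundary
  epiLayer <- wall & !erodeMask(wall | tr@backgroundMask, 1L)
  endoLayer <- endoLayer & !epiLayer
  x <- transmuralDepth(wall, endoLayer, epiLayer, spec@voxelSize, offset = 0)
  expect_true(all(x[endoLayer] == 0))
  expect_true(all(x[epiLayer] == 1))
  expect_error(transmuralDepth(wall, array(FALSE, dim(wall)), epiLayer,
                               spec@voxelSize))
})

test_that("AHA labels partition the mask with the standard sector layout", {
  tr <- smallTruthCoarse()
  spec <- smallSpec()
  lab <- aha17Labels(tr@wallMask, tr@voxelSize, rvInsertionAngle = 0,
                     origin = tr@origin)
  expect_true(all(!is.na(lab[tr@wallMask])))
  expect_true(all(is.na(lab[!tr@wallMask])))
  expect_setequal(unique(lab[tr@wallMask]), 1:17)
  # every voxel has exactly one label: counts sum to the mask count
  expect_equal(sum(table(lab[tr@wallMask])), sum(tr@wallMask))
  # uniform annulus: the six basal sectors are equally populated within 2%
  # (checked at fine resolution, where angular quantization is negligible)
  trF <- smallTruthFine()
  labF <- aha17Labels(trF@wallMask, smallSpec()@voxelSize, 0, trF@origin)
  basal <- table(labF[trF@wallMask & !is.na(labF) & labF <= 6])
  expect_lt(diff(range(basal)) / mean(basal), 0.02)
  # thin masks are rejected
  thin <- tr@wallMask; thin[, , -(1:2)] <- FALSE
  expect_error(aha17Labels(thin, tr@voxelSize), "3 slices")
})

test_that("rotating the reference angle by 60 deg permutes basal labels cyclically", {
  tr <- smallTruthCoarse()
  lab0 <- aha17Labels(tr@wallMask, tr@voxelSize, 0, tr@origin)
  lab60 <- aha17Labels(tr@wallMask, tr@voxelSize, 60, tr@origin)
  w <- which(tr@wallMask & lab0 <= 12)
  ring <- ifelse(lab0[w] <= 6, 0L, 6L)
  expected <- ring + ((lab0[w] - ring - 1L + 5L) %% 6L) + 1L
  expect_identical(lab60[w], expected)
  # apical 90-deg sectors rotate cyclically too
  lab90 <- aha17Labels(tr@wallMask, tr@voxelSize, 90, tr@origin)
  wA <- which(tr@wallMask & lab0 >= 13 & lab0 <= 16)
  expectedA <- 13L + ((lab0[wA] - 13L + 3L) %% 4L)
  expect_identical(lab90[wA], expectedA)
  # the apex cap is unaffected by the reference angle
  expect_identical(which(lab0 == 17L), which(lab60 == 17L))
})

test_that("transmural profile: constant maps, analytic law and bin bookkeeping", {
  tr <- smallTruthCoarse()
  spec <- smallSpec()
  depth <- tr@depth
  lab <- tr@labels
  const <- array(NA_real_, gridDim(tr)); const[tr@wallMask] <- 10
  pr <- transmuralProfile(const, depth, lab, 7L)
  expect_equal(nrow(pr), 200L)
  expect_equal(pr$bin_x[1], 0.0025)
  ok <- pr$n > 0
  expect_true(all(pr$mean[ok] == 10))
  expect_true(all(pr$sd[ok] == 0))
  expect_equal(sum(pr$n), sum(lab == 7L & tr@wallMask, na.rm = TRUE))
  # analytic HA profile: endo bin ~ +60, epi bin ~ -60, linear in between
  ha <- tr@angles$HA
  prh <- transmuralProfile(ha, depth, NULL, NULL)
  okh <- which(prh$n > 0)
  expect_equal(prh$mean[okh[1]],
               spec@haEndo + (spec@haEpi - spec@haEndo) * prh$bin_x[okh[1]],
               tolerance = 2)
  expect_equal(prh$mean[okh[length(okh)]],
               spec@haEndo + (spec@haEpi - spec@haEndo) *
                 prh$bin_x[okh[length(okh)]],
               tolerance = 2)
  expect_error(transmuralProfile(ha, depth, lab, 99L), "absent")
})

test_that("local unwrap keeps profiles continuous through +/-90 deg", {
  # true angle runs 70 -> 110 deg across the wall; stored wrapped to [-90, 90]
  n <- 4000L
  x <- runif(n)
  trueAng <- 70 + 40 * x + rnorm(n, 0, 2)
  wrapped <- ((trueAng + 90) %% 180) - 90
  dim(wrapped) <- c(n, 1, 1)
  depth <- array(x, c(n, 1, 1))
  pr <- transmuralProfile(wrapped, depth, NULL, NULL, binWidth = 0.02)
  ok <- which(pr$n > 0)
  jumps <- abs(diff(pr$mean[ok]))
  expect_lt(max(jumps), 90)
  # the unwrapped profile tracks the true line (modulo 180)
  fit <- linearFit(pr)
  expect_equal(abs(fit$slope), 40, tolerance = 4)
})

test_that("unwrap is idempotent on already-continuous profiles", {
  n <- 3000L
  x <- runif(n)
  ang <- 50 - 100 * x             # stays within [-90, 90]
  m <- array(ang, c(n, 1, 1)); depth <- array(x, c(n, 1, 1))
  pr <- transmuralProfile(m, depth, NULL, NULL, binWidth = 0.02)
  ok <- pr$n > 0
  # bin means equal plain per-bin averages (no shift applied anywhere)
  bin <- pmin(pmax(floor(x / 0.02), 0), 49) + 1
  plain <- tapply(ang, bin, mean)
  expect_equal(unname(pr$mean[ok]), unname(as.vector(plain)),
               tolerance = 1e-12)
})

test_that("adding a small constant shifts the intercept, not the slope", {
  tr <- smallTruthCoarse()
  ha <- tr@angles$HA * 0.4          # keep |angle| < 60 so +20 stays in range
  depth <- tr@depth
  pr1 <- transmuralProfile(ha, depth, NULL, NULL)
  pr2 <- transmuralProfile(ha + 20, depth, NULL, NULL)
  f1 <- linearFit(pr1); f2 <- linearFit(pr2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
  expect_equal(f2$intercept - f1$intercept, 20, tolerance = 1e-6)
})

test_that("linear fit: exact line, constant profile, and degenerate input", {
  x <- (seq_len(200) - 0.5) * 0.005
  pr <- data.frame(bin_x = x, mean = 60 - 120 * x, sd = 0, n = 50L)
  f <- linearFit(pr)
  expect_equal(f$slope, -120)
  expect_equal(f$intercept, 60)
  expect_equal(f$r.squared, 1)
  prc <- data.frame(bin_x = x, mean = rep(7, 200), sd = 0, n = 50L)
  fc <- linearFit(prc)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r.squared, 0)
  expect_error(linearFit(data.frame(bin_x = x[1:2], mean = c(1, 2), sd = 0,
                                    n = c(5L, 5L))), "fewer than 3")
})
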