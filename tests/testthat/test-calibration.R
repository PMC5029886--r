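test_that("BOLD fraction maps R2* changes to signal fractions", {
  expect_equal(boldFraction(0), 0)
  expect_equal(boldFraction(-1, 0.030), expm1(0.030), tolerance = 1e-12)
  expect_equal(round(boldFraction(-1, 0.030), 5), 0.03045)
  expect_gt(boldFraction(-0.5), 0)
  expect_lt(boldFraction(0.5), 0)
  # small-signal limit within 2% for |dR2*| <= 1
  d <- seq(-1, 1, by = 0.05); d <- d[d != 0]
  expect_true(all(abs(boldFraction(d) / (-0.030 * d) - 1) < 0.02))
})

test_that("gas curve is zero for b = 0 and reproduces the forward model", {
  cond <- studyConditions()
  p <- modelParams()
  E <- seq(0.05, 0.95, by = 0.05)
  m0 <- gasCurve(E, 0, 1.5, 1, cond$cao2HC, cond$cao20, p)
  expect_true(all(m0[is.finite(m0)] == 0))
  # positive finite M on a sub-interval for a GM-like hypercapnic response
  r <- gmLikeResponses(conditions = cond)
  mHC <- gasCurve(E, boldFraction(r$dR2sHC), r$fHC, 1, cond$cao2HC,
                  cond$cao20, p)
  expect_true(any(is.finite(mHC) & mHC > 0))
  # forward/inverse identity: M(E_true) = M_true to 1e-12
  for (Mv in c(0.03, 0.05, 0.1)) for (Ev in c(0.25, 0.4, 0.55)) {
    dr <- forwardDeltaR2star(Mv, Ev, 1.5, 1, cond$cao2HC, cond$cao20, p)
    expect_equal(gasCurve(Ev, boldFraction(dr), 1.5, 1, cond$cao2HC,
                          cond$cao20, p), Mv, tolerance = 1e-12)
  }
})

test_that("forward dR2* is zero without a response and monotone in M", {
  cond <- studyConditions()
  p <- modelParams()
  # f = 1 and identical O2 content: d = 1, no response
  expect_equal(forwardDeltaR2star(0.07, 0.4, 1, 1, cond$cao20, cond$cao20, p),
               0, tolerance = 1e-15)
  Ms <- seq(0.02, 0.12, by = 0.02)
  drs <- vapply(Ms, function(m)
    forwardDeltaR2star(m, 0.4, 1.5, 1, cond$cao2HC, cond$cao20, p),
    numeric(1))
  expect_true(all(diff(abs(drs)) > 0))
})

test_that("solver recovers generating (M, OEF) and honors homogeneity", {
  cond <- studyConditions()
  p <- modelParams()
  r <- gmLikeResponses(M = 0.05, oef = 0.40, fHC = 1.5, conditions = cond)
  s <- solveVoxel(r, p)
  expect_true(s$solved)
  expect_equal(s$M, 0.05, tolerance = 1e-4)
  expect_equal(s$oef, 0.40, tolerance = 1e-4)
  # the brute-force grid oracle agrees within its resolution
  expect_equal(bruteForceOEF(r, p, step = 1e-4), s$oef, tolerance = 2e-4)
  # scaling both BOLD fractions by c scales M by c, OEF unchanged
  cc <- 1.7
  r2 <- r
  r2$dR2sHC <- -log(1 + cc * boldFraction(r$dR2sHC)) / p$teRef
  r2$dR2sHO <- -log(1 + cc * boldFraction(r$dR2sHO)) / p$teRef
  s2 <- solveVoxel(r2, p)
  expect_equal(s2$M, cc * s$M, tolerance = 1e-3)
  expect_equal(s2$oef, s$oef, tolerance = 1e-4)
  # non-intersecting curves (flipped HO response sign): no solution
  r3 <- r; r3$dR2sHO <- -r3$dR2sHO
  s3 <- solveVoxel(r3, p)
  expect_false(s3$solved)
  expect_true(is.na(s3$M))
})

test_that("O2 delivery and CMRO2 are the stated products", {
  expect_equal(o2Delivery(0, 20), 0)
  expect_equal(o2Delivery(50, 20, 44.6), 446)
  expect_equal(o2Delivery(100, 20, 44.6), 2 * o2Delivery(50, 20, 44.6))
  expect_equal(cmro2(0, 377), 0)
  expect_equal(cmro2(0.37, 377), 139.5, tolerance = 0.01)
  oefs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(cmro2(oefs, 377)) > 0))
})

test_that("map-level solve counts detection and masks ROI averages", {
  cond <- studyConditions()
  p <- modelParams()
  dm <- c(10, 10, 1)
  set.seed(3)
  M <- array(runif(100, 0.03, 0.08), dm)
  E <- array(runif(100, 0.3, 0.5), dm)
  fHC <- array(runif(100, 1.3, 1.7), dm)
  dHC <- forwardDeltaR2star(M, E, fHC, 1, cond$cao2HC, cond$cao20, p)
  dHO <- forwardDeltaR2star(M, E, 1, 1, cond$cao2HO, cond$cao20, p)
  # give 10 of 100 voxels non-intersecting curves
  dHO[1:10] <- -dHO[1:10]
  resp <- list(cbf0 = array(50, dm), fHC = fHC, fHO = array(1, dm),
               dR2sHC = dHC, dR2sHO = dHO,
               cao20 = cond$cao20, cao2HC = cond$cao2HC,
               cao2HO = cond$cao2HO)
  sol <- solveMap(resp, array(TRUE, dm), p)
  expect_equal(sol$detectionRate, 90)
  expect_equal(sum(sol$solved), 90)
  expect_equal(sol$M[sol$solved], M[sol$solved], tolerance = 1e-4)
  # CMRO2 = OEF x delivery exactly for every solved voxel
  expect_equal(sol$cmro2[sol$solved],
               (sol$oef * sol$delivery)[sol$solved], tolerance = 1e-12)
  expect_error(solveMap(resp, array(FALSE, dm), p), "empty")
})

test_that("ROI weighted average honors weights, cutoffs and exclusions", {
  dm <- c(2, 2, 1)
  map <- array(c(1, 3, 100, 7), dm)
  gm <- array(c(0.25, 0.75, 0.49, 0.8), dm)
  # constant map: the constant, regardless of weights
  expect_equal(roiWeightedAverage(array(5, dm), array(0.6, dm)), 5)
  # hand weighted mean over two eligible voxels with weights {1, 3}
  m2 <- array(c(1, 3, 0, 0), dm)
  g2 <- array(c(0.5 * 0.5, 1.5 * 0.5, 0.1, 0.1), dm)  # weights 1 and 3 (x0.25)
  expect_equal(roiWeightedAverage(m2, g2, gmCutoff = 0.25),
               (1 * 0.25 + 3 * 0.75) / (0.25 + 0.75))
  # GM probability 0.49 is ignored
  expect_equal(roiWeightedAverage(map, gm),
               (3 * 0.75 + 7 * 0.8) / (0.75 + 0.8))
  # excluded voxels never contribute
  inc <- array(c(TRUE, FALSE, TRUE, TRUE), dm)
  expect_equal(roiWeightedAverage(map, gm, include = inc), 7)
  expect_error(roiWeightedAverage(map, array(0.1, dm)), "empty ROI")
})
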