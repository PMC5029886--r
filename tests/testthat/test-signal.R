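test_that("R2*/S0 estimation exactly inverts the two-echo decay model", {
  g <- acquisitionGeometry()
  s1 <- 100 * exp(-g$te1 * 25); s2 <- 100 * exp(-g$te2 * 25)
  est <- estimateR2star(s1, s2, g)
  expect_equal(est$r2star, 25, tolerance = 1e-12)
  expect_equal(est$s0, 100, tolerance = 1e-12)
  est2 <- estimateR2star(80, 80, g)
  expect_equal(est2$r2star, 0)
  expect_equal(est2$s0, 80)
  # property: random positive pairs reproduce the first echo exactly
  set.seed(1)
  a <- runif(200, 10, 200); b <- runif(200, 5, 199)
  e <- estimateR2star(a, b, g)
  expect_equal(e$s0 * exp(-g$te1 * e$r2star), a, tolerance = 1e-12)
  expect_true(all(is.na(unlist(suppressWarnings(estimateR2star(-1, 5, g))))))
})

test_that("design matrix has the documented structure and full rank", {
  p <- makeDefaultParadigm()
  st <- noiselessStudy()$study
  frames <- frameInfo(st$series)
  X <- buildDesign(p, frames)
  expect_equal(nrow(X), 524)       # 262 TRs x 2 echoes
  expect_equal(ncol(X), 15)        # 4 baseline + 8 response + 3 drift
  expect_equal(qr(X)$rank, 15)
  expect_equal(sum(grepl("^e[12]_(label|control)$", colnames(X))), 4)
  expect_equal(sum(grepl("_(HC|HO)$", colnames(X))), 8)
  expect_equal(sum(grepl("^drift", colnames(X))), 3)
  # gas blocks after the last acquired frame leave all-zero response
  # columns, which must be reported as rank deficient
  p0 <- gasParadigm(1080, rbind(c(1079.0, 0.5)), rbind(c(1078.0, 0.5)))
  expect_error(suppressWarnings(buildDesign(p0, frames)), "rank-deficient")
})

test_that("GLM recovers channel levels exactly on noiseless data", {
  fx <- noiselessStudy()
  st <- fx$study
  X <- buildDesign(st$paradigm, frameInfo(st$series))
  glm <- fitGLM(st$series, X)
  expect_true(all(glm$sigma2 < 1e-12))
  # injected effect amplitude: recovered within 1e-6
  dat <- seriesData(st$series)
  rHC <- gasRegressor(st$paradigm, "hc")(frameInfo(st$series)$time)
  sel <- frameInfo(st$series)$echo == 2 &
         frameInfo(st$series)$state == "control"
  dat[3, 3, 2, sel] <- dat[3, 3, 2, sel] + 5 * rHC[sel]
  s2 <- new("DualEchoSeries", data = dat, frames = frameInfo(st$series),
            geometry = geometry(st$series))
  g2 <- fitGLM(s2, X)
  d <- g2$coef[, "e2_control_HC"] - glm$coef[, "e2_control_HC"]
  expect_equal(array(d, c(6, 6, 3))[3, 3, 2], 5, tolerance = 1e-6)
  # pure drift series fits with zero response effects
  nf <- nrow(frameInfo(st$series))
  drift <- 50 + 3 * poly(frameInfo(st$series)$time, 3) %*% c(1, 1, 1)
  dd <- array(rep(as.numeric(drift), each = prod(c(6, 6, 3))),
              c(6, 6, 3, nf))
  s3 <- new("DualEchoSeries", data = dd, frames = frameInfo(st$series),
            geometry = geometry(st$series))
  g3 <- fitGLM(s3, X)
  expect_true(all(abs(g3$coef[, grepl("_(HC|HO)$", colnames(g3$coef))]) < 1e-8))
})

test_that("identity transforms leave the series exactly unchanged", {
  st <- noiselessStudy()$study
  nTR <- length(unique(frameInfo(st$series)$tr))
  out <- applySharedTransforms(st$series, replicate(nTR, diag(4),
                                                    simplify = FALSE))
  expect_identical(seriesData(out), seriesData(st$series))
  expect_error(applySharedTransforms(st$series, list(diag(4))),
               "one transform per TR")
})

test_that("translation and its inverse round-trip within interpolation error", {
  set.seed(2)
  vol <- array(runif(6 * 6 * 3), c(6, 6, 3))
  # integer-voxel translation then its inverse: exact away from the border
  fwd <- diag(4); fwd[1, 4] <- 1
  bwd <- diag(4); bwd[1, 4] <- -1
  out <- calbold:::.resampleTrilinear(calbold:::.resampleTrilinear(vol, fwd),
                                      bwd)
  expect_equal(out[2:6, , ], vol[2:6, , ], tolerance = 1e-12)
  # a sub-voxel shift round-trips to within the interpolation blur on a
  # smooth field
  sm <- gaussianSmooth3D(vol, fwhm = 12, voxelSize = 4.5)
  f2 <- diag(4); f2[1, 4] <- 0.4
  b2 <- diag(4); b2[1, 4] <- -0.4
  out2 <- calbold:::.resampleTrilinear(calbold:::.resampleTrilinear(sm, f2),
                                       b2)
  expect_equal(out2[3:4, 2:5, 2], sm[3:4, 2:5, 2], tolerance = 0.05)
})

test_that("preprocessing smooths at the stated FWHM and normalizes to 100", {
  # impulse response: log of a Gaussian is quadratic, so a quadratic fit of
  # the profile recovers sigma
  vol <- array(0, c(13, 13, 5)); vol[7, 7, 3] <- 1
  sm <- gaussianSmooth3D(vol, fwhm = 8, voxelSize = 4.5)
  prof <- sm[, 7, 3]
  i <- which(prof > max(prof) * 1e-4)
  fit <- lm(log(prof[i]) ~ poly(i, 2, raw = TRUE))
  sigmaVox <- sqrt(-1 / (2 * unname(coef(fit)[3])))
  fwhmEst <- sigmaVox * 4.5 * 2 * sqrt(2 * log(2))
  expect_equal(fwhmEst, 8, tolerance = 0.02 * 8)
  # constant in-mask series normalizes to exactly 100
  st <- noiselessStudy()$study
  dat <- seriesData(st$series); dat[] <- 50
  s <- new("DualEchoSeries", data = dat, frames = frameInfo(st$series),
           geometry = geometry(st$series))
  pp <- preprocessSeries(s, array(TRUE, c(6, 6, 3)), fwhm = 8)
  expect_true(all(abs(seriesData(pp) - 100) < 1e-9))
  expect_error(preprocessSeries(s, array(FALSE, c(6, 6, 3))), "empty")
})

test_that("median filter removes spikes, keeps constants, idempotent on steps", {
  m <- array(5, c(6, 6, 4))
  expect_equal(medianFilter3D(m), m)
  m2 <- m; m2[3, 3, 2] <- 50
  expect_equal(medianFilter3D(m2)[3, 3, 2], 5)
  # two-valued step fixture: filtering twice equals filtering once
  step <- array(1, c(6, 6, 4)); step[4:6, , ] <- 2
  once <- medianFilter3D(step)
  expect_equal(medianFilter3D(once), once)
})

test_that("state maps recover generating responses on noiseless data", {
  fx <- noiselessStudy()
  st <- fx$study
  maps <- fx$result$stateMaps
  truth <- st$truth@maps
  # baseline T2* recovered
  expect_equal(maps$t2star0, truth$t2star0, tolerance = 1e-6)
  # ASL difference positive wherever CBF0 > 0
  expect_true(all(maps$asl$baseline > 0))
  # generating R2* changes recovered to 1e-6
  dHC <- forwardDeltaR2star(truth$m, truth$oef, truth$fHC, 1,
                            st$conditions$cao2HC, st$conditions$cao20,
                            st$params)
  expect_equal(maps$dR2sHC, dHC, tolerance = 1e-6)
})

test_that("exclusion mask applies the T2* and positive-dR2* rules", {
  dm <- c(4, 4, 2)
  maps <- list(t2star0 = array(45, dm),
               dR2sHC = array(-0.3, dm),
               dR2sHO = array(-0.1, dm))
  maps$t2star0[1, 1, 1] <- 25          # susceptibility-degraded
  maps$dR2sHO[2, 1, 1] <- 0.1          # nasal-cavity artifact
  maps$dR2sHC[3, 1, 1] <- 0.2          # non-parenchymal
  gm <- array(0.8, dm); gm[4, 1, 1] <- 0.49
  ex <- buildExclusionMask(maps, gm)
  expect_false(ex$include[1, 1, 1])
  expect_match(ex$reason[1, 1, 1], "low_t2star")
  expect_false(ex$include[2, 1, 1])
  expect_match(ex$reason[2, 1, 1], "pos_dr2s_ho")
  expect_false(ex$include[3, 1, 1])
  expect_true(ex$include[4, 1, 1])       # low GM still solvable...
  expect_false(ex$roiEligible[4, 1, 1])  # ...but out of ROI statistics
  expect_true(ex$include[4, 4, 2])
  expect_equal(sum(!ex$include), 3)
  expect_equal(unname(ex$counts["non_gm"]), 1)
})
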