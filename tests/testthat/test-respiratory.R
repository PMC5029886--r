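test_that("breath-point extraction counts extrema of a pure sinusoid", {
  t <- seq(0, 60 - 0.05, by = 0.05)
  p <- 40 + 10 * sin(2 * pi * t / 5)     # period 5 s, 12 cycles in 60 s
  bp <- extractBreathPoints(t, p, gas = "co2", breathPeriod = 5)
  expect_gte(length(bp$et), 11)  # boundary cycles may be partial
  expect_lte(length(bp$et), 12)
  expect_equal(length(bp$et), length(bp$fi))
  expect_true(all(abs(bp$et - 50) < 0.1))
  expect_true(all(abs(bp$fi - 30) < 0.1))
})

test_that("degenerate traces raise controlled errors", {
  t <- seq(0, 60, by = 0.1)
  expect_error(extractBreathPoints(t, rep(40, length(t)), gas = "co2"),
               "no breaths")
  expect_error(extractBreathPoints(seq(0, 3, 1), c(1, 2, 1, 2), gas = "co2",
                                   breathPeriod = 1),
               "sampling rate")
})

test_that("attenuation correction applies the adjacent-FI-error rule", {
  # ET midway between FI neighbors with errors {3, 5} against expected 0
  bp <- breathPoints(etTime = 10, et = 45, fiTime = c(8, 12), fi = c(3, 5),
                     expectedFI = function(t) rep(0, length(t)), gas = "co2")
  expect_equal(correctFilterAttenuation(bp)$et, 49)
  # FI observed equal to expected everywhere: ET unchanged
  bp2 <- breathPoints(etTime = c(10, 20), et = c(45, 46),
                      fiTime = c(8, 12, 18, 22), fi = rep(2, 4),
                      expectedFI = function(t) rep(2, length(t)), gas = "co2")
  expect_equal(correctFilterAttenuation(bp2)$et, c(45, 46))
  # monotone: a larger FI error produces a larger same-sign ET shift
  shift <- function(e) {
    b <- breathPoints(10, 45, c(8, 12), c(e, e),
                      function(t) rep(0, length(t)), gas = "co2")
    correctFilterAttenuation(b)$et - 45
  }
  errs <- c(-4, -2, 0, 1, 3)
  shifts <- vapply(errs, shift, numeric(1))
  expect_equal(shifts, errs)
  expect_true(all(diff(shifts) > 0))
})

test_that("water-vapor correction rescales by (PB-47)/PB and is invertible", {
  bp <- breathPoints(etTime = 1:3, et = c(100, 0, 40), fiTime = 1:3 + 0.5,
                     fi = c(1, 1, 1), gas = "co2")
  cc <- correctWaterVapor(bp, pb = 760)
  expect_equal(cc$et, c(100, 0, 40) * (760 - 47) / 760)
  expect_equal(cc$et[1], 93.8, tolerance = 1e-3)
  expect_equal(cc$et[2], 0)
  back <- cc$et * 760 / (760 - 47)
  expect_equal(back, c(100, 0, 40), tolerance = 1e-12)
  expect_error(correctWaterVapor(bp, pb = 40), "47")
})

test_that("end-tidal model recovers constants and programmed block steps", {
  p <- makeDefaultParadigm()
  t <- seq(2, 1078, by = 4)
  # constant series: baseline = constant, all effects zero
  f0 <- fitEndTidalModel(time = t, value = rep(40, length(t)), paradigm = p)
  expect_equal(f0$baseline, 40, tolerance = 1e-9)
  expect_equal(unname(f0$blockEffects), rep(0, 4), tolerance = 1e-9)
  # noiseless +10 mmHg HC steps along the model regressors
  rHC1 <- gasRegressor(p, blocks = hcBlocks(p)[1, , drop = FALSE])(t)
  rHC2 <- gasRegressor(p, blocks = hcBlocks(p)[2, , drop = FALSE])(t)
  v <- 40 + 10 * rHC1 + 10 * rHC2 + 0.002 * (t - mean(t))
  f1 <- fitEndTidalModel(time = t, value = v, paradigm = p)
  expect_equal(f1$dHC, 10, tolerance = 0.5)
  expect_equal(f1$baseline, 40, tolerance = 0.5)
  # two HO blocks at +255 and +265: the per-gas change is their mean
  rHO1 <- gasRegressor(p, blocks = hoBlocks(p)[1, , drop = FALSE])(t)
  rHO2 <- gasRegressor(p, blocks = hoBlocks(p)[2, , drop = FALSE])(t)
  v2 <- 111 + 255 * rHO1 + 265 * rHO2
  f2 <- fitEndTidalModel(time = t, value = v2, paradigm = p)
  expect_equal(f2$dHO, 260, tolerance = 0.5)
  expect_error(fitEndTidalModel(time = t[1:5], value = v[1:5], paradigm = p),
               "at least 20")
})

test_that("baseline estimate is invariant to the response-regressor span", {
  # adding response-shaped components with zero net amplitude (i.e. none)
  # and polynomial drift leaves the baseline estimate unchanged
  p <- makeDefaultParadigm()
  t <- seq(2, 1078, by = 4)
  base <- fitEndTidalModel(time = t, value = rep(40, length(t)), paradigm = p)
  drift <- 3 * poly(t, 3) %*% c(1, -2, 0.5)
  fd <- fitEndTidalModel(time = t, value = 40 + as.numeric(drift), paradigm = p)
  expect_equal(fd$baseline, base$baseline, tolerance = 1e-8)
})

test_that("programmed end-tidal changes are recovered through the full chain", {
  st <- simulateStudy(shape = c(2, 2, 1), seed = 11, noiseSd = 0,
                      attenuation = 0.1)
  tr <- st$trace
  et <- endTidalSummary(tr, st$paradigm,
                        expectedFIO2 = attr(tr, "expectedFIO2"),
                        expectedFICO2 = attr(tr, "expectedFICO2"))
  # programmed (vapor-corrected) values: 111 / +7 / +259; CO2 40 / +10 / -1
  expect_equal(et$eto2, 111, tolerance = 1)
  expect_equal(et$dETO2HO, 259, tolerance = 1)
  expect_equal(et$dETO2HC, 7, tolerance = 1)
  expect_equal(et$etco2, 40, tolerance = 1)
  expect_equal(et$dETCO2HC, 10, tolerance = 1)
  expect_equal(et$dETCO2HO, -1, tolerance = 1)
})

test_that("attenuation 0 leaves plateau end-tidal values unfiltered", {
  st <- simulateStudy(shape = c(2, 2, 1), seed = 12, noiseSd = 0,
                      attenuation = 0)
  tr <- st$trace
  bp <- extractBreathPoints(tr, gas = "co2", breathPeriod = 4,
                            expectedFI = attr(tr, "expectedFICO2"))
  # baseline plateau (first 100 s): observed ET equals the programmed dry ET
  sel <- bp$etTime < 100
  expect_true(all(abs(bp$et[sel] - st$levels$co2$et0) < 0.05))
})
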