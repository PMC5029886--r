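## Synthetic-data generator: ground-truth maps, respiratory traces and
## annotated dual-echo pCASL series with the statistical structure the
## analysis assumes, so the full pipeline is testable without any download.

#' Default programmed respiratory levels
#'
#' Programmed end-tidal and fixed-inspired plateau levels per gas channel in
#' dry-analyzer units (mmHg). The defaults are chosen so that after the
#' water-vapor correction at 760 mmHg the end-tidal values match typical
#' group means of a 60% O2 / 5% CO2 protocol: ETO2 111 (baseline), 370 (HO),
#' 118 (HC); ETCO2 40 (baseline), 50 (HC), 39 (HO).
#'
#' @param pb barometric pressure used to back out the dry-analyzer values
#' @return nested list with `o2` and `co2` components (`fi0`, `et0`, `fiHC`,
#'   `etHC`, `fiHO`, `etHO`; ET gas levels may be length 2 for per-block
#'   values)
#' @export
respiratoryDefaults <- function(pb = 760) {
  f <- pb / (pb - 47)   # corrected -> dry
  list(
    o2 = list(fi0 = 159.2, et0 = 111 * f,
              fiHC = 152.0, etHC = 118 * f,
              fiHO = 456.0, etHO = 370 * f),
    co2 = list(fi0 = 0.3, et0 = 40 * f,
               fiHC = 38.0, etHC = 50 * f,
               fiHO = 0.3, etHO = 39 * f))
}

## per-channel target functions: slow (HRF-convolved) ET and stepwise FI
.channelTargets <- function(paradigm, lev) {
  hc <- hcBlocks(paradigm); ho <- hoBlocks(paradigm)
  etHC <- rep_len(lev$etHC, nrow(hc))
  etHO <- rep_len(lev$etHO, nrow(ho))
  regs <- c(lapply(seq_len(nrow(hc)), function(i)
              gasRegressor(paradigm, blocks = hc[i, , drop = FALSE])),
            lapply(seq_len(nrow(ho)), function(i)
              gasRegressor(paradigm, blocks = ho[i, , drop = FALSE])))
  amps <- c(etHC - lev$et0, etHO - lev$et0)
  et <- function(t) {
    out <- rep(lev$et0, length(t))
    for (i in seq_along(regs)) out <- out + amps[i] * regs[[i]](t)
    out
  }
  fi <- function(t) {
    out <- rep(lev$fi0, length(t))
    out[blockIndicator(hc, t) > 0] <- lev$fiHC
    out[blockIndicator(ho, t) > 0] <- lev$fiHO
    out
  }
  list(et = et, fi = fi)
}

#' Simulate a two-channel respiratory trace
#'
#' Generates continuous O2 and CO2 partial-pressure traces for a gas
#' paradigm. Each breath oscillates between the fixed-inspired and
#' end-tidal plateau of its channel (raised-cosine within the breath, so
#' end-expiration reaches the ET target exactly); during gas blocks the ET
#' plateaus shift along the HRF-convolved block time course
#' (near-exponential transitions) while the programmed FI steps at block
#' boundaries. A sampling-line filter attenuation `a` shrinks the observed
#' peak-to-peak amplitude symmetrically about the breath midline: observed
#' FI moves toward the midline and observed ET by the same amount.
#'
#' @param paradigm a [GasParadigm-class]
#' @param breathPeriod breath period, seconds (default 4)
#' @param levels programmed plateau levels, see [respiratoryDefaults()]
#' @param attenuation filter attenuation factor in [0, 1)
#' @param rate sampling rate, Hz (default 10)
#' @param noiseSd additive measurement noise SD, mmHg (default 0)
#' @param seed integer seed for the measurement noise
#' @return a [RespiratoryTrace-class]; the programmed FI schedules are
#'   attached as attributes `expectedFIO2` / `expectedFICO2` (functions of
#'   time) for the attenuation correction
#' @export
simulateRespiratoryTrace <- function(paradigm = makeDefaultParadigm(),
                                     breathPeriod = 4,
                                     levels = respiratoryDefaults(),
                                     attenuation = 0.1, rate = 10,
                                     noiseSd = 0, seed = 1L) {
  stopifnot(attenuation >= 0, attenuation < 1, breathPeriod > 0, rate > 0)
  time <- seq(0, totalDuration(paradigm) - 1 / rate, by = 1 / rate)
  breath <- floor(time / breathPeriod)
  phase <- (time - breath * breathPeriod) / breathPeriod
  tMid <- (breath + 0.5) * breathPeriod
  set.seed(seed)
  one <- function(lev) {
    tg <- .channelTargets(paradigm, lev)
    etB <- tg$et(tMid)   # per-breath targets, constant within a breath
    fiB <- tg$fi(tMid)
    p <- fiB + (etB - fiB) * (1 - cos(2 * pi * phase)) / 2
    mid <- (etB + fiB) / 2
    p <- mid + (1 - attenuation) * (p - mid)
    if (noiseSd > 0) p <- p + stats::rnorm(length(p), sd = noiseSd)
    list(p = pmax(p, 0), fi = tg$fi)
  }
  o2 <- one(levels$o2)
  co2 <- one(levels$co2)
  tr <- new("RespiratoryTrace", time = time, pO2 = o2$p, pCO2 = co2$p,
            rate = rate)
  attr(tr, "expectedFIO2") <- o2$fi
  attr(tr, "expectedFICO2") <- co2$fi
  tr
}

#' Generate ground-truth parameter maps
#'
#' Draws independent uniform voxelwise maps within the given ranges,
#' reproducibly for a fixed seed. A configurable fraction of voxels is
#' assigned a short baseline T2* (below the exclusion threshold) to
#' exercise the masking rules. The hyperoxic flow ratio f_HO is constant
#' across voxels by default, matching the analysis convention of a single
#' whole-brain hyperoxic flow response per subject.
#'
#' @param shape grid shape (nx, ny, nz)
#' @param seed integer seed
#' @param ranges named list of (min, max) ranges for `cbf0` (mL/100 g/min),
#'   `t2star0` (ms), `m` (fraction), `oef` (fraction), `gm` (probability),
#'   `fHC` (ratio), `s0` (signal units); scalar `fHO`
#' @param lowT2Frac fraction of voxels given T2*0 in `lowT2Range` (default 0.05)
#' @param lowT2Range short-T2* range, ms (default c(20, 28))
#' @param noiseSd additive signal noise SD for the series simulator
#' @param driftSd SD of the per-voxel drift-basis coefficients
#' @return a [GroundTruth-class]
#' @export
makeGroundTruth <- function(shape = c(12, 12, 4), seed = 1L,
                            ranges = list(cbf0 = c(40, 60),
                                          t2star0 = c(40, 60),
                                          m = c(0.03, 0.08),
                                          oef = c(0.25, 0.55),
                                          gm = c(0, 1),
                                          fHC = c(1.3, 1.7),
                                          s0 = c(80, 120)),
                            fHO = 1.0, lowT2Frac = 0.05,
                            lowT2Range = c(20, 28),
                            noiseSd = 0.5, driftSd = 2) {
  stopifnot(all(shape >= 1), lowT2Frac >= 0, lowT2Frac <= 1)
  defaults <- eval(formals(makeGroundTruth)$ranges)
  for (nm in names(defaults))
    if (is.null(ranges[[nm]])) ranges[[nm]] <- defaults[[nm]]
  chk <- function(nm, lo, hi) {
    r <- ranges[[nm]]
    if (r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop("invalid range for ", nm)
  }
  chk("oef", 1e-6, 1 - 1e-6); chk("m", 1e-9, Inf); chk("fHC", 1, Inf)
  chk("cbf0", 1e-9, Inf); chk("t2star0", 1e-9, Inf); chk("gm", 0, 1)
  if (fHO < 0.9 || fHO > 1.05) stop("fHO must be in [0.9, 1.05]")
  nvox <- prod(shape)
  set.seed(seed)
  draw <- function(r) array(stats::runif(nvox, r[1], r[2]), shape)
  maps <- list(cbf0 = draw(ranges$cbf0), t2star0 = draw(ranges$t2star0),
               m = draw(ranges$m), oef = draw(ranges$oef),
               gm = draw(ranges$gm), fHC = draw(ranges$fHC),
               fHO = array(fHO, shape), s0 = draw(ranges$s0))
  nLow <- round(lowT2Frac * nvox)
  if (nLow > 0) {
    low <- sample.int(nvox, nLow)
    maps$t2star0[low] <- stats::runif(nLow, lowT2Range[1], lowT2Range[2])
  }
  drift <- matrix(stats::rnorm(nvox * 3, sd = driftSd), nvox, 3)
  new("GroundTruth", dim = as.integer(shape), maps = maps,
      noiseSd = noiseSd, driftCoefs = drift, seed = as.integer(seed))
}

#' Arterial condition set from end-tidal O2 values
#'
#' Computes the per-condition arterial O2 content and the hyperoxic blood
#' T1 from alveolar (water-vapor-corrected) end-tidal O2 values.
#'
#' @param eto20,eto2HC,eto2HO end-tidal O2 at baseline / during HC / during
#'   HO, mmHg (alveolar scale)
#' @param blood blood parameters from [bloodParams()]
#' @return list with `cao20`, `cao2HC`, `cao2HO` (mL O2/dL), `t1bHO` (s)
#'   and the input pressures
#' @export
studyConditions <- function(eto20 = 111, eto2HC = 118, eto2HO = 370,
                            blood = bloodParams()) {
  list(cao20 = arterialO2Content(eto20, blood)$cao2,
       cao2HC = arterialO2Content(eto2HC, blood)$cao2,
       cao2HO = arterialO2Content(eto2HO, blood)$cao2,
       t1bHO = bloodT1Hyperoxia(eto2HO, eto20, blood),
       pao20 = eto20, pao2HC = eto2HC, pao2HO = eto2HO)
}

#' Simulate an annotated dual-echo pCASL series
#'
#' Forward model of the full acquisition. Per voxel, the signal of echo e in
#' label state s under condition c is
#' \deqn{S = S0_{s,c}\, e^{-TE_e (R2^*_0 + \Delta R2^*_c)}}
#' where the label-state S0 is depressed relative to control by the ASL
#' difference implied by the condition's CBF through the quantification
#' model ([aslSignalFromCBF()]; the hyperoxic difference uses the shortened
#' blood T1), and the gas R2* changes are generated from the ground-truth
#' (M, OEF) through the calibration forward model
#' ([forwardDeltaR2star()]). Each frame mixes the per-condition endpoint
#' levels linearly along the HRF-convolved block regressors, then adds
#' polynomial drift and white Gaussian noise. Label and control alternate
#' per TR (first TR is a label frame) and the two echoes of a TR are
#' adjacent frames.
#'
#' @param truth a [GroundTruth-class]
#' @param paradigm a [GasParadigm-class]
#' @param geom geometry from [acquisitionGeometry()]; its `nSlices` must
#'   equal the grid's third dimension
#' @param params model parameters from [modelParams()]
#' @param conditions arterial conditions from [studyConditions()]
#' @param const ASL constants from [perfusionConstants()]
#' @param seed integer seed for the noise
#' @param ar1 lag-1 autocorrelation of the noise (default 0, white)
#' @return a [DualEchoSeries-class]
#' @export
simulateDualEchoSeries <- function(truth, paradigm = makeDefaultParadigm(),
                                   geom = NULL, params = modelParams(),
                                   conditions = studyConditions(),
                                   const = perfusionConstants(),
                                   seed = 1L, ar1 = 0) {
  dm <- truth@dim
  if (is.null(geom)) geom <- acquisitionGeometry(nSlices = dm[3])
  if (geom$nSlices != dm[3])
    stop("geometry nSlices must match the grid's third dimension")
  nTR <- floor(totalDuration(paradigm) / geom$tr)
  tTR <- (seq_len(nTR) - 1) * geom$tr
  frames <- data.frame(
    frame = seq_len(2L * nTR),
    tr = rep(seq_len(nTR), each = 2L),
    time = rep(tTR, each = 2L),
    echo = rep(1:2, nTR),
    state = rep(ifelse(seq_len(nTR) %% 2L == 1L, "label", "control"),
                each = 2L))
  nvox <- prod(dm)
  m <- truth@maps
  slice <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  r2s0 <- 1000 / m$t2star0                       # s^-1 from ms
  dR2s <- list(
    baseline = array(0, dm),
    HC = forwardDeltaR2star(m$m, m$oef, m$fHC, params$rHC,
                            conditions$cao2HC, conditions$cao20, params),
    HO = forwardDeltaR2star(m$m, m$oef, m$fHO, params$rHO,
                            conditions$cao2HO, conditions$cao20, params))
  t1bFor <- c(baseline = const$t1b, HC = const$t1b, HO = conditions$t1bHO)
  fFor <- list(baseline = array(1, dm), HC = m$fHC, HO = m$fHO)
  ## endpoint signal levels per echo x state x condition, as voxel vectors
  lev <- list()
  for (cd in c("baseline", "HC", "HO")) {
    dM <- aslSignalFromCBF(fFor[[cd]] * m$cbf0, m$s0, slice, const, geom,
                           t1b = t1bFor[[cd]])
    r2 <- r2s0 + dR2s[[cd]]
    for (e in 1:2) {
      te <- if (e == 1L) geom$te1 else geom$te2
      lev[[paste0("e", e, "_control_", cd)]] <- as.numeric(m$s0 * exp(-te * r2))
      lev[[paste0("e", e, "_label_", cd)]] <-
        as.numeric((m$s0 - dM) * exp(-te * r2))
    }
  }
  rHC <- gasRegressor(paradigm, "hc")(frames$time)
  rHO <- gasRegressor(paradigm, "ho")(frames$time)
  driftX <- driftBasis(frames$time)
  set.seed(seed)
  nf <- nrow(frames)
  noise <- matrix(stats::rnorm(nvox * nf, sd = truth@noiseSd), nvox, nf)
  if (ar1 > 0 && truth@noiseSd > 0) {
    for (j in 2:nf) noise[, j] <- ar1 * noise[, j - 1L] +
                                  sqrt(1 - ar1^2) * noise[, j]
  }
  driftMat <- truth@driftCoefs %*% t(driftX)   # nvox x nframes
  dat <- array(0, c(dm, nf))
  for (fr in seq_len(nf)) {
    key <- paste0("e", frames$echo[fr], "_", frames$state[fr])
    v <- lev[[paste0(key, "_baseline")]] *
           (1 - rHC[fr] - rHO[fr]) +
         lev[[paste0(key, "_HC")]] * rHC[fr] +
         lev[[paste0(key, "_HO")]] * rHO[fr]
    dat[, , , fr] <- v + driftMat[, fr] + noise[, fr]
  }
  new("DualEchoSeries", data = dat, frames = frames, geometry = geom)
}

#' Simulate a complete synthetic study
#'
#' Generates a coherent subject dataset: ground-truth maps, a respiratory
#' trace whose water-vapor-corrected end-tidal plateaus match the arterial
#' conditions used to generate the imaging data, and the annotated dual-echo
#' series.
#'
#' @param shape grid shape (default c(12, 12, 4))
#' @param seed integer seed (all randomness derives from it)
#' @param paradigm a [GasParadigm-class]
#' @param noiseSd signal noise SD (default 0.5; 0 for a noiseless subject)
#' @param attenuation respiratory filter attenuation (default 0.1)
#' @param params model parameters from [modelParams()]
#' @param const ASL constants from [perfusionConstants()]
#' @param pb barometric pressure, mmHg
#' @param ... further arguments passed to [makeGroundTruth()]
#' @return list with `truth`, `trace`, `series`, `paradigm`, `geom`,
#'   `params`, `const`, `conditions`, `levels`, `pb`, `seed`
#' @export
simulateStudy <- function(shape = c(12, 12, 4), seed = 1L,
                          paradigm = makeDefaultParadigm(), noiseSd = 0.5,
                          attenuation = 0.1, params = modelParams(),
                          const = perfusionConstants(), pb = 760, ...) {
  levels <- respiratoryDefaults(pb)
  vap <- (pb - 47) / pb
  conditions <- studyConditions(eto20 = levels$o2$et0 * vap,
                                eto2HC = levels$o2$etHC * vap,
                                eto2HO = mean(levels$o2$etHO) * vap,
                                blood = params$blood)
  truth <- makeGroundTruth(shape = shape, seed = seed, noiseSd = noiseSd, ...)
  trace <- simulateRespiratoryTrace(paradigm, levels = levels,
                                    attenuation = attenuation,
                                    seed = seed + 1000L)
  geom <- acquisitionGeometry(nSlices = shape[3])
  series <- simulateDualEchoSeries(truth, paradigm, geom, params,
                                   conditions, const, seed = seed + 2000L)
  list(truth = truth, trace = trace, series = series, paradigm = paradigm,
       geom = geom, params = params, const = const,
       conditions = conditions, levels = levels, pb = pb, seed = seed)
}
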