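#' Breath-point container
#'
#' Per-breath end-tidal (ET) and fixed-inspired (FI) extrema extracted from a
#' continuous gas trace, plus the programmed (expected) FI schedule.
#'
#' @param etTime,et ET point times (s) and pressures (mmHg)
#' @param fiTime,fi FI point times (s) and pressures (mmHg)
#' @param expectedFI function of time giving the programmed FI pressure
#' @param gas `"co2"` or `"o2"` (determines which extremum is the ET)
#' @return object of class `"BreathPoints"`
#' @export
breathPoints <- function(etTime, et, fiTime, fi, expectedFI = NULL,
                         gas = c("co2", "o2")) {
  gas <- match.arg(gas)
  if (is.unsorted(etTime, strictly = TRUE) || is.unsorted(fiTime, strictly = TRUE))
    stop("breath points must be strictly time-ordered")
  structure(list(etTime = etTime, et = et, fiTime = fiTime, fi = fi,
                 expectedFI = expectedFI, gas = gas),
            class = "BreathPoints")
}

#' @export
print.BreathPoints <- function(x, ...) {
  cat("BreathPoints (", x$gas, "): ", length(x$et), " ET / ",
      length(x$fi), " FI points\n", sep = "")
  invisible(x)
}

## centered moving average, edge-truncated
.movAvg <- function(x, halfwidth) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract end-tidal and fixed-inspired points from a gas trace
#'
#' Detects one ET and one FI point per breath cycle. Breath cycles are
#' delimited by upward zero-crossings of the trace after subtracting its
#' slowly varying midline (moving average over one breath period); within
#' each cycle the two extrema are taken. For CO2 the end-tidal point is the
#' cycle maximum (expired gas is CO2-rich); for O2 it is the minimum.
#'
#' @param time,pressure trace samples (s, mmHg); alternatively `time` can be
#'   a [RespiratoryTrace-class] and `gas` selects the channel
#' @param gas `"co2"` or `"o2"`
#' @param breathPeriod nominal breath period, seconds; the sampling rate must
#'   be at least 4x the breath frequency
#' @param expectedFI optional programmed FI schedule, function of time
#' @return a [breathPoints()] object
#' @export
extractBreathPoints <- function(time, pressure = NULL, gas = c("co2", "o2"),
                                breathPeriod = 4, expectedFI = NULL) {
  gas <- match.arg(gas)
  if (is(time, "RespiratoryTrace")) {
    tr <- time
    pressure <- if (gas == "co2") tr@pCO2 else tr@pO2
    time <- tr@time
  }
  stopifnot(length(time) == length(pressure), breathPeriod > 0)
  dt <- stats::median(diff(time))
  if (1 / dt < 4 / breathPeriod)
    stop("sampling rate below 4x breath frequency")
  hw <- max(1L, round(breathPeriod / 2 / dt))
  osc <- pressure - .movAvg(pressure, hw)
  sgn <- sign(osc)
  up <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0) + 1L
  if (length(up) < 3L) stop("no breaths detected")
  etT <- etP <- fiT <- fiP <- rep(NA_real_, length(up) - 1L)
  for (i in seq_len(length(up) - 1L)) {
    idx <- up[i]:(up[i + 1L] - 1L)
    imax <- idx[which.max(pressure[idx])]
    imin <- idx[which.min(pressure[idx])]
    if (!is.null(expectedFI)) {
      ## breaths straddling (or immediately adjacent to) a programmed gas
      ## switch are ambiguous: the inspired level changes within the breath
      ## and cycle segmentation drifts; drop them
      ts <- c(time[idx[1]] - breathPeriod, time[idx[1]],
              time[idx[length(idx)]], time[idx[length(idx)]] + breathPeriod)
      fe <- expectedFI(ts)
      if (max(fe) - min(fe) > 1e-6) next
      ## the inspired point is the extremum nearest the programmed FI; this
      ## stays correct when the usual ordering inverts (e.g. end-tidal O2
      ## above inspired air O2 while washing out after a hyperoxic block)
      fiExp <- expectedFI(mean(time[range(idx)]))
      if (abs(pressure[imax] - fiExp) <= abs(pressure[imin] - fiExp)) {
        ii <- imax; ie <- imin
      } else {
        ii <- imin; ie <- imax
      }
    } else if (gas == "co2") { ie <- imax; ii <- imin
    } else { ie <- imin; ii <- imax }
    etT[i] <- time[ie]; etP[i] <- pressure[ie]
    fiT[i] <- time[ii]; fiP[i] <- pressure[ii]
  }
  drop <- is.na(etT)
  etT <- etT[!drop]; etP <- etP[!drop]
  fiT <- fiT[!drop]; fiP <- fiP[!drop]
  if (!length(etT)) stop("no breaths detected")
  ## a cycle may assign ET and FI at identical times on degenerate flat
  ## segments; enforce strict ordering by dropping duplicates
  keepE <- c(TRUE, diff(etT) > 0)
  keepI <- c(TRUE, diff(fiT) > 0)
  breathPoints(etT[keepE], etP[keepE], fiT[keepI], fiP[keepI],
               expectedFI = expectedFI, gas = gas)
}

#' Correct end-tidal points for sampling-line filter attenuation
#'
#' A resistive filter in the gas sampling line low-passes the respiratory
#' waveform, attenuating its peak-to-peak amplitude: observed FI moves toward
#' the breath midline and observed ET by an equal amount in the opposite
#' direction. Since the programmed FI is known, each ET point is corrected by
#' the mean observed-minus-expected FI error of the two temporally adjacent
#' FI points (one at a series boundary).
#'
#' @param points a [breathPoints()] object with a non-NULL `expectedFI`
#' @return corrected `BreathPoints`
#' @export
correctFilterAttenuation <- function(points) {
  stopifnot(inherits(points, "BreathPoints"))
  if (length(points$fi) == 0L) stop("no FI points")
  if (is.null(points$expectedFI)) stop("expected FI schedule required")
  err <- points$fi - points$expectedFI(points$fiTime)
  fiExpAtFI <- points$expectedFI(points$fiTime)
  et <- points$et
  for (i in seq_along(et)) {
    ## the two adjacent FI points, restricted to the same programmed-gas
    ## segment as the ET point (the FI error changes size across a gas
    ## switch); their errors are combined by linear interpolation in time,
    ## which reduces to the plain mean for a breath midway between them
    same <- abs(fiExpAtFI - points$expectedFI(points$etTime[i])) < 1e-6
    prev <- which(points$fiTime <= points$etTime[i] & same)
    nxt <- which(points$fiTime > points$etTime[i] & same)
    if (!length(prev) && !length(nxt)) {
      prev <- which(points$fiTime <= points$etTime[i])
      nxt <- which(points$fiTime > points$etTime[i])
    }
    if (length(prev) && length(nxt)) {
      p <- max(prev); n <- min(nxt)
      w <- (points$etTime[i] - points$fiTime[p]) /
           (points$fiTime[n] - points$fiTime[p])
      et[i] <- et[i] + (1 - w) * err[p] + w * err[n]
    } else if (length(prev)) {
      et[i] <- et[i] + err[max(prev)]
    } else {
      et[i] <- et[i] + err[min(nxt)]
    }
  }
  points$et <- et
  points
}

#' Correct end-tidal pressures for expired water vapor
#'
#' Gas analyzers report dry-gas fractions; alveolar gas is saturated with
#' water vapor (partial pressure 47 mmHg at body temperature). ET pressures
#' are rescaled to alveolar values:
#' \deqn{p_{corr} = p_{obs} (P_B - 47) / P_B.}
#'
#' @param points a [breathPoints()] object (only ET pressures are rescaled)
#' @param pb barometric pressure, mmHg (> 47); default 760
#' @return corrected `BreathPoints`
#' @export
correctWaterVapor <- function(points, pb = 760) {
  stopifnot(inherits(points, "BreathPoints"))
  if (pb <= 47) stop("barometric pressure must exceed 47 mmHg")
  points$et <- points$et * (pb - 47) / pb
  points
}

#' Fit the polynomial + four-regressor end-tidal model
#'
#' Least-squares fit of an ET point series against a third-degree polynomial
#' (offset included, polynomial terms orthogonalized to zero mean over the
#' series so the offset is the drift-free baseline) plus four block
#' regressors - one per gas block (HC1, HC2, HO1, HO2), each the
#' HRF-convolved block normalized to unit plateau. Regressors are evaluated
#' at the irregular breath times; no resampling. The per-gas end-tidal change
#' is the mean of that gas's two block effect sizes.
#'
#' @param points a [breathPoints()] object (ET series), or numeric times via
#'   `time`/`value`
#' @param paradigm a [GasParadigm-class]
#' @param time,value optional explicit ET series overriding `points`
#' @return list with `baseline` (mmHg), `dHC`, `dHO` (mean block effects,
#'   mmHg), `blockEffects` (named length-4 vector) and the `fit` residual SD
#' @export
fitEndTidalModel <- function(points = NULL, paradigm = makeDefaultParadigm(),
                             time = NULL, value = NULL) {
  if (!is.null(points)) {
    stopifnot(inherits(points, "BreathPoints"))
    time <- points$etTime; value <- points$et
  }
  if (length(time) < 20L)
    stop("need at least 20 breath points spanning the paradigm")
  hc <- hcBlocks(paradigm); ho <- hoBlocks(paradigm)
  regs <- cbind(
    HC1 = gasRegressor(paradigm, blocks = hc[1, , drop = FALSE])(time),
    HC2 = gasRegressor(paradigm, blocks = hc[2, , drop = FALSE])(time),
    HO1 = gasRegressor(paradigm, blocks = ho[1, , drop = FALSE])(time),
    HO2 = gasRegressor(paradigm, blocks = ho[2, , drop = FALSE])(time))
  pol <- stats::poly(time, degree = 3)   # orthogonal, zero-mean columns
  X <- cbind(offset = 1, pol, regs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient end-tidal design")
  beta <- qr.coef(qrX, value)
  res <- value - X %*% beta
  eff <- beta[c("HC1", "HC2", "HO1", "HO2")]
  list(baseline = unname(beta["offset"]),
       dHC = unname(mean(eff[c("HC1", "HC2")])),
       dHO = unname(mean(eff[c("HO1", "HO2")])),
       blockEffects = eff,
       residualSD = stats::sd(res))
}

#' Summarize end-tidal O2 and CO2 for one scan
#'
#' Runs the full respiratory chain for both gas channels of a trace:
#' breath-point extraction, filter-attenuation correction (when the
#' programmed FI schedules are supplied), water-vapor correction, and the
#' polynomial + four-regressor model.
#'
#' @param trace a [RespiratoryTrace-class]
#' @param paradigm a [GasParadigm-class]
#' @param expectedFIO2,expectedFICO2 programmed FI schedules (functions of
#'   time, dry-analyzer mmHg); NULL skips the attenuation correction
#' @param breathPeriod nominal breath period, seconds
#' @param pb barometric pressure, mmHg; NA skips the water-vapor correction
#' @return list with `eto2` / `etco2` baselines (mmHg) and gas-induced
#'   changes `dETO2HC`, `dETO2HO`, `dETCO2HC`, `dETCO2HO`
#' @export
endTidalSummary <- function(trace, paradigm = makeDefaultParadigm(),
                            expectedFIO2 = NULL, expectedFICO2 = NULL,
                            breathPeriod = 4, pb = 760) {
  one <- function(gas, expFI) {
    bp <- extractBreathPoints(trace, gas = gas, breathPeriod = breathPeriod,
                              expectedFI = expFI)
    if (!is.null(expFI)) bp <- correctFilterAttenuation(bp)
    if (!is.na(pb)) bp <- correctWaterVapor(bp, pb = pb)
    fitEndTidalModel(bp, paradigm)
  }
  o2 <- one("o2", expectedFIO2)
  co2 <- one("co2", expectedFICO2)
  list(eto2 = o2$baseline, etco2 = co2$baseline,
       dETO2HC = o2$dHC, dETO2HO = o2$dHO,
       dETCO2HC = co2$dHC, dETCO2HO = co2$dHO)
}
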