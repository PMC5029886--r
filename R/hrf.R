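## Haemodynamic response kernel for slow gas challenges.
##
## Single-gamma density parameterized by its mode (time-to-peak) and FWHM
## (width). Arterial partial pressures respond slowly to a change in
## inspired gas, and convolving block regressors with this kernel yields
## near-exponential transitions toward each plateau.

.hrfCache <- new.env(parent = emptyenv())

## FWHM of a gamma density with given shape, mode fixed by scale = mode/(shape-1)
.gammaFWHM <- function(shape, mode) {
  scale <- mode / (shape - 1)
  peak <- stats::dgamma(mode, shape = shape, scale = scale)
  half <- function(t) stats::dgamma(t, shape = shape, scale = scale) - peak / 2
  t1 <- stats::uniroot(half, c(1e-8, mode), tol = 1e-10)$root
  ## upper half-point: bracket by expanding beyond the mode
  hi <- mode * 2
  while (half(hi) > 0) hi <- hi * 2
  t2 <- stats::uniroot(half, c(mode, hi), tol = 1e-10)$root
  t2 - t1
}

.solveGammaShape <- function(peakTime, width) {
  key <- paste0("shape_", peakTime, "_", width)
  if (!is.null(.hrfCache[[key]])) return(.hrfCache[[key]])
  f <- function(k) .gammaFWHM(k, peakTime) - width
  k <- stats::uniroot(f, c(1.05, 200), tol = 1e-9)$root
  .hrfCache[[key]] <- k
  k
}

#' Gamma HRF kernel for gas-challenge regressors
#'
#' Single-gamma haemodynamic response kernel with a 20-s time-to-peak (mode)
#' and 40-s width (FWHM), peak-normalized. Shape and scale are solved
#' numerically from the (mode, FWHM) pair.
#'
#' @param dt sampling interval, seconds
#' @param peakTime kernel mode, seconds (default 20)
#' @param width kernel FWHM, seconds (default 40)
#' @return list with `t` (times), `k` (kernel values, max 1), `shape`, `scale`
#' @export
gammaHRFKernel <- function(dt = 0.1, peakTime = 20, width = 40) {
  stopifnot(dt > 0, peakTime > 0, width > 0)
  shape <- .solveGammaShape(peakTime, width)
  scale <- peakTime / (shape - 1)
  tmax <- stats::qgamma(0.9999, shape = shape, scale = scale)
  t <- seq(0, tmax, by = dt)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  list(t = t, k = k / max(k), shape = shape, scale = scale)
}

#' Gas-response regressor: HRF-convolved block time course
#'
#' Convolves the block indicator of a gas condition with the gamma HRF kernel
#' and normalizes the result to unit maximum, so the fitted effect size is
#' the plateau change of the modeled quantity. The returned closure can be
#' evaluated at arbitrary times (linear interpolation on a fine internal
#' grid); simulator and analysis share the identical regressor.
#'
#' @param paradigm a [GasParadigm-class]
#' @param condition `"hc"` or `"ho"` (both blocks of the condition combined),
#'   ignored when `blocks` is given
#' @param blocks optional two-column matrix (onset, duration) to build a
#'   regressor for an arbitrary subset of blocks (e.g. a single HC block)
#' @param dt internal grid step, seconds
#' @param peakTime,width HRF kernel parameters, seconds
#' @return a function of time returning regressor values in [0, 1]
#' @export
#' @examples
#' r <- gasRegressor(makeDefaultParadigm(), "hc")
#' r(c(0, 230))   # 0 at scan start, near 1 late in the first HC block
gasRegressor <- function(paradigm, condition = c("hc", "ho"), blocks = NULL,
                         dt = 0.1, peakTime = 20, width = 40) {
  if (is.null(blocks)) {
    condition <- match.arg(condition)
    blocks <- if (condition == "hc") hcBlocks(paradigm) else hoBlocks(paradigm)
  }
  tg <- seq(0, totalDuration(paradigm), by = dt)
  x <- blockIndicator(blocks, tg)
  ker <- gammaHRFKernel(dt = dt, peakTime = peakTime, width = width)
  y <- stats::filter(c(numeric(length(ker$k) - 1L), x), ker$k,
                     method = "convolution", sides = 1)
  y <- as.numeric(y)[length(ker$k):(length(ker$k) + length(tg) - 1L)]
  y[is.na(y)] <- 0
  m <- max(y)
  if (m > 0) y <- y / m
  stats::approxfun(tg, y, rule = 2)
}
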