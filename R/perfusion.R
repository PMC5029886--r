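#' Acquisition geometry of the dual-echo pCASL sequence
#'
#' @param tr repetition time, s
#' @param te1,te2 first/second echo times, s (te2 > te1 > 0)
#' @param nSlices number of 2D slices
#' @param firstSlicePLD,lastSlicePLD post-labeling delay of the first and
#'   last acquired slice, s
#' @param tau labeling duration, s
#' @param voxelSize voxel edge length, mm (isotropic grid assumed)
#' @return named list of validated geometry parameters
#' @export
acquisitionGeometry <- function(tr = 4.12, te1 = 0.0084, te2 = 0.030,
                                nSlices = 21, firstSlicePLD = 0.900,
                                lastSlicePLD = 1.986, tau = 2.0,
                                voxelSize = 4.5) {
  stopifnot(te2 > te1, te1 > 0, tr > 0, nSlices >= 1, tau > 0,
            firstSlicePLD > 0, lastSlicePLD >= firstSlicePLD, voxelSize > 0)
  list(tr = tr, te1 = te1, te2 = te2, nSlices = nSlices,
       firstSlicePLD = firstSlicePLD, lastSlicePLD = lastSlicePLD,
       tau = tau, voxelSize = voxelSize)
}

#' ASL quantification constants
#'
#' Single-compartment pCASL quantification constants following the ASL
#' consensus recommendation: blood-brain partition coefficient `lambda`
#' (mL/g), labeling efficiency `alphaLabel`, arterial blood T1 `t1b` (s),
#' and the conversion `u` from mL O2 to micromoles (ideal gas at STPD).
#'
#' @param lambda mL/g (default 0.9)
#' @param alphaLabel labeling efficiency fraction (default 0.85)
#' @param t1b arterial blood T1, s (default 1.65)
#' @param u micromol O2 per mL O2 (default 44.6)
#' @return named list
#' @export
perfusionConstants <- function(lambda = 0.9, alphaLabel = 0.85,
                               t1b = 1.65, u = 44.6) {
  stopifnot(lambda > 0, alphaLabel > 0, t1b > 0, u > 0)
  list(lambda = lambda, alphaLabel = alphaLabel, t1b = t1b, u = u)
}

#' Slice-dependent post-labeling delay
#'
#' In a 2D readout each slice is acquired later than the previous one, so
#' the effective PLD grows linearly with slice index between the first and
#' last slice values.
#'
#' @param slice slice index (1-based), may be a vector
#' @param geom geometry from [acquisitionGeometry()]
#' @return PLD in seconds
#' @export
#' @examples
#' g <- acquisitionGeometry()
#' slicePLD(1, g)                  # 0.900
#' mean(slicePLD(1:21, g))         # 1.443 s brain-averaged PLD
slicePLD <- function(slice, geom = acquisitionGeometry()) {
  if (any(slice < 1 | slice > geom$nSlices)) stop("slice index out of range")
  if (geom$nSlices == 1L) return(rep(geom$firstSlicePLD, length(slice)))
  geom$firstSlicePLD + (slice - 1) *
    (geom$lastSlicePLD - geom$firstSlicePLD) / (geom$nSlices - 1)
}

## quantification kernel: CBF = 6000 * lambda * dM / (M0 * K(T1b, PLD))
## with K = 2 * alphaLabel * T1b * (1 - exp(-tau/T1b)) * exp(-PLD/T1b)
.aslKernel <- function(pld, const, geom, t1b) {
  2 * const$alphaLabel * t1b * (1 - exp(-geom$tau / t1b)) * exp(-pld / t1b)
}

#' Convert ASL difference signal to CBF
#'
#' Single-compartment pCASL model:
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\, e^{PLD_i/T1b}}
#'   {2\,\alpha\,T1b\,M_0\,(1 - e^{-\tau/T1b})}}
#' in mL/100 g/min, with the slice-dependent PLD of [slicePLD()]. Linear in
#' the control-minus-label difference `dM`, hence exactly invertible (see
#' [aslSignalFromCBF()]).
#'
#' @param dM control-minus-label difference signal (vector or array)
#' @param m0 equilibrium magnetization map, same shape as `dM` (> 0)
#' @param slice slice index per element (scalar or same shape)
#' @param const constants from [perfusionConstants()]
#' @param geom geometry from [acquisitionGeometry()]
#' @param t1b optional blood T1 override, s (e.g. the hyperoxia-shortened T1)
#' @return CBF in mL/100 g/min; NA where `m0 <= 0`
#' @export
quantifyCBF <- function(dM, m0, slice, const = perfusionConstants(),
                        geom = acquisitionGeometry(), t1b = const$t1b) {
  pld <- slicePLD(slice, geom)
  out <- 6000 * const$lambda * dM / (m0 * .aslKernel(pld, const, geom, t1b))
  out[m0 <= 0] <- NA_real_
  out
}

#' Forward ASL model: difference signal implied by a CBF value
#'
#' Exact inverse of [quantifyCBF()]; used by the simulator to generate the
#' label/control modulation from ground-truth CBF.
#'
#' @inheritParams quantifyCBF
#' @param cbf CBF in mL/100 g/min
#' @return control-minus-label difference signal
#' @export
aslSignalFromCBF <- function(cbf, m0, slice, const = perfusionConstants(),
                             geom = acquisitionGeometry(), t1b = const$t1b) {
  pld <- slicePLD(slice, geom)
  cbf * m0 * .aslKernel(pld, const, geom, t1b) / (6000 * const$lambda)
}

#' Correct the hyperoxic CBF response for blood-T1 shortening
#'
#' Hyperoxia shortens arterial blood T1, so ASL signal quantified with the
#' baseline T1 underestimates CBF during HO. Each voxel's HO CBF is
#' re-quantified with the hyperoxic T1 (the correction factor is the ratio of
#' the quantification kernels at the voxel's slice PLD). Because the
#' hyperoxic ASL response has low contrast-to-noise, the gray-matter
#' probability-weighted mean of the corrected percent change is returned as
#' the per-subject whole-brain estimate that replaces the voxelwise HO flow
#' response downstream.
#'
#' @param dPctCBFHORaw voxelwise raw percent CBF change to HO (3D array),
#'   quantified with the baseline T1
#' @param t1bHO hyperoxic blood T1, s, in (0, t1b]
#' @param gm gray-matter probability map, same shape
#' @param slice slice index per voxel (3D array or scalar)
#' @param const constants from [perfusionConstants()]
#' @param geom geometry from [acquisitionGeometry()]
#' @param gmCutoff minimum GM probability entering the weighted mean
#' @return list with `map` (corrected percent change) and `gmMean` (scalar)
#' @export
correctHyperoxiaCBF <- function(dPctCBFHORaw, t1bHO, gm, slice,
                                const = perfusionConstants(),
                                geom = acquisitionGeometry(),
                                gmCutoff = 0.5) {
  if (!is.numeric(t1bHO) || t1bHO <= 0 || t1bHO > const$t1b)
    stop("t1bHO must be in (0, t1b]")
  pld <- slicePLD(slice, geom)
  ## CBF scales with 1/K; the raw map used the baseline T1 kernel
  factor <- .aslKernel(pld, const, geom, const$t1b) /
            .aslKernel(pld, const, geom, t1bHO)
  ## percent change: CBF_HO_corr/CBF0 - 1 = (1 + raw/100) * factor - 1
  map <- 100 * ((1 + dPctCBFHORaw / 100) * factor - 1)
  w <- ifelse(gm >= gmCutoff & is.finite(map), gm, 0)
  if (sum(w) == 0) stop("no GM voxels for the whole-brain HO estimate")
  list(map = map, gmMean = sum(map * w, na.rm = TRUE) / sum(w), factor = factor)
}
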