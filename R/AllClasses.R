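#' @import methods
NULL

#' Gas paradigm: timing of hypercapnic and hyperoxic blocks
#'
#' Holds the block-design respiratory schedule: total scan duration plus the
#' onsets and durations (seconds) of the hypercapnia (HC) and hyperoxia (HO)
#' blocks. Blocks must lie within the scan and must not overlap.
#'
#' @slot totalDuration total scan duration in seconds
#' @slot hcBlocks two-column matrix (onset, duration) of HC blocks, seconds
#' @slot hoBlocks two-column matrix (onset, duration) of HO blocks, seconds
#' @export
setClass("GasParadigm",
  representation(totalDuration = "numeric",
                 hcBlocks = "matrix",
                 hoBlocks = "matrix"))

setValidity("GasParadigm", function(object) {
  msgs <- character()
  if (length(object@totalDuration) != 1L || object@totalDuration <= 0)
    msgs <- c(msgs, "totalDuration must be a single positive number")
  for (nm in c("hcBlocks", "hoBlocks")) {
    b <- slot(object, nm)
    if (ncol(b) != 2L) msgs <- c(msgs, paste(nm, "must have 2 columns (onset, duration)"))
    else {
      if (any(b[, 2] <= 0)) msgs <- c(msgs, paste(nm, "durations must be positive"))
      if (any(b[, 1] < 0) || any(rowSums(b) > object@totalDuration))
        msgs <- c(msgs, paste(nm, "must lie within [0, totalDuration]"))
    }
  }
  # all blocks pairwise non-overlapping
  all <- rbind(object@hcBlocks, object@hoBlocks)
  if (nrow(all) > 1L) {
    o <- order(all[, 1])
    all <- all[o, , drop = FALSE]
    if (any(all[-nrow(all), 1] + all[-nrow(all), 2] > all[-1, 1]))
      msgs <- c(msgs, "gas blocks overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Respiratory trace: continuously sampled O2 and CO2 partial pressures
#'
#' @slot time sampling times, seconds, strictly increasing
#' @slot pO2 O2 partial pressure, mmHg
#' @slot pCO2 CO2 partial pressure, mmHg
#' @slot rate nominal sampling rate, Hz
#' @export
setClass("RespiratoryTrace",
  representation(time = "numeric", pO2 = "numeric", pCO2 = "numeric",
                 rate = "numeric"))

setValidity("RespiratoryTrace", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@pO2) != n || length(object@pCO2) != n)
    msgs <- c(msgs, "time, pO2 and pCO2 must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (any(object@pO2 < 0) || any(object@pCO2 < 0))
    msgs <- c(msgs, "partial pressures must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth parameter maps for the simulator
#'
#' Voxelwise physiological truth from which a synthetic dual-echo pCASL
#' study is generated: resting perfusion CBF0 (mL/100 g/min), baseline
#' T2* (ms), the BOLD calibration parameter M (fraction at the reference
#' echo time), resting OEF (fraction), gray-matter probability, and the
#' fractional CBF responses f_HC and f_HO (unitless ratios). Also carries
#' the additive noise SD, per-voxel drift coefficients and the seed used.
#'
#' @slot dim integer grid shape (nx, ny, nz)
#' @slot maps named list of 3D arrays: cbf0, t2star0, m, oef, gm, fHC, fHO, s0
#' @slot noiseSd additive Gaussian noise SD in signal units
#' @slot driftCoefs matrix (nvox x 3) of drift-basis coefficients
#' @slot seed integer seed the maps were drawn with
#' @export
setClass("GroundTruth",
  representation(dim = "integer", maps = "list", noiseSd = "numeric",
                 driftCoefs = "matrix", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msgs <- character()
  need <- c("cbf0", "t2star0", "m", "oef", "gm", "fHC", "fHO", "s0")
  miss <- setdiff(need, names(object@maps))
  if (length(miss)) msgs <- c(msgs, paste("missing maps:", paste(miss, collapse = ", ")))
  else {
    for (nm in need)
      if (!identical(dim(object@maps[[nm]]), object@dim))
        msgs <- c(msgs, paste("map", nm, "does not match grid shape"))
    if (!length(msgs)) {
      m <- object@maps
      if (any(m$oef <= 0 | m$oef >= 1)) msgs <- c(msgs, "OEF must be in (0,1)")
      if (any(m$m <= 0)) msgs <- c(msgs, "M must be positive")
      if (any(m$fHC < 1)) msgs <- c(msgs, "f_HC must be >= 1")
      if (any(m$fHO < 0.9 | m$fHO > 1.05)) msgs <- c(msgs, "f_HO must be in [0.9, 1.05]")
      if (any(m$cbf0 <= 0)) msgs <- c(msgs, "CBF0 must be positive")
      if (any(m$t2star0 <= 0)) msgs <- c(msgs, "T2*0 must be positive")
      if (any(m$gm < 0 | m$gm > 1)) msgs <- c(msgs, "GM probability must be in [0,1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Annotated 4D dual-echo pCASL series
#'
#' The raw pipeline input: a 4D array of echo volumes plus a frame table
#' annotating every volume with its TR index, acquisition time, echo number
#' and label/control state, and the acquisition geometry.
#'
#' @slot data 4D numeric array (nx, ny, nz, nframes)
#' @slot frames data.frame with columns frame, tr, time, echo, state
#' @slot geometry acquisition geometry list from [acquisitionGeometry()]
#' @export
setClass("DualEchoSeries",
  representation(data = "array", frames = "data.frame", geometry = "list"))

setValidity("DualEchoSeries", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 4L)
    msgs <- c(msgs, "data must be a 4D array")
  else if (dim(object@data)[4] != nrow(object@frames))
    msgs <- c(msgs, "frame annotation rows must match 4th dimension")
  need <- c("frame", "tr", "time", "echo", "state")
  if (!all(need %in% names(object@frames)))
    msgs <- c(msgs, "frames must have columns frame, tr, time, echo, state")
  else if (!all(object@frames$state %in% c("label", "control")))
    msgs <- c(msgs, "state must be 'label' or 'control'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GasParadigm", function(object) {
  cat("GasParadigm:", object@totalDuration, "s total;",
      nrow(object@hcBlocks), "HC block(s) of",
      paste(object@hcBlocks[, 2], collapse = "/"), "s;",
      nrow(object@hoBlocks), "HO block(s) of",
      paste(object@hoBlocks[, 2], collapse = "/"), "s\n")
})

setMethod("show", "RespiratoryTrace", function(object) {
  cat("RespiratoryTrace:", length(object@time), "samples at",
      object@rate, "Hz over", round(max(object@time), 1), "s\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth grid", paste(object@dim, collapse = "x"),
      "| noise SD", object@noiseSd, "| seed", object@seed, "\n")
})

setMethod("show", "DualEchoSeries", function(object) {
  d <- dim(object@data)
  cat("DualEchoSeries", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "frames (", length(unique(object@frames$tr)), "TRs x 2 echoes )\n")
})
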