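## Sensitivity machinery: systematic sweeps of the assumed calibration
## parameters and propagation of random measurement errors through the
## two-gas calibration model, with CV-vs-error curves.

#' A gray-matter-like baseline voxel for sensitivity analyses
#'
#' Representative GM inputs for the calibration model: resting CBF 50
#' mL/100 g/min, hypercapnic flow ratio 1.5, no hyperoxic flow change, and
#' R2* responses forward-generated from M = 0.05, OEF = 0.39 at typical
#' end-tidal O2 values (111/118/370 mmHg at baseline/HC/HO).
#'
#' @param M,oef generating calibration parameter and resting OEF
#' @param cbf0 resting CBF, mL/100 g/min
#' @param fHC,fHO flow ratios
#' @param conditions arterial conditions from [studyConditions()]
#' @param params model parameters from [modelParams()]
#' @return a `responses` list as consumed by [solveVoxel()], with the
#'   generating values attached as attributes `M` and `oef`
#' @export
gmLikeResponses <- function(M = 0.05, oef = 0.39, cbf0 = 50, fHC = 1.5,
                            fHO = 1.0, conditions = studyConditions(),
                            params = modelParams()) {
  r <- list(
    cbf0 = cbf0, fHC = fHC, fHO = fHO,
    dR2sHC = forwardDeltaR2star(M, oef, fHC, params$rHC,
                                conditions$cao2HC, conditions$cao20, params),
    dR2sHO = forwardDeltaR2star(M, oef, fHO, params$rHO,
                                conditions$cao2HO, conditions$cao20, params),
    cao20 = conditions$cao20, cao2HC = conditions$cao2HC,
    cao2HO = conditions$cao2HO,
    pao20 = conditions$pao20, pao2HC = conditions$pao2HC,
    pao2HO = conditions$pao2HO)
  attr(r, "M") <- M
  attr(r, "oef") <- oef
  r
}

#' Default systematic sweep ranges
#'
#' Explored ranges of the assumed parameters: alpha 0.15-0.45, beta 1.0-1.5,
#' Hb 11-17 g/dL, fractional CMRO2 during HC 0.90-1.10 (+/-1% per mmHg
#' end-tidal CO2 change of ~10 mmHg), during HO 0.93-1.07 (+/-1% per
#' 40 mmHg end-tidal O2 change of ~260 mmHg), and hyperoxic flow ratio
#' 0.90-1.00.
#'
#' @return named list of c(min, max) ranges
#' @export
sweepDefaults <- function() {
  list(alpha = c(0.15, 0.45), beta = c(1.0, 1.5), hb = c(11, 17),
       rHC = c(0.90, 1.10), rHO = c(0.93, 1.07), fHO = c(0.90, 1.00))
}

## re-solve the baseline voxel with one parameter replaced; an assumed [Hb]
## propagates into the arterial O2 contents, which are derived from the
## end-tidal pressures under that assumption
.solveWith <- function(responses, params, name, value) {
  if (name %in% c("alpha", "beta", "rHC", "rHO")) {
    params[[name]] <- value
  } else if (name == "hb") {
    params$blood$hb <- value
    if (is.null(responses$pao20))
      stop("Hb sweep requires end-tidal pressures in the responses")
    responses$cao20 <- arterialO2Content(responses$pao20, params$blood)$cao2
    responses$cao2HC <- arterialO2Content(responses$pao2HC, params$blood)$cao2
    responses$cao2HO <- arterialO2Content(responses$pao2HO, params$blood)$cao2
  } else if (name == "fHO") {
    responses$fHO <- value
  } else stop("unknown sweep parameter: ", name)
  solveVoxel(responses, params)
}

#' Systematic sweep of an assumed calibration parameter
#'
#' Re-solves a baseline voxel across a grid of one assumed parameter
#' (`alpha`, `beta`, `hb`, `rHC`, `rHO` or `fHO`), all others fixed.
#'
#' @param parameter parameter name
#' @param range c(min, max); default from [sweepDefaults()]
#' @param n number of grid points (default 13)
#' @param responses baseline voxel inputs (default [gmLikeResponses()])
#' @param params model parameters at baseline
#' @return data.frame with columns value, M, oef, cmro2, solved
#' @export
sweepSystematic <- function(parameter, range = NULL, n = 13,
                            responses = gmLikeResponses(),
                            params = modelParams()) {
  if (is.null(range)) range <- sweepDefaults()[[parameter]]
  if (is.null(range)) stop("unknown sweep parameter: ", parameter)
  base <- solveVoxel(responses, params)
  if (!base$solved) stop("unsolvable baseline voxel")
  grid <- seq(range[1], range[2], length.out = n)
  rows <- lapply(grid, function(v) {
    s <- .solveWith(responses, params, parameter, v)
    data.frame(value = v, M = s$M, oef = s$oef, cmro2 = s$cmro2,
               solved = s$solved)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  out
}

#' Coefficient of variation between a true and a perturbed value
#'
#' Percent SD over mean of the pair \{true, simulated\} (n-1 denominator).
#' For simulated = true (1 + e) this equals the closed form
#' \eqn{100 |e| / (\sqrt 2 (1 + e/2))}: an added error yields a lower CV
#' (20% at e = +33%) than a subtracted one (28% at e = -33%).
#'
#' @param true,simulated the two values (nonzero mean)
#' @return CV in percent
#' @export
cvBetween <- function(true, simulated) {
  m <- mean(c(true, simulated))
  if (m == 0) stop("zero mean")
  100 * stats::sd(c(true, simulated)) / m
}

#' Propagate random measurement errors through the calibration model
#'
#' For each relative error e on a grid, the named measured input
#' (`dPctCBFHC` scales the hypercapnic percent flow change, `dR2sHC` or
#' `dR2sHO` scale an R2* response) is multiplied by (1 + e), the voxel is
#' re-solved, and the CV between the perturbed and the e = 0 solution is
#' computed. Since resting CBF and arterial O2 content are not varied, the
#' OEF and CMRO2 CV curves are identical by construction.
#'
#' @param input `"dPctCBFHC"`, `"dR2sHC"` or `"dR2sHO"`
#' @param errors relative error grid; must include 0
#'   (default 13 points spanning -0.33 to +0.33)
#' @param responses baseline voxel inputs (default [gmLikeResponses()])
#' @param params model parameters
#' @return data.frame with columns error, M, oef, cvM, cvOEF, solved
#' @export
propagateRandomError <- function(input = c("dPctCBFHC", "dR2sHC", "dR2sHO"),
                                 errors = seq(-0.33, 0.33, length.out = 13),
                                 responses = gmLikeResponses(),
                                 params = modelParams()) {
  input <- match.arg(input)
  if (!any(errors == 0)) stop("error grid must include 0")
  base <- solveVoxel(responses, params)
  if (!base$solved) stop("unsolvable baseline voxel")
  rows <- lapply(errors, function(e) {
    r <- responses
    if (input == "dPctCBFHC") {
      r$fHC <- 1 + (r$fHC - 1) * (1 + e)
    } else {
      r[[input]] <- r[[input]] * (1 + e)
    }
    s <- solveVoxel(r, params)
    data.frame(error = e, M = s$M, oef = s$oef,
               cvM = if (s$solved) cvBetween(base$M, s$M) else NA_real_,
               cvOEF = if (s$solved) cvBetween(base$oef, s$oef) else NA_real_,
               solved = s$solved)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  out
}
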