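#' Generalized calibration model parameters
#'
#' Assumed parameters of the generalized calibration model (GCM): `alpha`,
#' the flow-volume coupling exponent; `beta`, the nonlinearity of the R2*
#' dependence on deoxyhemoglobin; `rHC`/`rHO`, the fractional CMRO2 change
#' during hypercapnia/hyperoxia (1 = isometabolism); `teRef`, the reference
#' echo time at which M is expressed; plus the blood parameters and the
#' mL-O2-to-micromol conversion. Solver controls: OEF search bounds, grid
#' step and bisection tolerance.
#'
#' @param alpha flow-volume coupling (default 0.18)
#' @param beta dHb nonlinearity exponent (default 1.5)
#' @param rHC,rHO fractional CMRO2 during HC/HO (default 1)
#' @param teRef reference echo time, s (default 0.030)
#' @param blood blood parameters from [bloodParams()]
#' @param u micromol per mL O2 (default 44.6)
#' @param oefBounds OEF search interval (default c(0.01, 0.99))
#' @param gridStep sign-change scan step on the OEF grid (default 1e-3)
#' @param tol bisection tolerance on OEF (default 1e-7)
#' @return named list
#' @export
modelParams <- function(alpha = 0.18, beta = 1.5, rHC = 1, rHO = 1,
                        teRef = 0.030, blood = bloodParams(), u = 44.6,
                        oefBounds = c(0.01, 0.99), gridStep = 1e-3,
                        tol = 1e-7) {
  stopifnot(alpha > 0, alpha < 1, beta >= 1, rHC > 0, rHO > 0, teRef > 0,
            u > 0, length(oefBounds) == 2L, oefBounds[1] > 0,
            oefBounds[2] < 1, gridStep > 0, tol > 0)
  list(alpha = alpha, beta = beta, rHC = rHC, rHO = rHO, teRef = teRef,
       blood = blood, u = u, oefBounds = oefBounds, gridStep = gridStep,
       tol = tol)
}

#' Fractional BOLD signal change from an R2* change
#'
#' \deqn{b = e^{-TE_{ref}\,\Delta R2^*} - 1;} positive iff the R2* change is
#' negative (a BOLD signal increase).
#'
#' @param dR2star R2* change, s^-1
#' @param teRef reference echo time, s
#' @return fractional signal change
#' @export
boldFraction <- function(dR2star, teRef = 0.030) {
  stopifnot(teRef > 0)
  exp(-teRef * dR2star) - 1
}

#' The M(E) curve of one gas challenge
#'
#' For a grid of candidate resting OEF values E, the calibration parameter
#' implied by the measured response to one gas:
#' \deqn{M(E) = \frac{b}{1 - f^{\alpha} d(E)^{\beta}}}
#' with b the fractional BOLD change, f the fractional CBF change and d the
#' venous deoxyhemoglobin ratio of [dhbRatio()]. Points where d is
#' non-physical or the denominator vanishes are returned as NA.
#'
#' @param E OEF grid, values in (0, 1)
#' @param b fractional BOLD change of the gas
#' @param f fractional CBF change of the gas
#' @param r fractional CMRO2 change of the gas
#' @param cao2Gas,cao20 arterial O2 content during gas / at baseline, mL/dL
#' @param params model parameters from [modelParams()]
#' @return M(E), NA where invalid
#' @export
gasCurve <- function(E, b, f, r, cao2Gas, cao20, params = modelParams()) {
  d <- dhbRatio(E, f, r, cao2Gas, cao20, params$blood)
  den <- 1 - f^params$alpha * d^params$beta
  m <- b / den
  m[!is.finite(d) | abs(den) < 1e-9] <- NA_real_
  m
}

#' Forward model: R2* change implied by (M, OEF) for one gas
#'
#' Exact inverse of the [gasCurve()] relation, used by the simulator:
#' \deqn{\Delta R2^* = -\ln(1 + M (1 - f^{\alpha} d^{\beta})) / TE_{ref}.}
#'
#' @param M calibration parameter (fraction at `teRef`), > 0
#' @param oef resting OEF in (0, 1)
#' @inheritParams gasCurve
#' @return R2* change in s^-1
#' @export
forwardDeltaR2star <- function(M, oef, f, r, cao2Gas, cao20,
                               params = modelParams()) {
  if (any(M <= 0)) stop("M must be positive")
  if (any(oef <= 0 | oef >= 1)) stop("OEF must be in (0,1)")
  d <- dhbRatio(oef, f, r, cao2Gas, cao20, params$blood)
  arg <- 1 + M * (1 - f^params$alpha * d^params$beta)
  if (any(!is.finite(arg) | arg <= 0))
    stop("non-physical forward model argument (log of non-positive value)")
  -log(arg) / params$teRef
}

#' Solve the two-gas calibration system for one voxel
#'
#' Locates intersections of the hypercapnia and hyperoxia M(E) curves by a
#' sign-change scan of M_HC(E) - M_HO(E) on a uniform OEF grid, refined by
#' bisection. A solution must have M > 0 and OEF inside the search bounds;
#' with multiple intersections the root with the smallest OEF is reported
#' and the root count recorded. No sign change (or an all-invalid curve)
#' yields `solved = FALSE`.
#'
#' @param responses list with voxel inputs `cbf0` (mL/100 g/min), `fHC`,
#'   `fHO` (CBF ratios), `dR2sHC`, `dR2sHO` (s^-1) and subject-level
#'   `cao20`, `cao2HC`, `cao2HO` (mL O2/dL)
#' @param params model parameters from [modelParams()]
#' @return list: `solved`, `M`, `oef`, `delivery`, `cmro2`, `rootCount`,
#'   `reason` (when unsolved)
#' @export
solveVoxel <- function(responses, params = modelParams()) {
  r <- responses
  unsolved <- function(reason, rootCount = 0L)
    list(solved = FALSE, M = NA_real_, oef = NA_real_,
         delivery = NA_real_, cmro2 = NA_real_,
         rootCount = rootCount, reason = reason)
  if (any(!is.finite(c(r$fHC, r$fHO, r$dR2sHC, r$dR2sHO,
                       r$cao20, r$cao2HC, r$cao2HO))))
    return(unsolved("non-finite inputs"))
  bHC <- boldFraction(r$dR2sHC, params$teRef)
  bHO <- boldFraction(r$dR2sHO, params$teRef)
  E <- seq(params$oefBounds[1], params$oefBounds[2], by = params$gridStep)
  mHC <- gasCurve(E, bHC, r$fHC, params$rHC, r$cao2HC, r$cao20, params)
  mHO <- gasCurve(E, bHO, r$fHO, params$rHO, r$cao2HO, r$cao20, params)
  g <- mHC - mHO
  ok <- is.finite(g)
  if (!any(ok)) return(unsolved("all curve points invalid"))
  zeros <- E[ok & g == 0]          # roots landing exactly on grid points
  idx <- which(ok[-length(ok)] & ok[-1] &
               sign(g[-length(g)]) * sign(g[-1]) < 0)
  gfun <- function(e) {
    gasCurve(e, bHC, r$fHC, params$rHC, r$cao2HC, r$cao20, params) -
      gasCurve(e, bHO, r$fHO, params$rHO, r$cao2HO, r$cao20, params)
  }
  roots <- zeros
  for (i in idx) {
    lo <- E[i]; hi <- E[i + 1L]
    while (hi - lo > params$tol) {
      mid <- (lo + hi) / 2
      gm <- gfun(mid)
      if (!is.finite(gm)) break
      if (sign(gm) == sign(gfun(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  if (!length(roots)) return(unsolved("no intersection"))
  Ms <- vapply(roots, function(e)
    gasCurve(e, bHC, r$fHC, params$rHC, r$cao2HC, r$cao20, params),
    numeric(1))
  keep <- is.finite(Ms) & Ms > 0
  if (!any(keep)) return(unsolved("no root with positive M",
                                  rootCount = length(roots)))
  roots <- roots[keep]; Ms <- Ms[keep]
  j <- which.min(roots)
  oef <- roots[j]
  delivery <- if (!is.null(r$cbf0)) o2Delivery(r$cbf0, r$cao20, params$u)
              else NA_real_
  list(solved = TRUE, M = Ms[j], oef = oef,
       delivery = delivery, cmro2 = oef * delivery,
       rootCount = length(roots), reason = NA_character_)
}

#' Resting oxygen delivery
#'
#' Product of resting CBF and arterial O2 content, converted to
#' micromoles: \deqn{delivery = CBF_0 \cdot (CaO2_0/100) \cdot u}
#' in micromol/100 g/min (CaO2 in mL O2/dL = mL O2 per 100 mL blood).
#'
#' @param cbf0 resting CBF, mL/100 g/min
#' @param cao20 arterial O2 content, mL O2/dL
#' @param u micromol per mL O2
#' @return delivery in micromol/100 g/min
#' @export
o2Delivery <- function(cbf0, cao20, u = 44.6) {
  if (any(cbf0 < 0, na.rm = TRUE)) stop("CBF0 must be non-negative")
  cbf0 * (cao20 / 100) * u
}

#' Cerebral metabolic rate of oxygen
#'
#' \deqn{CMRO2 = OEF \times delivery}, micromol/100 g/min.
#'
#' @param oef oxygen extraction fraction in (0, 1)
#' @param delivery O2 delivery, micromol/100 g/min
#' @return CMRO2 in micromol/100 g/min
#' @export
cmro2 <- function(oef, delivery) {
  if (any(oef < 0 | oef >= 1, na.rm = TRUE)) stop("OEF must be in [0,1)")
  oef * delivery
}

#' Voxelwise calibration solve over a masked map
#'
#' Applies [solveVoxel()] to every included voxel and assembles M, OEF,
#' delivery and CMRO2 maps plus solution bookkeeping. The detection rate is
#' the fraction of included voxels where a solution was found, overall and
#' per ROI; unsolved voxels are excluded from all M/OEF/CMRO2 averages.
#'
#' @param responses list of 3D arrays `cbf0`, `fHC`, `fHO`, `dR2sHC`,
#'   `dR2sHO` plus subject scalars `cao20`, `cao2HC`, `cao2HO`
#' @param include logical 3D array of voxels to solve (from
#'   [buildExclusionMask()])
#' @param params model parameters from [modelParams()]
#' @param rois optional named list of logical ROI masks for per-ROI
#'   detection rates
#' @return list with maps `M`, `oef`, `delivery`, `cmro2`, logical `solved`,
#'   integer `rootCount`, scalar `detectionRate` (percent) and
#'   `roiDetection` (named vector, percent)
#' @export
solveMap <- function(responses, include, params = modelParams(),
                     rois = NULL) {
  dm <- dim(responses$cbf0)
  idx <- which(include)
  if (!length(idx)) stop("empty include set")
  M <- oef <- delivery <- cm <- array(NA_real_, dm)
  solved <- array(FALSE, dm)
  rootCount <- array(0L, dm)
  for (i in idx) {
    sol <- solveVoxel(list(
      cbf0 = responses$cbf0[i], fHC = responses$fHC[i],
      fHO = responses$fHO[i], dR2sHC = responses$dR2sHC[i],
      dR2sHO = responses$dR2sHO[i], cao20 = responses$cao20,
      cao2HC = responses$cao2HC, cao2HO = responses$cao2HO), params)
    rootCount[i] <- sol$rootCount
    if (sol$solved) {
      solved[i] <- TRUE
      M[i] <- sol$M; oef[i] <- sol$oef
      delivery[i] <- sol$delivery; cm[i] <- sol$cmro2
    }
  }
  roiDet <- NULL
  if (!is.null(rois))
    roiDet <- vapply(rois, function(m) {
      inc <- include & m
      if (!any(inc)) return(NA_real_)
      100 * sum(solved & inc) / sum(inc)
    }, numeric(1))
  list(M = M, oef = oef, delivery = delivery, cmro2 = cm,
       solved = solved, rootCount = rootCount,
       detectionRate = 100 * sum(solved) / length(idx),
       roiDetection = roiDet)
}

#' GM-probability-weighted ROI average
#'
#' Mean of a map weighted by gray-matter probability over ROI voxels with
#' GM probability of at least `gmCutoff`, excluding masked voxels and (for
#' solution-dependent metrics) voxels without a calibration solution.
#'
#' @param map 3D metric map
#' @param gm GM probability map
#' @param roi logical ROI mask (default: everywhere)
#' @param include logical inclusion mask (default: everywhere)
#' @param gmCutoff minimum GM probability (default 0.5)
#' @return weighted mean scalar
#' @export
roiWeightedAverage <- function(map, gm, roi = NULL, include = NULL,
                               gmCutoff = 0.5) {
  sel <- gm >= gmCutoff & is.finite(map)
  if (!is.null(roi)) sel <- sel & roi
  if (!is.null(include)) sel <- sel & include
  if (!any(sel)) stop("empty ROI after exclusions")
  sum(map[sel] * gm[sel]) / sum(gm[sel])
}
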