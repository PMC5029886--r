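## Signal extraction from annotated dual-echo series: shared-transform
## resampling, smoothing/normalization, the per-channel GLM, dual-echo
## R2*/S0 estimation, median filtering and exclusion masking.

#' Apply per-TR rigid transforms with the shared-matrix contract
#'
#' Resamples every frame of the series with the transform of its TR, so both
#' echo frames of a TR always share the identical transformation matrix.
#' Transforms are 4x4 affine matrices in voxel coordinates (output voxel
#' coordinates are mapped through the matrix to input sampling locations);
#' interpolation is trilinear with zero padding outside the volume. Identity
#' matrices leave the data exactly unchanged.
#'
#' @param series a [DualEchoSeries-class]
#' @param transforms list with one 4x4 matrix per TR
#' @return the resampled series
#' @export
applySharedTransforms <- function(series, transforms) {
  frames <- frameInfo(series)
  trs <- sort(unique(frames$tr))
  if (length(transforms) != length(trs))
    stop("need exactly one transform per TR (",
         length(trs), " TRs, ", length(transforms), " transforms)")
  dat <- seriesData(series)
  dm <- dim(dat)[1:3]
  for (k in seq_along(trs)) {
    A <- transforms[[k]]
    if (!is.matrix(A) || !all(dim(A) == c(4L, 4L)))
      stop("transforms must be 4x4 matrices")
    if (isTRUE(all.equal(A, diag(4), tolerance = 0))) next
    rows <- which(frames$tr == trs[k])
    for (fr in rows)
      dat[, , , fr] <- .resampleTrilinear(array(dat[, , , fr], dm), A)
  }
  new("DualEchoSeries", data = dat, frames = frames,
      geometry = geometry(series))
}

## trilinear resampling of a 3D volume through a 4x4 affine (voxel coords,
## 1-based); out-of-volume samples are zero
.resampleTrilinear <- function(vol, A) {
  dm <- dim(vol)
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                             z = seq_len(dm[3])))
  src <- cbind(g, 1) %*% t(A)
  x <- src[, 1]; y <- src[, 2]; z <- src[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(g))
  att <- function(i, j, k) {
    inb <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
    v <- numeric(length(i))
    v[inb] <- vol[cbind(i[inb], j[inb], k[inb])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    val <- val + w * att(x0 + dx, y0 + dy, z0 + dz)
  }
  array(val, dm)
}

## separable truncated-Gaussian kernel; renormalized at edges so constants
## are preserved
.gauss1d <- function(x, sigmaVox) {
  if (sigmaVox <= 0) return(x)
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  n <- length(x)
  xp <- c(numeric(r), x, numeric(r))
  op <- c(numeric(r), rep(1, n), numeric(r))
  num <- stats::filter(xp, k, sides = 2)[(r + 1L):(r + n)]
  den <- stats::filter(op, k, sides = 2)[(r + 1L):(r + n)]
  as.numeric(num / den)
}

## smooth along the first axis of a 3D array
.smoothAxis1 <- function(a, sigmaVox) {
  dm <- dim(a)
  array(apply(matrix(a, dm[1]), 2, .gauss1d, sigmaVox = sigmaVox), dm)
}

#' 3D Gaussian smoothing
#'
#' Separable Gaussian smoothing of a 3D volume with the kernel width given
#' as FWHM in millimetres. Edge kernels are renormalized, so constant
#' volumes are preserved. `fwhm = 0` is the identity.
#'
#' @param vol 3D array
#' @param fwhm kernel full width at half maximum, mm
#' @param voxelSize voxel edge length, mm
#' @return smoothed array
#' @export
gaussianSmooth3D <- function(vol, fwhm, voxelSize = 4.5) {
  if (fwhm == 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  vol <- .smoothAxis1(vol, sigma)
  vol <- aperm(.smoothAxis1(aperm(vol, c(2, 1, 3)), sigma), c(2, 1, 3))
  aperm(.smoothAxis1(aperm(vol, c(3, 2, 1)), sigma), c(3, 2, 1))
}

#' Preprocess a dual-echo series
#'
#' Per-frame 3D Gaussian spatial smoothing, removal of extra-cerebral voxels
#' (zeroed outside the brain mask) and intensity normalization: a single
#' global rescaling so the whole-series in-mask mean equals 100.
#'
#' @param series a [DualEchoSeries-class]
#' @param mask logical 3D brain mask (non-empty)
#' @param fwhm smoothing kernel FWHM, mm (default 8; 0 disables smoothing)
#' @return preprocessed series
#' @export
preprocessSeries <- function(series, mask, fwhm = 8) {
  if (!any(mask)) stop("empty brain mask")
  dat <- seriesData(series)
  vs <- geometry(series)$voxelSize
  nf <- dim(dat)[4]
  dm <- dim(dat)[1:3]
  maskArr <- array(as.numeric(mask), dm)
  for (fr in seq_len(nf)) {
    v <- gaussianSmooth3D(array(dat[, , , fr], dm), fwhm, vs)
    dat[, , , fr] <- v * maskArr
  }
  mIdx <- which(rep(as.logical(mask), nf))
  dat <- dat * (100 / mean(dat[mIdx]))
  new("DualEchoSeries", data = dat, frames = frameInfo(series),
      geometry = geometry(series))
}

## zero-mean drift basis shared by simulator and GLM
driftBasis <- function(times, degree = 3) {
  stats::poly(times, degree = degree)
}

#' Build the dual-echo GLM design matrix
#'
#' One row per frame. Columns: four channel-baseline indicators (echo 1/2 x
#' label/control), eight response regressors (channel indicator times the
#' HRF-convolved block regressor, per condition HC and HO), and three shared
#' zero-mean polynomial drift terms (degrees 1-3; the constant lies in the
#' span of the channel baselines). Full column rank on the default paradigm;
#' rank deficiency is reported with the offending columns.
#'
#' @param paradigm a [GasParadigm-class]
#' @param frames frame annotation data.frame (columns tr, time, echo, state)
#' @param checkRank error on rank deficiency (default TRUE)
#' @return numeric matrix with named columns and attribute `"channels"`
#' @export
buildDesign <- function(paradigm, frames, checkRank = TRUE) {
  need <- c("time", "echo", "state")
  if (!all(need %in% names(frames)))
    stop("frame annotations must cover all frames with time/echo/state")
  chan <- paste0("e", frames$echo, "_", frames$state)
  levs <- c("e1_label", "e1_control", "e2_label", "e2_control")
  base <- sapply(levs, function(l) as.numeric(chan == l))
  rHC <- gasRegressor(paradigm, "hc")(frames$time)
  rHO <- gasRegressor(paradigm, "ho")(frames$time)
  resp <- cbind(sapply(levs, function(l) as.numeric(chan == l) * rHC),
                sapply(levs, function(l) as.numeric(chan == l) * rHO))
  colnames(resp) <- c(paste0(levs, "_HC"), paste0(levs, "_HO"))
  drift <- driftBasis(frames$time)
  colnames(drift) <- paste0("drift", 1:3)
  X <- cbind(base, resp, drift)
  if (checkRank) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient design; offending columns: ",
           paste(bad, collapse = ", "))
    }
  }
  attr(X, "channels") <- levs
  X
}

#' Voxelwise ordinary least squares fit
#'
#' Fits every voxel's frame series to the design matrix by OLS and stores
#' the coefficients plus residual variance. The fitted signal level of a
#' channel in a condition is the channel baseline plus that channel's
#' condition effect (see [channelLevel()]).
#'
#' @param series a [DualEchoSeries-class]
#' @param design design matrix from [buildDesign()]
#' @return list of class `"GLMResult"`: `coef` (matrix nvox x p), `sigma2`,
#'   `dim` (grid shape), column names as in the design
#' @export
fitGLM <- function(series, design) {
  dat <- seriesData(series)
  dm <- dim(dat)
  Y <- matrix(dat, nrow = prod(dm[1:3]), ncol = dm[4])
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("numerically singular design")
  beta <- t(qr.coef(qrX, t(Y)))
  res <- Y - beta %*% t(design)
  sigma2 <- rowSums(res^2) / (dm[4] - ncol(design))
  colnames(beta) <- colnames(design)
  structure(list(coef = beta, sigma2 = sigma2, dim = dm[1:3],
                 channels = attr(design, "channels")),
            class = "GLMResult")
}

#' Fitted signal level of one channel in one condition
#'
#' @param glm a `"GLMResult"` from [fitGLM()]
#' @param channel one of `"e1_label"`, `"e1_control"`, `"e2_label"`,
#'   `"e2_control"`
#' @param condition `"baseline"`, `"HC"` or `"HO"`
#' @return 3D array of fitted levels
#' @export
channelLevel <- function(glm, channel, condition = c("baseline", "HC", "HO")) {
  condition <- match.arg(condition)
  lev <- glm$coef[, channel]
  if (condition != "baseline")
    lev <- lev + glm$coef[, paste0(channel, "_", condition)]
  array(lev, glm$dim)
}

#' Dual-echo R2* and S0 estimation
#'
#' Two-point exponential fit using both echoes:
#' \deqn{R2^* = \ln(S_1/S_2)/(TE_2 - TE_1), \quad S_0 = S_1 e^{TE_1 R2^*}.}
#' Exact inverse of the mono-exponential decay model. Non-positive signals
#' mark the voxel invalid (NA).
#'
#' @param sE1,sE2 signal at the first/second echo (any shape)
#' @param geom geometry from [acquisitionGeometry()]
#' @return list with `r2star` (s^-1) and `s0` (signal units)
#' @export
estimateR2star <- function(sE1, sE2, geom = acquisitionGeometry()) {
  bad <- !(sE1 > 0 & sE2 > 0)
  r2 <- log(sE1 / sE2) / (geom$te2 - geom$te1)
  s0 <- sE1 * exp(geom$te1 * r2)
  r2[bad] <- NA_real_; s0[bad] <- NA_real_
  list(r2star = r2, s0 = s0)
}

#' 3D median filter (radius 1)
#'
#' Each voxel is replaced by the median of its 3x3x3 Chebyshev neighborhood;
#' neighborhoods are truncated at volume edges. Used to suppress isolated
#' non-parenchymal voxels (e.g. large vessels) in the condition maps.
#'
#' @param map 3D array
#' @param radius neighborhood Chebyshev radius (default 1; 0 is identity)
#' @return filtered array
#' @export
medianFilter3D <- function(map, radius = 1) {
  if (radius == 0) return(map)
  dm <- dim(map)
  stopifnot(length(dm) == 3L)
  out <- map
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    ii <- max(1, i - radius):min(dm[1], i + radius)
    jj <- max(1, j - radius):min(dm[2], j + radius)
    kk <- max(1, k - radius):min(dm[3], k + radius)
    out[i, j, k] <- stats::median(map[ii, jj, kk])
  }
  out
}

#' Per-condition S0/R2* state maps and derived responses
#'
#' From the fitted GLM: estimates S0 and R2* per label state and condition
#' via the dual-echo fit, median-filters the state maps (before any
#' differencing), then derives the BOLD R2* per condition (mean of control
#' and label), the ASL difference (control minus label S0), baseline T2*
#' (ms) and the R2* changes to each gas.
#'
#' @param glm a `"GLMResult"` from [fitGLM()]
#' @param geom geometry from [acquisitionGeometry()]
#' @param medianRadius radius of the 3D median filter applied to every
#'   state map (default 1; 0 disables)
#' @return list of 3D arrays: `s0Control`, `s0Label`, `r2star` (per
#'   condition each), `asl` per condition, `t2star0` (ms), `dR2sHC`,
#'   `dR2sHO` (s^-1)
#' @export
computeStateMaps <- function(glm, geom = acquisitionGeometry(),
                             medianRadius = 1) {
  conds <- c("baseline", "HC", "HO")
  s0c <- s0l <- r2 <- stats::setNames(vector("list", 3), conds)
  for (cd in conds) {
    ec <- estimateR2star(channelLevel(glm, "e1_control", cd),
                         channelLevel(glm, "e2_control", cd), geom)
    el <- estimateR2star(channelLevel(glm, "e1_label", cd),
                         channelLevel(glm, "e2_label", cd), geom)
    s0c[[cd]] <- medianFilter3D(ec$s0, medianRadius)
    s0l[[cd]] <- medianFilter3D(el$s0, medianRadius)
    rc <- medianFilter3D(ec$r2star, medianRadius)
    rl <- medianFilter3D(el$r2star, medianRadius)
    r2[[cd]] <- (rc + rl) / 2
  }
  asl <- lapply(conds, function(cd) s0c[[cd]] - s0l[[cd]])
  names(asl) <- conds
  list(s0Control = s0c, s0Label = s0l, r2star = r2, asl = asl,
       t2star0 = 1000 / r2$baseline,
       dR2sHC = r2$HC - r2$baseline,
       dR2sHO = r2$HO - r2$baseline)
}

#' Build the voxel exclusion mask
#'
#' Voxels failing the calibration model's assumptions are excluded: baseline
#' T2* below the susceptibility threshold (default 30 ms), positive R2*
#' change to hyperoxia (nasal-cavity susceptibility) or to hypercapnia
#' (non-parenchymal). Low gray-matter probability does not exclude a voxel
#' from solving but bars it from ROI statistics; it is recorded separately.
#'
#' @param maps state maps from [computeStateMaps()]
#' @param gm GM probability map
#' @param t2Threshold T2* lower threshold, ms (default 30)
#' @param gmCutoff GM probability cutoff for ROI statistics (default 0.5)
#' @return list: logical `include`, logical `roiEligible`, and a character
#'   3D array `reason` (`""`, or comma-joined codes among `low_t2star`,
#'   `pos_dr2s_ho`, `pos_dr2s_hc`, `invalid`; `non_gm` only affects
#'   `roiEligible`)
#' @export
buildExclusionMask <- function(maps, gm, t2Threshold = 30, gmCutoff = 0.5) {
  dm <- dim(maps$t2star0)
  bad <- list(
    low_t2star = maps$t2star0 < t2Threshold,
    pos_dr2s_ho = maps$dR2sHO > 0,
    pos_dr2s_hc = maps$dR2sHC > 0,
    invalid = !is.finite(maps$t2star0) | !is.finite(maps$dR2sHC) |
              !is.finite(maps$dR2sHO))
  bad <- lapply(bad, function(x) { x[is.na(x)] <- TRUE; x })
  reason <- array("", dm)
  for (nm in names(bad))
    reason[bad[[nm]]] <- ifelse(reason[bad[[nm]]] == "", nm,
                                paste(reason[bad[[nm]]], nm, sep = ","))
  include <- !Reduce(`|`, bad)
  list(include = include, roiEligible = include & gm >= gmCutoff,
       reason = reason,
       counts = c(vapply(bad, sum, integer(1)), non_gm = sum(gm < gmCutoff)))
}
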