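## Pipeline orchestration: respiratory -> signal -> perfusion -> calibration
## for one subject dataset, plus on-disk readers and writers (NIfTI series
## and maps, TSV annotations and traces, JSON summaries).

#' Analyze one (synthetic or loaded) subject dataset
#'
#' Runs the full single-subject chain: end-tidal extraction and corrections,
#' arterial O2 content and hyperoxic blood T1, series preprocessing, the
#' dual-echo GLM, state maps, CBF quantification with the hyperoxic T1
#' correction and whole-brain flow substitution, exclusion masking and the
#' voxelwise calibration solve, ending in GM-weighted summary values.
#'
#' @param study a dataset as returned by [simulateStudy()] or [readStudy()]
#' @param fwhm spatial smoothing FWHM, mm (default 8; 0 disables)
#' @param medianRadius median-filter radius for state maps (default 1;
#'   0 disables)
#' @param mask optional logical brain mask (default: whole grid)
#' @param rois optional named list of logical ROI masks
#' @param t2Threshold baseline T2* exclusion threshold, ms
#' @param gmCutoff GM probability cutoff for ROI statistics
#' @param breathPeriod nominal breath period for ET extraction, s
#' @return list with `endTidal`, `conditions` (estimated), `stateMaps`,
#'   `cbf` (maps cbf0, fHC, dPctCBFHO, gmMeanDPctCBFHO, fHO), `exclusion`,
#'   `solution`, `gmMeans` (cbf0, Mpct, oef, delivery, cmro2),
#'   `detectionRate`, `counts`
#' @export
analyzeStudy <- function(study, fwhm = 8, medianRadius = 1, mask = NULL,
                         rois = NULL, t2Threshold = 30, gmCutoff = 0.5,
                         breathPeriod = 4) {
  series <- study$series
  geom <- geometry(series)
  params <- study$params
  const <- study$const
  dm <- dim(seriesData(series))[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  gm <- truthMap(study$truth, "gm")

  ## -- respiratory chain -------------------------------------------------
  et <- endTidalSummary(study$trace, study$paradigm,
                        expectedFIO2 = attr(study$trace, "expectedFIO2"),
                        expectedFICO2 = attr(study$trace, "expectedFICO2"),
                        breathPeriod = breathPeriod, pb = study$pb)
  cond <- studyConditions(eto20 = et$eto2,
                          eto2HC = et$eto2 + et$dETO2HC,
                          eto2HO = et$eto2 + et$dETO2HO,
                          blood = params$blood)

  ## -- signal extraction -------------------------------------------------
  pre <- preprocessSeries(series, mask, fwhm = fwhm)
  X <- buildDesign(study$paradigm, frameInfo(pre))
  glm <- fitGLM(pre, X)
  maps <- computeStateMaps(glm, geom, medianRadius = medianRadius)

  ## -- perfusion ---------------------------------------------------------
  slice <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  m0 <- maps$s0Control$baseline
  cbf0 <- quantifyCBF(maps$asl$baseline, m0, slice, const, geom)
  fHC <- ifelse(maps$asl$baseline > 0, maps$asl$HC / maps$asl$baseline, NA)
  dPctHORaw <- ifelse(maps$asl$baseline > 0,
                      100 * (maps$asl$HO / maps$asl$baseline - 1), NA)
  hoCorr <- correctHyperoxiaCBF(dPctHORaw, cond$t1bHO, gm, slice,
                                const, geom, gmCutoff = gmCutoff)
  fHO <- 1 + hoCorr$gmMean / 100

  ## -- exclusion & calibration solve ------------------------------------
  excl <- buildExclusionMask(maps, gm, t2Threshold = t2Threshold,
                             gmCutoff = gmCutoff)
  responses <- list(cbf0 = cbf0, fHC = fHC,
                    fHO = array(fHO, dm),
                    dR2sHC = maps$dR2sHC, dR2sHO = maps$dR2sHO,
                    cao20 = cond$cao20, cao2HC = cond$cao2HC,
                    cao2HO = cond$cao2HO)
  sol <- solveMap(responses, excl$include & is.finite(cbf0) & is.finite(fHC),
                  params, rois = rois)

  ## -- GM-weighted summaries ---------------------------------------------
  gmMeans <- c(
    cbf0 = roiWeightedAverage(cbf0, gm, include = excl$include,
                              gmCutoff = gmCutoff),
    Mpct = 100 * roiWeightedAverage(sol$M, gm, include = sol$solved,
                                    gmCutoff = gmCutoff),
    oef = roiWeightedAverage(sol$oef, gm, include = sol$solved,
                             gmCutoff = gmCutoff),
    delivery = roiWeightedAverage(sol$delivery, gm, include = sol$solved,
                                  gmCutoff = gmCutoff),
    cmro2 = roiWeightedAverage(sol$cmro2, gm, include = sol$solved,
                               gmCutoff = gmCutoff))
  ## detection rate restricted to ROI-eligible (GM) voxels
  gmInc <- excl$roiEligible & is.finite(cbf0) & is.finite(fHC)
  detGM <- if (any(gmInc)) 100 * sum(sol$solved & gmInc) / sum(gmInc)
           else NA_real_
  list(endTidal = et, conditions = cond, stateMaps = maps,
       cbf = list(cbf0 = cbf0, fHC = fHC, dPctCBFHO = hoCorr$map,
                  gmMeanDPctCBFHO = hoCorr$gmMean, fHO = fHO),
       exclusion = excl, solution = sol, gmMeans = gmMeans,
       detectionRate = detGM, counts = excl$counts)
}

#' Write a simulated study to disk
#'
#' NIfTI 4D series, frame-annotation TSV, truth maps as NIfTI, respiratory
#' trace TSV and a JSON manifest of the simulation parameters.
#'
#' @param study dataset from [simulateStudy()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- study$geom$voxelSize
  wn <- function(x, f)
    RNifti::writeNifti(RNifti::asNifti(x, pixdim = rep(vs, 3)),
                       file.path(dir, f))
  wn(seriesData(study$series), "series.nii.gz")
  utils::write.table(frameInfo(study$series),
                     file.path(dir, "frames.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(study$truth@maps))
    wn(study$truth@maps[[nm]], paste0("truth_", nm, ".nii.gz"))
  tr <- study$trace
  utils::write.table(
    data.frame(time = tr@time, pO2 = tr@pO2, pCO2 = tr@pCO2),
    file.path(dir, "respiratory.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    shape = study$truth@dim, seed = study$seed,
    noiseSd = study$truth@noiseSd, pb = study$pb,
    geometry = study$geom, constants = study$const,
    params = study$params[c("alpha", "beta", "rHC", "rHO", "teRef", "u")],
    conditions = study$conditions, levels = study$levels,
    traceRate = tr@rate,
    paradigm = list(totalDuration = totalDuration(study$paradigm),
                    hcBlocks = hcBlocks(study$paradigm),
                    hoBlocks = hoBlocks(study$paradigm)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study dataset written by [writeStudy()]
#'
#' @param dir directory containing the study files
#' @return dataset list in the layout of [simulateStudy()]
#' @export
readStudy <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  paradigm <- gasParadigm(man$paradigm$totalDuration,
                          matrix(man$paradigm$hcBlocks, ncol = 2),
                          matrix(man$paradigm$hoBlocks, ncol = 2))
  geom <- do.call(acquisitionGeometry, man$geometry)
  const <- do.call(perfusionConstants, man$constants)
  frames <- utils::read.delim(file.path(dir, "frames.tsv"))
  dat <- array(as.numeric(RNifti::readNifti(file.path(dir, "series.nii.gz"))),
               c(man$shape, nrow(frames)))
  series <- new("DualEchoSeries", data = dat, frames = frames,
                geometry = geom)
  maps <- list()
  for (nm in c("cbf0", "t2star0", "m", "oef", "gm", "fHC", "fHO", "s0"))
    maps[[nm]] <- array(as.numeric(
      RNifti::readNifti(file.path(dir, paste0("truth_", nm, ".nii.gz")))),
      man$shape)
  truth <- new("GroundTruth", dim = as.integer(man$shape), maps = maps,
               noiseSd = man$noiseSd,
               driftCoefs = matrix(0, prod(man$shape), 3),
               seed = as.integer(man$seed))
  rsp <- utils::read.delim(file.path(dir, "respiratory.tsv"))
  trace <- new("RespiratoryTrace", time = rsp$time, pO2 = rsp$pO2,
               pCO2 = rsp$pCO2, rate = man$traceRate)
  levels <- man$levels
  ## rebuild the programmed FI schedules for the attenuation correction
  attr(trace, "expectedFIO2") <- .channelTargets(paradigm, levels$o2)$fi
  attr(trace, "expectedFICO2") <- .channelTargets(paradigm, levels$co2)$fi
  params <- modelParams(alpha = man$params$alpha, beta = man$params$beta,
                        rHC = man$params$rHC, rHO = man$params$rHO,
                        teRef = man$params$teRef, u = man$params$u)
  list(truth = truth, trace = trace, series = series, paradigm = paradigm,
       geom = geom, params = params, const = const,
       conditions = man$conditions, levels = levels, pb = man$pb,
       seed = man$seed)
}

#' Write analysis result maps and summary
#'
#' M (percent), OEF, O2 delivery and CMRO2 maps as NIfTI, the exclusion
#' include mask, a subject summary JSON (GM means, detection rate, end-tidal
#' estimates) and the ROI detection table as TSV.
#'
#' @param result output of [analyzeStudy()]
#' @param dir output directory
#' @param voxelSize voxel size recorded in the NIfTI headers, mm
#' @return `dir`, invisibly
#' @export
writeAnalysis <- function(result, dir, voxelSize = 4.5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wn <- function(x, f)
    RNifti::writeNifti(RNifti::asNifti(x, pixdim = rep(voxelSize, 3)),
                       file.path(dir, f))
  sol <- result$solution
  wn(100 * sol$M, "M_percent.nii.gz")
  wn(sol$oef, "OEF.nii.gz")
  wn(sol$delivery, "O2delivery.nii.gz")
  wn(sol$cmro2, "CMRO2.nii.gz")
  wn(result$cbf$cbf0, "CBF0.nii.gz")
  wn(array(as.numeric(result$exclusion$include),
           dim(result$cbf$cbf0)), "include_mask.nii.gz")
  summary <- list(endTidal = result$endTidal,
                  gmMeans = as.list(result$gmMeans),
                  detectionRate = result$detectionRate,
                  gmMeanDPctCBFHO = result$cbf$gmMeanDPctCBFHO,
                  t1bHO = result$conditions$t1bHO,
                  exclusionCounts = as.list(result$counts))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sol$roiDetection))
    utils::write.table(
      data.frame(roi = names(sol$roiDetection),
                 detectionRate = sol$roiDetection),
      file.path(dir, "roi_detection.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
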