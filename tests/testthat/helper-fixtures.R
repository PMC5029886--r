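# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small noiseless study (6x6x3) analyzed without spatial filters; cached
noiselessStudy <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulateStudy(shape = c(6, 6, 3), seed = 7,
                                     noiseSd = 0)
    .fixtures$result <- analyzeStudy(.fixtures$study, fwhm = 0,
                                     medianRadius = 0)
  }
  list(study = .fixtures$study, result = .fixtures$result)
}

# brute-force intersection oracle: exhaustive minimization of |M_HC - M_HO|
# on a uniform OEF grid, independent of the bisection solver
bruteForceOEF <- function(responses, params = modelParams(), step = 1e-5) {
  E <- seq(params$oefBounds[1], params$oefBounds[2], by = step)
  bHC <- boldFraction(responses$dR2sHC, params$teRef)
  bHO <- boldFraction(responses$dR2sHO, params$teRef)
  g <- abs(gasCurve(E, bHC, responses$fHC, params$rHC, responses$cao2HC,
                    responses$cao20, params) -
           gasCurve(E, bHO, responses$fHO, params$rHO, responses$cao2HO,
                    responses$cao20, params))
  E[which.min(g)]
}
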