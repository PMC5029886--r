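#' Blood and oxygen-transport parameters
#'
#' Constants of the oxygen-transport model. `hb` is the hemoglobin
#' concentration (g Hb/dL blood), `phi` the O2-carrying capacity of
#' hemoglobin (mL O2/g Hb), `eps` the plasma solubility of O2
#' (mL O2/dL/mmHg), `t1b0` the baseline arterial blood T1 (s) and `kappa`
#' the slope of the blood R1 vs PaO2 relationship (s^-1/mmHg) governing T1
#' shortening under hyperoxia.
#'
#' @param hb g Hb/dL blood (default 15)
#' @param phi mL O2/g Hb (default 1.34)
#' @param eps mL O2/dL/mmHg (default 0.003)
#' @param t1b0 s (default 1.65)
#' @param kappa s^-1/mmHg (default 1.38e-4)
#' @return named list of validated parameters
#' @export
bloodParams <- function(hb = 15, phi = 1.34, eps = 0.003,
                        t1b0 = 1.65, kappa = 1.38e-4) {
  p <- list(hb = hb, phi = phi, eps = eps, t1b0 = t1b0, kappa = kappa)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1)) & names(p) != "kappa"))
    stop("blood parameters must be single positive numbers")
  if (kappa < 0) stop("kappa must be non-negative")
  p
}

#' Severinghaus hemoglobin-O2 dissociation curve
#'
#' Arterial O2 saturation as a function of arterial O2 partial pressure,
#' using the Severinghaus (1979) empirical form
#' \deqn{SaO2 = 1 / (23400 / (PaO2^3 + 150 PaO2) + 1).}
#' Strictly increasing in PaO2 with asymptote 1.
#'
#' @param pao2 arterial O2 partial pressure, mmHg (end-tidal O2 is used as a
#'   proxy, no alveolar-arterial gradient assumed)
#' @return saturation fraction in (0, 1]
#' @export
#' @examples
#' severinghausSaturation(111)  # ~0.983 at a typical room-air end-tidal O2
severinghausSaturation <- function(pao2) {
  if (any(pao2 <= 0)) stop("PaO2 must be positive")
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Arterial O2 content
#'
#' Total arterial O2 content: hemoglobin-bound plus dissolved,
#' \deqn{CaO2 = phi Hb SaO2 + eps PaO2} in mL O2/dL blood.
#'
#' @param pao2 arterial O2 partial pressure, mmHg
#' @param blood blood parameters from [bloodParams()]
#' @return list with `pao2`, `sao2` (fraction) and `cao2` (mL O2/dL)
#' @export
arterialO2Content <- function(pao2, blood = bloodParams()) {
  sao2 <- severinghausSaturation(pao2)
  list(pao2 = pao2, sao2 = sao2,
       cao2 = blood$phi * blood$hb * sao2 + blood$eps * pao2)
}

#' Venous deoxyhemoglobin ratio for a gas condition
#'
#' Fractional change in venous deoxyhemoglobin concentration
#' \eqn{[dHb]/[dHb]_0} during a gas challenge, from the O2-content balance:
#' \deqn{d = \frac{\phi Hb - CaO2_{gas} + (r/f)\,E\,CaO2_0}
#'               {\phi Hb - CaO2_0 + E\,CaO2_0}}
#' where E is the resting OEF, f the fractional CBF change and r the
#' fractional CMRO2 change during the challenge. Venous dissolved O2 is
#' neglected (deoxyhemoglobin from the total content deficit). Values with a
#' non-positive numerator or denominator are non-physical and returned as
#' `NA` (the calibration solver treats them as invalid curve points).
#'
#' @param oef0 resting oxygen extraction fraction, in (0,1); may be a vector
#' @param f fractional CBF change (CBF_gas/CBF_0), > 0
#' @param r fractional CMRO2 change (CMRO2_gas/CMRO2_0), > 0
#' @param cao2Gas,cao20 arterial O2 content during the gas block and at
#'   baseline, mL O2/dL
#' @param blood blood parameters from [bloodParams()]
#' @return d, same length as `oef0`; NA where non-physical
#' @export
dhbRatio <- function(oef0, f, r, cao2Gas, cao20, blood = bloodParams()) {
  if (any(f <= 0) || any(r <= 0)) stop("f and r must be positive")
  hbO2 <- blood$phi * blood$hb
  num <- hbO2 - cao2Gas + (r / f) * oef0 * cao20
  den <- hbO2 - cao20 + oef0 * cao20
  d <- num / den
  d[num <= 0 | den <= 0] <- NA_real_
  d
}

#' Arterial blood T1 under hyperoxia
#'
#' Dissolved molecular O2 is paramagnetic and shortens arterial blood T1.
#' The relaxation rate increases linearly with the PaO2 excess over
#' baseline: \deqn{T1 = 1 / (1/T1b_0 + \kappa (PaO2_{gas} - PaO2_0)).}
#'
#' @param pao2Gas PaO2 during hyperoxia, mmHg (must be >= `pao20`)
#' @param pao20 baseline PaO2, mmHg
#' @param blood blood parameters from [bloodParams()]
#' @return blood T1 in seconds, <= `blood$t1b0`
#' @export
#' @examples
#' bloodT1Hyperoxia(370, 111)  # ~1.557 s at a typical hyperoxic end-tidal O2
bloodT1Hyperoxia <- function(pao2Gas, pao20, blood = bloodParams()) {
  if (any(pao2Gas < pao20)) stop("pao2Gas must be >= pao20")
  1 / (1 / blood$t1b0 + blood$kappa * (pao2Gas - pao20))
}
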