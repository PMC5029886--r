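## Test-retest statistical machinery: difference statistics, within- and
## between-subject coefficients of variation, repeatability coefficient,
## the normality/heteroscedasticity-driven log-transform decision tree,
## paired tests, Bland-Altman summaries and multiplicity-corrected ROI
## comparisons.

.checkPaired <- function(a, b, nMin = 3L) {
  if (length(a) != length(b)) stop("testA and testB must have equal length")
  if (length(a) < nMin) stop("need at least ", nMin, " paired subjects")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
}

#' Difference statistics of a paired sample
#'
#' `dSD` is the sample standard deviation (n-1 denominator) of the
#' test-B-minus-test-A differences; the within-subject SD for two
#' measurements is \eqn{wsSD = dSD/\sqrt{2}}.
#'
#' @param a,b paired measurements (test A, test B), length >= 3
#' @return list with `dSD` and `wsSD`
#' @export
differenceStats <- function(a, b) {
  .checkPaired(a, b)
  dSD <- stats::sd(b - a)
  list(dSD = dSD, wsSD = dSD / sqrt(2))
}

#' Within-subject coefficient of variation
#'
#' Original scale: per subject, \eqn{wsSD_i = |B_i - A_i|/\sqrt 2} and
#' \eqn{mean_i = (A_i + B_i)/2};
#' \eqn{wsCV = 100 \sqrt{\mathrm{mean}_i[(wsSD_i/mean_i)^2]}}.
#' Log10 scale: \eqn{wsCV = 100\,(10^{wsSD_{log}} - 1)} with
#' \eqn{wsSD_{log}} the within-subject SD of the log10 data.
#'
#' @param a,b paired measurements
#' @param scale `"original"` or `"log10"`
#' @return wsCV in percent
#' @export
wsCV <- function(a, b, scale = c("original", "log10")) {
  scale <- match.arg(scale)
  .checkPaired(a, b)
  if (scale == "original") {
    means <- (a + b) / 2
    if (any(means == 0)) stop("zero subject mean")
    wssd <- abs(b - a) / sqrt(2)
    100 * sqrt(mean((wssd / means)^2))
  } else {
    if (any(a <= 0) || any(b <= 0)) stop("log scale requires positive values")
    100 * (10^(differenceStats(log10(a), log10(b))$wsSD) - 1)
  }
}

#' Coefficient of repeatability
#'
#' \eqn{CR = 1.96\,dSD = 1.96\sqrt{2}\,wsSD}: 95% of repeated differences
#' are expected within mean difference +/- CR.
#'
#' @param dSD standard deviation of the paired differences (>= 0)
#' @return CR
#' @export
repeatabilityCoefficient <- function(dSD) {
  if (any(dSD < 0)) stop("dSD must be non-negative")
  1.96 * dSD
}

#' Between-subject coefficient of variation
#'
#' SD over mean of the pooled test A and test B values, in percent.
#'
#' @param values pooled values (A and B together), nonzero mean
#' @return bsCV in percent
#' @export
bsCV <- function(values) {
  m <- mean(values)
  if (m == 0) stop("zero pooled mean")
  100 * stats::sd(values) / m
}

#' Log-transform decision tree
#'
#' Tests whether a paired sample satisfies the reproducibility-analysis
#' assumptions: normality of the differences (Shapiro-Wilk) and independence
#' of the difference magnitudes from the subject means (Kendall's tau,
#' two-sided), both at `alpha`. Failure of either triggers a retry on the
#' log10 data; if the log data pass, reproducibility is assessed on the log
#' scale; if they fail too, the original scale is kept with the
#' `"log10_failed"` annotation.
#'
#' @param a,b paired measurements
#' @param alpha significance level (default 0.05)
#' @return list with `scale` (`"original"`, `"log10"` or `"log10_failed"`),
#'   `pShapiro`, `pKendall` (for the scale examined last)
#' @export
transformDecision <- function(a, b, alpha = 0.05) {
  .checkPaired(a, b)
  check <- function(x, y) {
    d <- y - x
    pS <- stats::shapiro.test(d)$p.value
    pK <- suppressWarnings(
      stats::cor.test(abs(d), (x + y) / 2, method = "kendall",
                      exact = FALSE)$p.value)
    list(pShapiro = pS, pKendall = pK, ok = pS > alpha && pK > alpha)
  }
  orig <- check(a, b)
  if (orig$ok)
    return(list(scale = "original", pShapiro = orig$pShapiro,
                pKendall = orig$pKendall))
  if (any(a <= 0) || any(b <= 0))
    stop("log branch requires positive values")
  lg <- check(log10(a), log10(b))
  if (lg$ok)
    list(scale = "log10", pShapiro = lg$pShapiro, pKendall = lg$pKendall)
  else
    list(scale = "log10_failed", pShapiro = lg$pShapiro,
         pKendall = lg$pKendall)
}

#' Two-tailed paired t-test for an order effect
#'
#' @param a,b paired measurements (zero-variance differences are an error)
#' @return two-sided p-value
#' @export
pairedTTest <- function(a, b) {
  .checkPaired(a, b)
  if (stats::sd(b - a) == 0) stop("zero-variance differences")
  stats::t.test(b, a, paired = TRUE)$p.value
}

#' Bland-Altman summary
#'
#' Mean difference with limits of agreement at +/- the coefficient of
#' repeatability, and the fraction of paired differences inside the limits.
#'
#' @param a,b paired measurements
#' @param cr coefficient of repeatability; default `1.96 * sd(b - a)`
#' @return list with `meanDiff`, `lower`, `upper`, `fracWithin`, and the
#'   plotting coordinates `means`, `diffs`
#' @export
blandAltman <- function(a, b, cr = NULL) {
  .checkPaired(a, b)
  d <- b - a
  if (is.null(cr)) cr <- repeatabilityCoefficient(stats::sd(d))
  md <- mean(d)
  list(meanDiff = md, lower = md - cr, upper = md + cr,
       fracWithin = mean(d >= md - cr & d <= md + cr),
       means = (a + b) / 2, diffs = d)
}

#' Reproducibility metrics for one metric x ROI cell
#'
#' Runs the transform decision tree, then computes dSD, wsSD, wsCV, CR and
#' bsCV on the selected scale, plus the paired-t order-effect p-value (on
#' the original scale). The identities wsSD = dSD/sqrt(2) and
#' CR = 1.96 sqrt(2) wsSD hold by construction.
#'
#' @param a,b paired measurements
#' @param alpha significance level of the decision tree
#' @return list of class `"ReproMetrics"`
#' @export
reproMetrics <- function(a, b, alpha = 0.05) {
  dec <- transformDecision(a, b, alpha)
  onLog <- dec$scale == "log10"
  xa <- if (onLog) log10(a) else a
  xb <- if (onLog) log10(b) else b
  ds <- differenceStats(xa, xb)
  structure(list(
    scale = dec$scale,
    dSD = ds$dSD, wsSD = ds$wsSD,
    wsCV = wsCV(a, b, scale = if (onLog) "log10" else "original"),
    CR = repeatabilityCoefficient(ds$dSD),
    bsCV = bsCV(c(a, b)),
    pShapiro = dec$pShapiro, pKendall = dec$pKendall,
    pPairedT = pairedTTest(a, b),
    n = length(a)), class = "ReproMetrics")
}

#' @export
print.ReproMetrics <- function(x, ...) {
  cat(sprintf(
    "ReproMetrics (n=%d, scale=%s): wsCV %.2f%%, CR %.3g, bsCV %.2f%%, paired-t p=%.3g\n",
    x$n, x$scale, x$wsCV, x$CR, x$bsCV, x$pPairedT))
  invisible(x)
}

#' Pairwise ROI comparisons with multiplicity correction
#'
#' All pairwise two-sample comparisons of pooled per-ROI values (Welch
#' t-test), corrected over the ROI pairs (Bonferroni by default), with each
#' pair binned into the significance categories ns, <0.05, <0.005, <0.0005.
#'
#' @param values named list: one numeric vector of pooled values per ROI
#' @param alpha base significance level (default 0.05)
#' @param method multiplicity correction, `"bonferroni"` or `"holm"`
#' @return data.frame with columns roi1, roi2, p (corrected), category
#' @export
compareROIs <- function(values, alpha = 0.05, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need at least 2 ROIs")
  if (any(vapply(values, length, integer(1)) < 2L))
    stop("insufficient data per ROI")
  nms <- names(values)
  pairs <- utils::combn(nms, 2)
  p <- apply(pairs, 2, function(pr)
    stats::t.test(values[[pr[1]]], values[[pr[2]]])$p.value)
  p <- stats::p.adjust(p, method = method)
  cat <- cut(p, breaks = c(-Inf, 0.0005, 0.005, alpha, Inf),
             labels = c("<0.0005", "<0.005", "<0.05", "ns"))
  data.frame(roi1 = pairs[1, ], roi2 = pairs[2, ], p = p,
             category = as.character(cat), stringsAsFactors = FALSE)
}

#' Reproducibility report over a long-format two-session table
#'
#' For every metric x ROI combination with matched subjects in both
#' sessions, computes the full [reproMetrics()] cell.
#'
#' @param data data.frame with columns `subject`, `test` (two levels),
#'   `roi`, `metric`, `value`
#' @param tests the two session labels (default the sorted unique values)
#' @return data.frame, one row per metric x ROI
#' @export
reproducibilityReport <- function(data, tests = NULL) {
  need <- c("subject", "test", "roi", "metric", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (is.null(tests)) tests <- sort(unique(as.character(data$test)))
  if (length(tests) != 2L) stop("need exactly two sessions")
  out <- list()
  for (met in unique(data$metric)) for (roi in unique(data$roi)) {
    sub <- data[data$metric == met & data$roi == roi, ]
    if (!nrow(sub)) next
    a <- sub[sub$test == tests[1], ]
    b <- sub[sub$test == tests[2], ]
    common <- intersect(a$subject, b$subject)
    if (length(common) < length(unique(sub$subject)))
      stop("unmatched subjects for ", met, " in ", roi)
    a <- a$value[match(common, a$subject)]
    b <- b$value[match(common, b$subject)]
    rm <- reproMetrics(a, b)
    out[[length(out) + 1L]] <- data.frame(
      metric = met, roi = roi, n = rm$n, scale = rm$scale,
      dSD = rm$dSD, wsSD = rm$wsSD, wsCV = rm$wsCV, CR = rm$CR,
      bsCV = rm$bsCV, pShapiro = rm$pShapiro, pKendall = rm$pKendall,
      pPairedT = rm$pPairedT, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
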