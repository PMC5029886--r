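test_that("difference statistics match hand computations", {
  expect_equal(differenceStats(c(1, 2, 3), c(1, 2, 3)),
               list(dSD = 0, wsSD = 0))
  ds <- differenceStats(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(ds$dSD, 1)
  expect_equal(ds$wsSD, 0.7071, tolerance = 1e-4)
  # shift invariance
  a <- c(10, 12, 14, 9); b <- c(11, 11, 15, 10)
  expect_equal(differenceStats(a + 7, b + 7)$dSD, differenceStats(a, b)$dSD)
  expect_error(differenceStats(1:2, 2:3), "at least 3")
})

test_that("wsCV matches its per-subject definition on both scales", {
  a <- c(90, 90, 90); b <- c(110, 110, 110)
  # per subject: wsSD = 20/sqrt(2) = 14.142, mean = 100 -> 14.14%
  expect_equal(wsCV(a, b), 14.14, tolerance = 1e-2)
  expect_equal(wsCV(a, a), 0)
  # log scale: zero log-wsSD gives 0%
  expect_equal(wsCV(a, a, scale = "log10"), 0)
  expect_error(wsCV(c(-1, 2, 3), c(1, 2, 3), scale = "log10"), "positive")
  expect_error(wsCV(c(-1, 1, 2), c(1, -1, 2)), "zero subject mean")
})

test_that("repeatability coefficient brackets 95% of repeated differences", {
  expect_equal(repeatabilityCoefficient(0), 0)
  expect_equal(repeatabilityCoefficient(6.63), 13.0, tolerance = 0.01)
  set.seed(11)
  d <- rnorm(10000, sd = 3)
  cr <- repeatabilityCoefficient(sd(d))
  expect_equal(mean(abs(d - mean(d)) <= cr), 0.95, tolerance = 0.01)
})

test_that("bsCV is the pooled SD over mean and scale-invariant", {
  expect_equal(bsCV(c(5, 5, 5)), 0)
  expect_equal(bsCV(c(8, 12)), 28.28, tolerance = 1e-2)
  x <- c(3, 9, 5, 7)
  expect_equal(bsCV(3.7 * x), bsCV(x))
})

test_that("transform decision keeps additive data and logs multiplicative", {
  # i.i.d. normal differences independent of the means: stays original in
  # about 1 - alpha of replicates (two tests, correlated pass events)
  set.seed(101)
  keep <- replicate(300, {
    a <- rnorm(8, 100, 10); b <- a + rnorm(8, 0, 3)
    transformDecision(a, b)$scale == "original"
  })
  expect_gt(mean(keep), 0.85)
  # multiplicative error (SD proportional to the mean over a wide spread):
  # the log scale is selected in most replicates where original fails
  set.seed(102)
  res <- replicate(1000, {
    mu <- exp(runif(7, log(5), log(500)))
    a <- mu * exp(rnorm(7, 0, 0.25)); b <- mu * exp(rnorm(7, 0, 0.25))
    transformDecision(a, b)$scale
  })
  moved <- res[res != "original"]
  expect_gt(mean(moved == "log10"), 0.90)
  expect_error(transformDecision(c(0, 1, 2, 30), c(5, 1, 2, 1)),
               "positive")
})

test_that("paired t-test is calibrated under the null and powered", {
  expect_error(pairedTTest(c(1, 2, 3), c(1, 2, 3) + 2), "zero-variance")
  set.seed(5)
  p <- replicate(4000, {
    a <- rnorm(7); b <- a + rnorm(7)
    pairedTTest(a, b)
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  set.seed(6)
  pw <- replicate(500, {
    a <- rnorm(7, sd = 1); b <- a + rnorm(7, mean = 2, sd = 1)
    pairedTTest(a, b) < 0.05
  })
  expect_gt(mean(pw), 0.9)
})

test_that("Bland-Altman limits have width 2 CR and ~95% coverage", {
  a <- c(10, 11, 12, 13); b <- c(12, 9, 14, 11)
  ba <- blandAltman(a, b, cr = 3)
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$upper - ba$lower, 6)
  set.seed(7)
  a <- rnorm(5000, 50, 5); b <- a + rnorm(5000, 0, 2)
  ba2 <- blandAltman(a, b)
  expect_equal(ba2$fracWithin, 0.95, tolerance = 0.01)
})

test_that("ReproMetrics identities hold for every computed cell", {
  set.seed(8)
  for (i in 1:5) {
    a <- rlnorm(9, 3, 0.3); b <- a * rlnorm(9, 0, 0.1)
    rm <- reproMetrics(a, b)
    expect_equal(rm$wsSD, rm$dSD / sqrt(2))
    expect_equal(rm$CR, 1.96 * sqrt(2) * rm$wsSD)
    expect_gte(rm$wsCV, 0)
    expect_gte(rm$bsCV, 0)
    # subject-order invariance
    o <- sample(9)
    rm2 <- reproMetrics(a[o], b[o])
    expect_equal(rm2$wsCV, rm$wsCV)
    expect_equal(rm2$pPairedT, rm$pPairedT)
  }
})

test_that("ROI comparisons bin corrected p-values into the category scale", {
  set.seed(9)
  # identical distributions: everything ns
  vals <- lapply(1:4, function(i) rnorm(14, 10, 2))
  names(vals) <- paste0("roi", 1:4)
  cmp <- compareROIs(vals)
  expect_equal(nrow(cmp), choose(4, 2))
  expect_true(mean(cmp$category == "ns") > 0.8)
  # two ROIs separated by 10 SD land in the most extreme bin
  vals2 <- list(a = rnorm(14, 0, 1), b = rnorm(14, 10, 1))
  expect_equal(compareROIs(vals2)$category, "<0.0005")
  expect_error(compareROIs(vals[1]), "at least 2")
})

test_that("the two-session report recovers an injected within-subject CV", {
  set.seed(10)
  n <- 60
  mu <- rnorm(n, 100, 15)
  a <- mu * (1 + rnorm(n, 0, 0.1))
  b <- mu * (1 + rnorm(n, 0, 0.1))
  dat <- rbind(
    data.frame(subject = 1:n, test = "A", roi = "GM", metric = "cbf0",
               value = a),
    data.frame(subject = 1:n, test = "B", roi = "GM", metric = "cbf0",
               value = b))
  rep <- reproducibilityReport(dat)
  expect_equal(nrow(rep), 1)
  # true within-subject CV = sqrt(2)*10%/sqrt(2) = 10%, sampling error wide
  expect_equal(rep$wsCV, 10, tolerance = 2.5)
  # identical sessions: wsCV 0
  datB <- dat; datB$value[datB$test == "B"] <- datB$value[datB$test == "A"]
  # zero-variance differences break the paired t; use near-identical copy
  datB$value[datB$test == "B"] <- datB$value[datB$test == "A"] *
    (1 + rnorm(n, 0, 1e-9))
  repB <- reproducibilityReport(datB)
  expect_lt(repB$wsCV, 1e-6)
  bad <- dat[-1, ]
  expect_error(reproducibilityReport(bad), "unmatched")
})
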