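test_that("normality screening is calibrated and detects non-normality", {
  set.seed(41)
  pvals <- vapply(seq_len(100), function(i)
    ksNormality(rnorm(1000))$p.value, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.94)
  expect_lt(ksNormality(runif(1000))$p.value, 0.01)
  deg <- ksNormality(c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_error(ksNormality(c(1, 2)), "at least 3")
})

test_that("pooled t from summaries equals pooled t on matching raw data", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    a <- independentTTest(x, y)
    b <- summaryTTest(length(x), mean(x), sd(x),
                      length(y), mean(y), sd(y))
    expect_equal(a$t, b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_identical(a$df, length(x) + length(y) - 2)
    # cross-check against the reference pooled t implementation
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  }
  same <- independentTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(summaryTTest(5, 2, 0, 5, 2, 0)$degenerate)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    subj <- rnorm(n, 10, 2)
    ratings <- cbind(subj + rnorm(n, 0, 0.5),
                     subj + rnorm(n, 0.3, 0.5))
    res <- iccTwoReader(ratings)
    expect_equal(res$icc, aovICC21(ratings), tolerance = 1e-6)
    expect_lte(res$ci_low, res$icc)
    expect_gte(res$ci_high, res$icc)
  }
})

test_that("ICC endpoints behave: identity, noise floor, band labels", {
  x <- rnorm(40, 5)
  perfect <- iccTwoReader(cbind(x, x))
  expect_equal(perfect$icc, 1)
  expect_identical(perfect$band, "excellent")
  set.seed(31)
  subj <- rnorm(40, 0, 1)
  noisy <- cbind(subj + rnorm(40, 0, 20), subj + rnorm(40, 0, 20))
  res <- iccTwoReader(noisy)
  expect_lt(res$icc, 0.2)
  expect_identical(res$band, "poor")
  expect_error(iccTwoReader(cbind(1:4, 1:4)), "at least 5")
})

test_that("Bland-Altman bias and limits follow the closed form", {
  x <- c(5, 6, 7, 8)
  same <- blandAltman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  two <- blandAltman(c(0, 2), c(1, 1)) # differences -1, +1
  expect_equal(two$bias, 0)
  expect_equal(two$loa_high, 1.96 * sqrt(2))
  offset <- blandAltman(x + 3, x)
  expect_equal(offset$bias, 3)
  expect_equal(offset$loa_low, offset$loa_high)
  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("ROC analysis equals exhaustive pair counting", {
  r <- rocAnalysis(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1")
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(rocAnalysis(c(1, 3, 2, 4), c(0, 0, 1, 1),
                           positive = "1")$auc, 0.75)
  expect_equal(rocAnalysis(c(1, 1, 2, 2), c(0, 1, 0, 1),
                           positive = "1")$auc, 0.5)
  set.seed(53)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    values <- sample(1:6, n, replace = TRUE) # heavy ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- rocAnalysis(values, labels, positive = "1")
    oriented <- if (r$direction == ">") values else -values
    expect_identical(r$auc, bruteForceAUC(oriented, labels, "1"))
    # Youden identity holds exactly for the reported operating point
    expect_identical(r$youden, r$sensitivity + r$specificity - 1)
  }
})

test_that("marker orientation is auto-selected and recorded", {
  values <- c(4, 3, 2, 1)
  labels <- c(1, 1, 0, 0) # positives carry the high values
  r <- rocAnalysis(values, labels, positive = "1")
  expect_identical(r$direction, ">")
  rInv <- rocAnalysis(-values, labels, positive = "1")
  expect_identical(rInv$direction, "<")
  expect_equal(rInv$auc, r$auc)
  expect_error(rocAnalysis(1:4, rep(1, 4), positive = "1"), "two classes")
})

test_that("the ROC agrees with an established reference", {
  skip_if_not_installed("pROC")
  set.seed(61)
  values <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  mine <- rocAnalysis(values, labels, positive = "1")
  ref <- pROC::roc(labels, values, quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)],
               tolerance = 1e-9)
})

test_that("Youden index is sensitivity + specificity - 1", {
  expect_equal(round(youdenFromRates(0.8636, 0.6111), 4), 0.4747)
  expect_equal(youdenFromRates(1, 1), 1)
  expect_equal(youdenFromRates(0.5, 0.5), 0)
  expect_error(youdenFromRates(1.2, 0.5), "must lie")
})

test_that("DeLong comparison handles identity and detects separation", {
  set.seed(71)
  v <- rnorm(40)
  labels <- rep(0:1, 20)
  same <- delongCompare(v, v, labels, positive = "1")
  expect_equal(same$p, 1)
  expect_equal(same$diff, 0)
  # power: clearly different AUCs are flagged most of the time
  reject <- vapply(seq_len(500), function(i) {
    y <- rep(0:1, each = 200)
    a <- rnorm(400, y * 2.33) # binormal AUC ~0.95
    b <- rnorm(400, y * 0.95) # binormal AUC ~0.75
    delongCompare(a, b, y, positive = "1")$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})

test_that("DeLong comparison agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  y <- rbinom(80, 1, 0.5)
  a <- rnorm(80, y * 1.2)
  b <- rnorm(80, y * 0.4)
  mine <- delongCompare(a, b, y, positive = "1")
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(79)
  width <- function(n) {
    y <- rep(0:1, each = n)
    r <- rocAnalysis(rnorm(2 * n, y * 1.1), y, positive = "1")
    r$ci_high - r$ci_low
  }
  w1 <- median(vapply(1:30, function(i) width(50), numeric(1)))
  w2 <- median(vapply(1:30, function(i) width(450), numeric(1)))
  expect_lt(w2, w1 / 2) # 9x the n should shrink the CI about 3x
})
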