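#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample (the Lilliefors correction, required because
#' naive KS p-values are anti-conservative with estimated parameters).
#' Samples with zero variance are flagged degenerate rather than tested;
#' for n < 5 only the D statistic is returned (the p approximation needs
#' n >= 5).
#'
#' @param x numeric sample, n >= 3.
#' @return list: statistic (D), p.value, n, degenerate flag.
#' @export
ksNormality <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, n = n,
                degenerate = TRUE))
  if (n < 5L) {
    z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
    D <- max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n))
    return(list(statistic = D, p.value = NA_real_, n = n,
                degenerate = FALSE))
  }
  kt <- nortest::lillie.test(x)
  list(statistic = unname(kt$statistic), p.value = kt$p.value, n = n,
       degenerate = FALSE)
}

.tResult <- function(t, df, p, m1, s1, n1, m2, s2, n2, degenerate = FALSE)
  list(t = t, df = df, p = p,
       mean1 = m1, sd1 = s1, n1 = n1, mean2 = m2, sd2 = s2, n2 = n2,
       degenerate = degenerate)

#' Pooled two-sample t test from summary statistics
#'
#' Student (pooled-variance) independent-samples t computed directly from
#' per-group n, mean and SD, with df = n1 + n2 - 2. The sign convention is
#' mean2 - mean1, so a positive t means group 2 is larger.
#'
#' @param n1,mean1,sd1 first group summaries.
#' @param n2,mean2,sd2 second group summaries.
#' @return list: t, df, p (two-sided), per-group summaries.
#' @export
summaryTTest <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2)
      return(.tResult(NA_real_, df, NA_real_, mean1, sd1, n1, mean2, sd2,
                      n2, degenerate = TRUE))
    return(.tResult(sign(mean2 - mean1) * Inf, df, 0, mean1, sd1, n1,
                    mean2, sd2, n2))
  }
  t <- (mean2 - mean1) / se
  .tResult(t, df, 2 * stats::pt(-abs(t), df), mean1, sd1, n1, mean2, sd2,
           n2)
}

#' Pooled two-sample t test on raw samples
#'
#' @param group1,group2 numeric samples, each n >= 2.
#' @return as \code{\link{summaryTTest}}.
#' @export
independentTTest <- function(group1, group2) {
  g1 <- group1[!is.na(group1)]; g2 <- group2[!is.na(group2)]
  summaryTTest(length(g1), mean(g1), stats::sd(g1),
               length(g2), mean(g2), stats::sd(g2))
}

.iccBand <- function(icc) {
  if (icc <= 0.20) "poor"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "good"
  else "excellent"
}

#' Two-way random-effects absolute-agreement ICC, single measures
#'
#' ICC(2,1): subjects and raters are both random effects and systematic
#' rater offsets count as disagreement. Computed from the two-way ANOVA
#' mean squares, with the F-based 95% confidence interval of McGraw and
#' Wong. The agreement band uses the conventional cutpoints
#' 0.20/0.40/0.60/0.80 (poor/fair/moderate/good/excellent).
#'
#' @param ratings numeric matrix, one row per subject, one column per
#'   rater (typically two). Rows with missing values are dropped
#'   listwise.
#' @param conf.level confidence level for the interval.
#' @return list: icc, ci_low, ci_high, band, model, n, k, n_dropped.
#' @export
iccTwoReader <- function(ratings, conf.level = 0.95) {
  ratings <- as.matrix(ratings)
  complete <- stats::complete.cases(ratings)
  dropped <- sum(!complete)
  ratings <- ratings[complete, , drop = FALSE]
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 complete subjects")
  if (k < 2L) stop("need at least 2 raters")
  gm <- mean(ratings)
  SSR <- k * sum((rowMeans(ratings) - gm)^2)
  SSC <- n * sum((colMeans(ratings) - gm)^2)
  SST <- sum((ratings - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  if (isTRUE(all.equal(icc, 1)) || icc > 1) # perfect agreement: exact CI
    return(list(icc = 1, ci_low = 1, ci_high = 1, band = "excellent",
                model = "ICC(2,1)", n = n, k = k, n_dropped = dropped))
  alpha <- 1 - conf.level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci_low = lower, ci_high = upper,
       band = .iccBand(icc), model = "ICC(2,1)", n = n, k = k,
       n_dropped = dropped)
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean difference reader1 - reader2) and 95% limits of agreement
#' bias +/- 1.96 SD of the paired differences.
#'
#' @param reader1,reader2 paired numeric vectors.
#' @return list: bias, loa_low, loa_high, sd_diff, n.
#' @export
blandAltman <- function(reader1, reader2) {
  ok <- !is.na(reader1) & !is.na(reader2)
  d <- reader1[ok] - reader2[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * sdd,
       loa_high = bias + 1.96 * sdd, sd_diff = sdd, n = length(d))
}

#' Youden index from sensitivity and specificity
#'
#' J = sensitivity + specificity - 1.
#'
#' @param sensitivity,specificity proportions in [0, 1].
#' @return J.
#' @export
youdenFromRates <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

## Placement values: for each positive, the fraction of negatives it beats
## (ties count 1/2), and vice versa. Their means equal the AUC; their
## variances drive the DeLong machinery. The AUC itself is computed by the
## rank-sum identity, whose half-integer concordance total is exact in
## floating point and so matches exhaustive pair counting bit for bit.
.placements <- function(pos, neg) {
  v10 <- vapply(pos, function(x)
    mean((x > neg) + 0.5 * (x == neg)), numeric(1L))
  v01 <- vapply(neg, function(y)
    mean((pos > y) + 0.5 * (pos == y)), numeric(1L))
  m <- length(pos); n <- length(neg)
  concordant <- sum(rank(c(pos, neg), ties.method = "average")[seq_len(m)]) -
    m * (m + 1) / 2
  list(v10 = v10, v01 = v01, auc = concordant / (m * n))
}

.splitClasses <- function(values, labels, positive) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- classes[2L]
  if (!positive %in% classes) stop("positive class not present in labels")
  list(pos = values[labels == positive], neg = values[labels != positive],
       positive = positive)
}

#' Empirical ROC analysis with Youden-optimal cutoff and DeLong CI
#'
#' The AUC follows the Mann-Whitney convention (ties count 1/2). The
#' marker orientation is chosen so that AUC >= 0.5 and recorded:
#' direction ">" means higher values call the positive class,
#' "<" means lower values do. Candidate cutoffs are the midpoints between
#' consecutive distinct observed values plus the two infinities; the
#' reported cutoff maximises Youden's J, with ties broken toward higher
#' specificity. The 95% CI uses the DeLong placement-value variance,
#' truncated to [0, 1].
#'
#' @param values numeric marker values, one per subject.
#' @param labels two-class labels aligned with \code{values}.
#' @param positive label of the class to detect (default: second unique
#'   label).
#' @param conf.level confidence level.
#' @return list: auc, ci_low, ci_high, cutoff, sensitivity, specificity,
#'   youden, direction, n_pos, n_neg.
#' @export
rocAnalysis <- function(values, labels, positive = NULL,
                        conf.level = 0.95) {
  ok <- !is.na(values) & !is.na(labels)
  sc <- .splitClasses(values[ok], labels[ok], positive)
  pos <- sc$pos; neg <- sc$neg
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  pl <- .placements(pos, neg)
  direction <- ">"
  if (pl$auc < 0.5) { # lower marker values call the positive class
    direction <- "<"
    pos <- -pos; neg <- -neg
    pl <- .placements(pos, neg)
  }
  se2 <- stats::var(pl$v10) / length(pos) +
    stats::var(pl$v01) / length(neg)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(se2), 0), 1)

  u <- sort(unique(c(pos, neg)))
  cuts <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  sens <- vapply(cuts, function(t) mean(pos > t), numeric(1L))
  spec <- vapply(cuts, function(t) mean(neg <= t), numeric(1L))
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[which.max(spec[best])] # tie: prefer higher specificity
  cutoff <- if (direction == "<") -cuts[best] else cuts[best]
  list(auc = pl$auc, ci_low = ci[1L], ci_high = ci[2L],
       cutoff = unname(cutoff), sensitivity = sens[best],
       specificity = spec[best], youden = J[best], direction = direction,
       n_pos = length(pos), n_neg = length(neg))
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both markers are measured on the same subjects; the test accounts for
#' their correlation through the covariance of the placement values.
#' Marker orientation is supplied by the caller (typically the direction
#' recorded by \code{\link{rocAnalysis}}): "<" negates the marker so that
#' its AUC magnitude is compared, matching how markers with opposite
#' directionality are reported. Orientation is deliberately not inferred
#' from the data here — re-orienting both markers toward AUC >= 0.5 inside
#' the test would fold the null distribution of the AUC difference and
#' destroy the test's size. Two-sided normal p-value.
#'
#' @param valuesA,valuesB marker values on the same subjects.
#' @param labels shared two-class labels.
#' @param positive label of the positive class.
#' @param directionA,directionB ">" if higher marker values indicate the
#'   positive class (default), "<" otherwise.
#' @return list: aucA, aucB, diff (A - B), z, p.
#' @export
delongCompare <- function(valuesA, valuesB, labels, positive = NULL,
                          directionA = ">", directionB = ">") {
  if (length(valuesA) != length(valuesB) ||
      length(valuesA) != length(labels))
    stop("valuesA, valuesB and labels must be aligned")
  if (directionA == "<") valuesA <- -valuesA
  if (directionB == "<") valuesB <- -valuesB
  ok <- !is.na(valuesA) & !is.na(valuesB) & !is.na(labels)
  sa <- .splitClasses(valuesA[ok], labels[ok], positive)
  sb <- .splitClasses(valuesB[ok], labels[ok], sa$positive)
  pa <- .placements(sa$pos, sa$neg)
  pb <- .placements(sb$pos, sb$neg)
  m <- length(sa$pos); n <- length(sa$neg)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varDiff <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
    (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  diff <- pa$auc - pb$auc
  if (varDiff <= 0) {
    p <- if (diff == 0) 1 else 0
    return(list(aucA = pa$auc, aucB = pb$auc, diff = diff,
                z = if (diff == 0) 0 else sign(diff) * Inf, p = p))
  }
  z <- diff / sqrt(varDiff)
  list(aucA = pa$auc, aucB = pb$auc, diff = diff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
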