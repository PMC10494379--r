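.parameters <- c("adc", "d", "d_star", "f", "ddc", "alpha")
## display convention: diffusion coefficients printed x10^-3 mm^2/s
.displayScale <- c(adc = 1e3, d = 1e3, d_star = 1e3, f = 1,
                   ddc = 1e3, alpha = 1)

#' Run the full diagnostic-statistics chain on a lesion table
#'
#' Per diffusion parameter: Lilliefors normality per group, pooled
#' independent-samples t test between groups, ICC(2,1) and Bland-Altman
#' interobserver agreement (when at least two readers are present), ROC
#' analysis with Youden-optimal cutoff and DeLong 95% CI, and pairwise
#' DeLong comparisons of all parameter AUCs. Group statistics and ROC use
#' the reader-averaged value per subject; agreement uses the first two
#' readers. No multiple-testing correction is applied (recorded in the
#' metadata).
#'
#' @param table lesion table as from \code{\link{buildLesionTable}}:
#'   columns subject, group, reader, adc, d, d_star, f, ddc, alpha.
#' @param positive group label treated as the positive (detected) class;
#'   default "progression".
#' @param conf.level confidence level for intervals.
#' @return a \linkS4class{DiagnosticReport}.
#' @export
buildReport <- function(table, positive = "progression",
                        conf.level = 0.95) {
  need <- c("subject", "group", "reader", .parameters)
  if (!all(need %in% names(table)))
    stop("lesion table must have columns ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("empty lesion table")
  groupsOf <- tapply(table$group, table$subject, `[`, 1L)
  if (length(unique(table$group)) != 2L)
    stop("need exactly two groups")
  if (!positive %in% table$group)
    stop("positive group '", positive, "' not present")
  readers <- sort(unique(table$reader))

  ## reader-averaged per-subject values
  subj <- sort(unique(table$subject))
  avg <- data.frame(subject = subj, group = unname(groupsOf[subj]))
  for (p in .parameters)
    avg[[p]] <- as.numeric(tapply(table[[p]], table$subject,
                                  mean, na.rm = TRUE)[subj])

  neg <- setdiff(unique(avg$group), positive)
  groupStats <- normality <- performance <- agreement <- NULL
  for (p in .parameters) {
    g1 <- avg[[p]][avg$group == positive]
    g2 <- avg[[p]][avg$group == neg]
    tt <- independentTTest(g1, g2)
    groupStats <- rbind(groupStats, data.frame(
      parameter = p, mean_pos = tt$mean1, sd_pos = tt$sd1, n_pos = tt$n1,
      mean_neg = tt$mean2, sd_neg = tt$sd2, n_neg = tt$n2,
      t = tt$t, df = tt$df, p = tt$p))
    for (g in c(positive, neg)) {
      vals <- avg[[p]][avg$group == g]
      ks <- if (length(vals) >= 3L) ksNormality(vals)
      else list(statistic = NA_real_, p.value = NA_real_,
                degenerate = TRUE) # too few lesions to screen
      normality <- rbind(normality, data.frame(
        parameter = p, group = g, D = ks$statistic, p = ks$p.value,
        degenerate = ks$degenerate))
    }
    roc <- rocAnalysis(avg[[p]], avg$group, positive = positive,
                       conf.level = conf.level)
    performance <- rbind(performance, data.frame(
      parameter = p, auc = roc$auc, auc_ci_low = roc$ci_low,
      auc_ci_high = roc$ci_high, cutoff = roc$cutoff,
      youden = roc$youden, sensitivity = roc$sensitivity,
      specificity = roc$specificity, direction = roc$direction))
    if (length(readers) >= 2L) {
      r1 <- table[table$reader == readers[1L], c("subject", p)]
      r2 <- table[table$reader == readers[2L], c("subject", p)]
      merged <- merge(r1, r2, by = "subject")
      icc <- iccTwoReader(as.matrix(merged[, -1L]),
                          conf.level = conf.level)
      ba <- blandAltman(merged[[2L]], merged[[3L]])
      agreement <- rbind(agreement, data.frame(
        parameter = p, icc = icc$icc, icc_ci_low = icc$ci_low,
        icc_ci_high = icc$ci_high, band = icc$band, bias = ba$bias,
        loa_low = ba$loa_low, loa_high = ba$loa_high, n_pairs = ba$n))
    }
  }
  if (is.null(agreement))
    agreement <- data.frame(parameter = character(0L), icc = numeric(0L),
                            icc_ci_low = numeric(0L),
                            icc_ci_high = numeric(0L),
                            band = character(0L), bias = numeric(0L),
                            loa_low = numeric(0L), loa_high = numeric(0L),
                            n_pairs = integer(0L))

  pairs <- utils::combn(.parameters, 2L)
  dirOf <- stats::setNames(performance$direction, performance$parameter)
  aucComparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    dl <- delongCompare(avg[[a]], avg[[b]], avg$group,
                        positive = positive,
                        directionA = dirOf[[a]], directionB = dirOf[[b]])
    data.frame(parameter_a = a, parameter_b = b, auc_a = dl$aucA,
               auc_b = dl$aucB, diff = dl$diff, z = dl$z, p = dl$p)
  }))

  new("DiagnosticReport", groupStats = groupStats, agreement = agreement,
      performance = performance, aucComparisons = aucComparisons,
      normality = normality,
      metadata = list(positive = positive, negative = neg,
                      readers = readers,
                      n_pos = sum(avg$group == positive),
                      n_neg = sum(avg$group == neg),
                      multiple_testing = "none",
                      units = "diffusion coefficients in mm^2/s; display x10^3"))
}

.scaleCol <- function(df, col, params = df$parameter)
  df[[col]] * unname(.displayScale[params])

#' Table-style summaries of a diagnostic report
#'
#' \code{groupComparisonTable} mirrors the group-comparison layout
#' (means +/- SD per group, t, p, ICC); \code{performanceTable} mirrors
#' the diagnostic-performance layout (AUC, 95% CI, cutoff, Youden,
#' sensitivity, specificity). Diffusion coefficients and cutoffs are
#' scaled x10^3 into the conventional "x10^-3" display units.
#'
#' @param report a \linkS4class{DiagnosticReport}.
#' @return data.frame.
#' @export
groupComparisonTable <- function(report) {
  gs <- report@groupStats
  out <- data.frame(
    parameter = gs$parameter,
    mean_pos = .scaleCol(gs, "mean_pos"), sd_pos = .scaleCol(gs, "sd_pos"),
    mean_neg = .scaleCol(gs, "mean_neg"), sd_neg = .scaleCol(gs, "sd_neg"),
    t = abs(gs$t), p = gs$p)
  if (nrow(report@agreement))
    out$icc <- report@agreement$icc[match(out$parameter,
                                          report@agreement$parameter)]
  out
}

#' @rdname groupComparisonTable
#' @export
performanceTable <- function(report) {
  pf <- report@performance
  data.frame(parameter = pf$parameter, auc = pf$auc,
             ci_low = pf$auc_ci_low, ci_high = pf$auc_ci_high,
             cutoff = .scaleCol(pf, "cutoff"), youden = pf$youden,
             sensitivity = pf$sensitivity, specificity = pf$specificity,
             direction = pf$direction)
}

setMethod("show", "DiagnosticReport", function(object) {
  md <- object@metadata
  cat("DiagnosticReport:", md$positive, "(n =", md$n_pos, ") vs",
      md$negative, "(n =", md$n_neg, ")\n\n")
  cat("Group comparison (diffusion coefficients x10^-3 mm^2/s):\n")
  print(format(groupComparisonTable(object), digits = 3))
  cat("\nDiagnostic performance:\n")
  print(format(performanceTable(object), digits = 3))
  sig <- object@aucComparisons$p < 0.05
  cat("\nPairwise DeLong AUC comparisons:",
      sum(sig), "of", length(sig), "significant at 0.05\n")
  invisible(object)
})

#' Write a diagnostic report to disk
#'
#' Emits the full report as JSON plus two flat CSVs (group comparison and
#' diagnostic performance in display units).
#'
#' @param report a \linkS4class{DiagnosticReport}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "report.json"),
             group = file.path(dir, "group_comparison.csv"),
             perf = file.path(dir, "diagnostic_performance.csv"),
             delong = file.path(dir, "auc_comparisons.csv"))
  payload <- list(metadata = report@metadata,
                  group_stats = report@groupStats,
                  agreement = report@agreement,
                  performance = report@performance,
                  auc_comparisons = report@aucComparisons,
                  normality = report@normality)
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(groupComparisonTable(report), paths["group"],
                   row.names = FALSE)
  utils::write.csv(performanceTable(report), paths["perf"],
                   row.names = FALSE)
  utils::write.csv(report@aucComparisons, paths["delong"],
                   row.names = FALSE)
  invisible(paths)
}
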