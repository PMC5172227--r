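## Population-level statistics over per-cell probability scores.

#' Hedges' g effect size
#'
#' Difference of means divided by the pooled standard deviation, with the
#' pooled sd weighted by sample size:
#' \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}. No
#' small-sample correction factor is applied (the quantity then coincides
#' with Cohen's d).
#'
#' @param a,b numeric samples with at least two values each.
#' @return the effect size (mean(a) - mean(b)) / s_p.
#' @export
hedgesG <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  if (sp == 0)
    stop("pooled standard deviation is zero; effect size undefined",
         call. = FALSE)
  (mean(a) - mean(b)) / sp
}

#' Per-siRNA statistics panel over probability scores
#'
#' Computes, for one siRNA's per-cell scores against the control
#' population's scores: mean, sd, sem, interquartile range, 95% Student-t
#' confidence interval for the mean, the two-sided Kolmogorov-Smirnov
#' goodness-of-fit test of the standardized scores against the standard
#' normal (H = 1 when rejected at alpha = 0.05), the two-sided
#' Mann-Whitney U test versus control, Hedges' g versus control, and the
#' AUC separating the siRNA's scores from control's.
#'
#' Scores live on [0, 1], so the normality check is applied to
#' standardized scores ((s - mean)/sd); with zero score variance the KS
#' test is undefined and flagged NA with a warning.
#'
#' @param scoresSirna per-cell scores of the siRNA population (n >= 2).
#' @param scoresControl per-cell scores of the control population.
#' @param conf confidence level for the t-interval (default 0.95).
#' @return one-row data.frame: n, mean, sd, sem, iqr, ci_lower, ci_upper,
#'   ks_H, ks_p, mwu_p, hedges_g, auc.
#' @export
populationStats <- function(scoresSirna, scoresControl, conf = 0.95) {
  n <- length(scoresSirna)
  stopifnot(n >= 2, length(scoresControl) >= 2)
  m <- mean(scoresSirna)
  s <- stats::sd(scoresSirna)
  sem <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  if (s > 0) {
    ks <- suppressWarnings(
      stats::ks.test((scoresSirna - m) / s, "pnorm"))
    ksH <- as.integer(ks$p.value < 0.05)
    ksP <- ks$p.value
  } else {
    warning("zero score variance; KS normality test undefined")
    ksH <- NA_integer_; ksP <- NA_real_
  }
  mwu <- suppressWarnings(
    stats::wilcox.test(scoresSirna, scoresControl,
                       alternative = "two.sided"))
  data.frame(
    n = n, mean = m, sd = s, sem = sem,
    iqr = stats::IQR(scoresSirna),
    ci_lower = m - tq * sem, ci_upper = m + tq * sem,
    ks_H = ksH, ks_p = ksP,
    mwu_p = mwu$p.value,
    hedges_g = hedgesG(scoresSirna, scoresControl),
    auc = rocAUC(c(scoresSirna, scoresControl),
                 c(rep(1, n), rep(0, length(scoresControl)))))
}

#' Per-siRNA population score report from cross-validated scores
#'
#' Aggregates held-out per-cell scores to one population probability
#' score per siRNA (the mean of per-cell scores) and attaches the full
#' statistics panel versus the control population's held-out scores.
#' P-values are reported raw, as screens conventionally tabulate them,
#' with an additional Bonferroni-adjusted Mann-Whitney column for
#' convenience.
#'
#' @param scored data.frame from \code{\link{crossvalidate}} (or any table
#'   with sirna_id, target and score columns).
#' @param controlLabel control \code{sirna_id}.
#' @return data.frame, one row per non-control siRNA, with target,
#'   sirna_id and the \code{\link{populationStats}} panel plus
#'   \code{mwu_p_bonferroni}.
#' @export
populationReport <- function(scored, controlLabel) {
  stopifnot(all(c("sirna_id", "target", "score") %in% names(scored)))
  ctl <- scored$score[scored$sirna_id == controlLabel]
  if (length(ctl) < 2)
    stop("need control scores to build the report", call. = FALSE)
  sirnas <- setdiff(sort(unique(scored$sirna_id)), controlLabel)
  rows <- lapply(sirnas, function(s) {
    sel <- scored$sirna_id == s
    cbind(data.frame(target = scored$target[sel][1], sirna_id = s,
                     stringsAsFactors = FALSE),
          populationStats(scored$score[sel], ctl))
  })
  out <- do.call(rbind, rows)
  out$mwu_p_bonferroni <- pmin(out$mwu_p * length(sirnas), 1)
  rownames(out) <- NULL
  out
}

#' Normalized proliferation index
#'
#' Ratio of the mean cells-per-well of an siRNA condition over control;
#' values below 1 indicate an anti-proliferative phenotype.
#'
#' @param cellCountsSirna,cellCountsControl per-well cell counts.
#' @return the ratio of means.
#' @export
proliferationIndex <- function(cellCountsSirna, cellCountsControl) {
  stopifnot(length(cellCountsSirna) >= 1, length(cellCountsControl) >= 1)
  mc <- mean(cellCountsControl)
  if (mc <= 0)
    stop("control cell count must be positive", call. = FALSE)
  mean(cellCountsSirna) / mc
}
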