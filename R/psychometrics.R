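# ---------------------------------------------------------------------------
# Validation statistics battery: internal consistency (KR-20 / Cronbach
# alpha on dichotomous items), test-retest stability, known-groups pooled
# t-test, ROC analysis with Youden-J optimal threshold, and comparison of
# dependent / independent correlations.
# ---------------------------------------------------------------------------

#' Cronbach's alpha (KR-20 for dichotomous items)
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of total score).
#' For 0/1 items this is Kuder-Richardson formula 20 up to the use of the
#' unbiased (n-1) variance, which cancels in the ratio.
#'
#' @param responses numeric matrix or data frame, subjects in rows, items in
#'   columns; at least 2 items and 2 subjects.
#' @return Alpha; `NaN` (with a warning) when the total score has zero
#'   variance, in which case alpha is undefined.
#' @export
cronbach_alpha <- function(responses) {
  x <- as.matrix(responses)
  if (ncol(x) < 2L || nrow(x) < 2L) {
    stop_input("need at least 2 items and 2 subjects")
  }
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    warning("total score has zero variance; alpha undefined")
    return(NaN)
  }
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / total_var)
}

#' Average inter-item correlation
#'
#' Mean of all pairwise product-moment correlations between item columns.
#' Constant columns carry no correlation and are excluded with a warning.
#'
#' @inheritParams cronbach_alpha
#' @return Mean pairwise correlation.
#' @export
average_interitem_correlation <- function(responses) {
  x <- as.matrix(responses)
  keep <- apply(x, 2L, stats::var) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant item column(s) excluded")
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2L) stop_input("need at least 2 non-constant item columns")
  cm <- stats::cor(x)
  mean(cm[lower.tri(cm)])
}

#' Test-retest correlation
#'
#' Product-moment correlation between paired total scores at two
#' administrations.
#'
#' @param scores_t1,scores_t2 paired numeric vectors, length >= 3.
#' @return Correlation; `NaN` (with a warning) if either vector has zero
#'   variance.
#' @export
test_retest <- function(scores_t1, scores_t2) {
  if (length(scores_t1) != length(scores_t2)) {
    stop_input("score vectors must be paired (equal length)")
  }
  if (length(scores_t1) < 3L) stop_input("need at least 3 pairs")
  if (stats::var(scores_t1) == 0 || stats::var(scores_t2) == 0) {
    warning("zero variance; correlation undefined")
    return(NaN)
  }
  stats::cor(scores_t1, scores_t2)
}

#' Known-groups pooled-variance t-test
#'
#' Two-sample t-test with pooled variance and df = n1 + n2 - 2, comparing
#' clinical against non-clinical total scores.  The difference is taken as
#' (non-clinical minus clinical), so a clinically elevated scale yields a
#' negative t.
#'
#' @param clinical_scores,nonclinical_scores numeric vectors, each of
#'   length >= 2.
#' @return List with components `t`, `df` and `p` (two-sided).
#' @export
known_groups_ttest <- function(clinical_scores, nonclinical_scores) {
  if (length(clinical_scores) < 2L || length(nonclinical_scores) < 2L) {
    stop_input("each group needs at least 2 observations")
  }
  if (stats::var(clinical_scores) == 0 && stats::var(nonclinical_scores) == 0) {
    stop_input("degenerate (zero) variance in both groups")
  }
  ht <- stats::t.test(nonclinical_scores, clinical_scores, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' ROC analysis of a screening score
#'
#' Positivity rule: a subject is predicted clinical when score >= threshold.
#' Sensitivity is the fraction of clinical subjects at or above the
#' threshold; specificity the fraction of non-clinical subjects below it.
#' The AUC is the pair-counting (rank / Mann-Whitney) statistic with ties
#' counted 1/2.  The optimal threshold maximizes Youden's J = sensitivity +
#' specificity - 1; ties go to the smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels per-subject labels; `"clinical"` (or `TRUE`/1) marks the
#'   positive class, anything else the negative class.
#' @return An object of class `roc_result` with components `points` (data
#'   frame of threshold, sensitivity, specificity), `auc`,
#'   `optimal_threshold` and `youden_j`.
#' @export
roc_analysis <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_input("scores and labels must have equal length")
  }
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels == 1
         else labels == "clinical"
  if (!any(pos) || all(pos)) stop_input("both classes must be present")
  sp <- scores[pos]; sn <- scores[!pos]
  # Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(c(sp, sn))
  auc <- (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
  thresholds <- sort(unique(c(scores, max(scores) + 1)))
  sens <- vapply(thresholds, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(sn < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]  # thresholds ascending: first = smallest
  out <- structure(
    list(points = data.frame(threshold = thresholds, sensitivity = sens,
                             specificity = spec),
         auc = auc, optimal_threshold = thresholds[best],
         youden_j = j[best]),
    class = "roc_result"
  )
  attr(out, "scores") <- list(positive = sp, negative = sn)
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC analysis: AUC =", formatC(x$auc, digits = 3, format = "f"),
      "| optimal threshold", x$optimal_threshold,
      "(Youden J =", paste0(formatC(x$youden_j, digits = 3, format = "f"), ")"), "\n")
  invisible(x)
}

#' Sensitivity/specificity at a fixed threshold
#'
#' Evaluated directly from the underlying scores, so any threshold may be
#' queried, not only those realized in the sample.
#'
#' @param roc a `roc_result`.
#' @param threshold a score threshold (score >= threshold counts positive).
#' @return Named numeric vector with `sensitivity` and `specificity`.
#' @export
roc_at <- function(roc, threshold) {
  sc <- attr(roc, "scores")
  c(sensitivity = mean(sc$positive >= threshold),
    specificity = mean(sc$negative < threshold))
}

#' Compare two dependent correlations sharing one variable
#'
#' Tests r12 = r13 when both correlations are computed on the same sample
#' and share variable 1 (e.g. the same questionnaire correlated with two
#' criterion scales).  Uses the Fisher-transformed difference scaled by the
#' Meng-Rosenthal-Rubin covariance term for dependent correlations.
#'
#' @param r12,r13 the two correlations being compared.
#' @param r23 the correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return List with components `z` and `p` (two-sided).
#' @export
compare_dependent_correlations <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop_input("correlations must lie strictly inside (-1, 1)")
  }
  if (n <= 3) stop_input("n must exceed 3")
  rbar2 <- (r12^2 + r13^2) / 2
  f <- min((1 - r23) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 * (1 - r23) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two correlations from independent samples
#'
#' Fisher z-test: the difference of the atanh-transformed correlations is
#' scaled by sqrt(1/(n1-3) + 1/(n2-3)).
#'
#' @param r1,r2 the two correlations.
#' @param n1,n2 the two sample sizes (> 3).
#' @return List with components `z` and `p` (two-sided).
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop_input("correlations must lie strictly inside (-1, 1)")
  }
  if (n1 <= 3 || n2 <= 3) stop_input("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Batch validation report
#'
#' Runs the reliability and known-groups battery on a response table:
#' Cronbach's alpha and average inter-item correlation for the full scale
#' and per factor, the pooled known-groups t-test, the ROC analysis of the
#' total score, and (when retest responses are supplied) the test-retest
#' correlation.
#'
#' @param responses subjects x items 0/1 matrix (columns in context item
#'   order).
#' @param groups per-subject labels, `"clinical"` / `"nonclinical"`.
#' @param factors named list of item-id vectors partitioning the items.
#' @param retest optional matrix of the same shape as `responses` holding a
#'   second administration for (a subset of) the same subjects, matched by
#'   row name.
#' @param ctx the clinical context.
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(responses, groups, factors = queds_factors(),
                              retest = NULL, ctx = queds_context()) {
  x <- as.matrix(responses)
  if (ncol(x) != nrow(ctx$items)) {
    stop_input("responses must have one column per context item")
  }
  scores <- rowSums(x)
  col_of <- function(ids) match(ids, ctx$items$id)
  alpha <- list(total = cronbach_alpha(x))
  aic <- list()
  for (f in names(factors)) {
    xf <- x[, col_of(factors[[f]]), drop = FALSE]
    alpha[[f]] <- cronbach_alpha(xf)
    aic[[f]] <- average_interitem_correlation(xf)
  }
  clin <- groups == "clinical"
  out <- list(
    n = nrow(x),
    alpha = alpha,
    average_interitem_correlation = aic,
    known_groups = if (any(clin) && any(!clin))
      known_groups_ttest(scores[clin], scores[!clin]) else NULL,
    roc = if (any(clin) && any(!clin))
      roc_analysis(scores, ifelse(clin, "clinical", "nonclinical")) else NULL,
    group_means = list(
      clinical = if (any(clin)) mean(scores[clin]) else NA_real_,
      nonclinical = if (any(!clin)) mean(scores[!clin]) else NA_real_)
  )
  if (!is.null(retest)) {
    common <- intersect(rownames(x), rownames(retest))
    out$test_retest <- test_retest(rowSums(x[common, , drop = FALSE]),
                                   rowSums(retest[common, , drop = FALSE]))
    out$n_retest <- length(common)
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("QuEDS validation report (n =", x$n, ")\n")
  cat("  alpha: total", formatC(x$alpha$total, digits = 3, format = "f"))
  for (f in setdiff(names(x$alpha), "total")) {
    cat(" |", f, formatC(x$alpha[[f]], digits = 3, format = "f"))
  }
  cat("\n")
  if (!is.null(x$known_groups)) {
    cat("  known groups: t(", x$known_groups$df, ") = ",
        formatC(x$known_groups$t, digits = 2, format = "f"),
        ", p = ", format.pval(x$known_groups$p), "\n", sep = "")
  }
  if (!is.null(x$roc)) {
    cat("  ROC: AUC =", formatC(x$roc$auc, digits = 3, format = "f"),
        "| optimal threshold", x$roc$optimal_threshold, "\n")
  }
  if (!is.null(x$test_retest)) {
    cat("  test-retest r =", formatC(x$test_retest, digits = 3, format = "f"),
        "(n =", x$n_retest, ")\n")
  }
  invisible(x)
}
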