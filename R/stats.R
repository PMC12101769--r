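#' Welch's two-sample t-test with group summaries
#'
#' Unequal-variance t-test (Satterthwaite degrees of freedom) with per-group
#' means and 95% t-based confidence intervals, matching how between-group
#' pupil parameters are compared.
#'
#' @param a,b Numeric vectors (two independent groups).
#' @param conf_level Confidence level for the per-group CIs (default 0.95).
#' @return List of class `group_stats`: per-group `mean`, `ci` (matrix),
#'   `n`, plus `statistic`, `df`, `p`.
#' @export
welch_t <- function(a, b, conf_level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 finite values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no variance anywhere; equal means are indistinguishable
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (eq) 0 else Inf,
               parameter = length(a) + length(b) - 2,
               p.value = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  structure(list(mean = c(a = mean(a), b = mean(b)),
                 ci = rbind(a = group_ci(a, conf_level),
                            b = group_ci(b, conf_level)),
                 n = c(a = length(a), b = length(b)),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = unname(tt$p.value)),
            class = "group_stats")
}

group_ci <- function(x, conf_level = 0.95) {
  n <- length(x)
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(lower = mean(x) - half, upper = mean(x) + half)
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats: t = %.3f, df = %.2f, p = %.4g>\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Paired t-test between two within-participant conditions
#'
#' One-sample t-test on the per-participant differences `a - b`; reports the
#' mean paired difference and its CI.
#'
#' @param a,b Numeric vectors paired by participant (equal length; pairs
#'   with a missing value in either condition are dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `paired_stats`: `mean_difference`, `ci`, `n`,
#'   `statistic`, `df`, `p`.
#' @export
paired_t <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- (a - b)[keep]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
               parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(d, conf.level = conf_level)
  }
  structure(list(mean_difference = mean(d),
                 ci = group_ci(d, conf_level), n = length(d),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = unname(tt$p.value)),
            class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  cat(sprintf("<paired_stats: mean diff = %.3f, t = %.3f, p = %.4g>\n",
              x$mean_difference, x$statistic, x$p))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; two-sided p-value by the
#' t-approximation for n >= 10 and by exact permutation below (no ties) or
#' the t-approximation (ties), following `cor.test`.
#'
#' @param x,y Paired numeric vectors.
#' @return List of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) < 10 && !anyDuplicated(x) &&
                            !anyDuplicated(y)))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result: rho = %.3f, p = %.4g, n = %d>\n",
              x$rho, x$p, x$n))
  invisible(x)
}

#' ROC analysis for a diagnostic score
#'
#' AUC by the Mann-Whitney construction (ties count one half) with the
#' asymptotic DeLong 95% confidence interval, computed through pROC -- the
#' standard ROC package for this kind of analysis. The positive (case)
#' class is taken to be `labels == 1`; direction is auto-detected so the
#' reported `auc` reflects the observed direction of effect, while
#' `auc_raw` fixes the orientation "higher score = more likely a case" and
#' may fall below 0.5.
#'
#' @param scores Numeric diagnostic scores.
#' @param labels Binary labels (0 = control, 1 = case), or a factor/logical
#'   coercible to that.
#' @param specificity If not NULL, also report sensitivity at this
#'   specificity from the empirical ROC curve.
#' @return List of class `roc_result`: `auc`, `ci` (lower/upper),
#'   `direction`, `auc_raw`, optionally `sensitivity_at_specificity`.
#' @export
roc_auc <- function(scores, labels, specificity = NULL) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 levels = c(0, 1), direction = "auto")
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  raw <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   levels = c(0, 1), direction = "<")
  out <- list(auc = as.numeric(pROC::auc(r)),
              ci = c(lower = ci[1], upper = ci[3]),
              direction = r$direction,
              auc_raw = as.numeric(pROC::auc(raw)))
  if (!is.null(specificity)) {
    co <- pROC::coords(r, x = specificity, input = "specificity",
                       ret = "sensitivity", transpose = FALSE)
    out$sensitivity_at_specificity <- as.numeric(co[[1]])
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.3f (95%% CI %.3f-%.3f)>\n",
              x$auc, x$ci["lower"], x$ci["upper"]))
  invisible(x)
}

#' Bonferroni family-wise significance decisions
#'
#' A p-value is declared significant iff strictly below `alpha /
#' family_size` (so p exactly at the corrected threshold is not
#' significant).
#'
#' @param p Numeric vector of p-values.
#' @param family_size Number of comparisons in the family (default 4).
#' @param alpha Family-wise alpha (default 0.05).
#' @return List: `threshold`, logical `significant`.
#' @export
bonferroni <- function(p, family_size = 4, alpha = 0.05) {
  if (family_size < 1) stop("family_size must be >= 1")
  thr <- alpha / family_size
  list(threshold = thr, significant = p < thr)
}

#' Binormal effect size for a sensitivity/specificity pair
#'
#' For two equal-variance normal score distributions separated by Cohen's d,
#' a single decision threshold attains sensitivity `sens` and specificity
#' `spec` exactly when `d = qnorm(sens) + qnorm(spec)`. Used to translate a
#' clinically useful operating point into the group separation it demands.
#'
#' @param sens,spec Sensitivity and specificity, each in (0, 1).
#' @return Cohen's d (standard deviations).
#' @export
binormal_d_for_sens_spec <- function(sens, spec) {
  if (any(c(sens, spec) <= 0) || any(c(sens, spec) >= 1))
    stop("sensitivity and specificity must lie strictly in (0, 1)")
  stats::qnorm(sens) + stats::qnorm(spec)
}

#' Power of a two-sided two-sample t-test
#'
#' Exact noncentral-t power for detecting a standardized mean difference d
#' between groups of sizes n1 and n2 at two-sided level alpha.
#'
#' @param d Cohen's d (>= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05) {
  if (d < 0) stop("d must be non-negative")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp = ncp) + 1 - stats::pt(tc, df, ncp = ncp)
}

#' Expected AUC of a binormal score at separation d
#'
#' For two equal-variance normals separated by d, AUC = Phi(d / sqrt(2)).
#'
#' @param d Cohen's d.
#' @return AUC.
#' @export
binormal_auc <- function(d) stats::pnorm(d / sqrt(2))
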