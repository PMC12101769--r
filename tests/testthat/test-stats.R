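# Group comparisons, correlation, ROC, binormal analytics.

test_that("Welch test matches the hand-computed formula", {
  gs <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # hand computation: means 2 and 5, s^2 = 1 each, se = sqrt(2/3),
  # t = -3/sqrt(2/3) = -3.674, df = (2/3)^2 / (2 * (1/9) / 2) = 4
  expect_equal(gs$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(gs$df, 4, tolerance = 1e-9)
  expect_equal(gs$p, 2 * pt(-abs(gs$statistic), 4), tolerance = 1e-9)
  expect_true(gs$ci["a", "lower"] < gs$mean["a"] &
                gs$mean["a"] < gs$ci["a", "upper"])

  same <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("Welch reduces to the classical t for equal sizes and variances", {
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12) + 0.5
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)   # force equal variance
  gs <- welch_t(a, b)
  classic <- t.test(a, b, var.equal = TRUE)
  expect_equal(gs$statistic, unname(classic$statistic), tolerance = 1e-9)
  expect_equal(gs$df, unname(classic$parameter), tolerance = 1e-9)
})

test_that("paired test reports the mean within-participant difference", {
  ps <- paired_t(c(5, 6, 7, 8), c(3, 4, 5, 6))
  expect_equal(ps$mean_difference, 2)
  expect_equal(ps$p, 0)   # zero-variance difference, degenerate
  same <- paired_t(1:5, 1:5)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p, 1)
  real <- paired_t(c(1, 3, 2, 5), c(0, 1, 2, 2))
  oracle <- t.test(c(1, 3, 2, 5) - c(0, 1, 2, 2))
  expect_equal(real$p, oracle$p.value, tolerance = 1e-9)
})

test_that("Spearman correlation matches a brute-force rank computation", {
  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, -(1:8)^3)$rho, -1)

  x <- c(1, 2, 2, 4, 5, 6)      # one tie -> midranks
  y <- c(3, 1, 4, 4, 6, 5)
  got <- spearman(x, y)
  oracle <- cor(rank(x), rank(y))
  expect_equal(got$rho, oracle, tolerance = 1e-9)
  expect_error(spearman(rep(1, 6), 1:6), "constant")
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(17)
  x <- rnorm(20); y <- x + rnorm(20)
  r0 <- spearman(x, y)$rho
  expect_equal(spearman(exp(x), y)$rho, r0, tolerance = 1e-12)
  expect_equal(spearman(x, y^3)$rho, r0, tolerance = 1e-12)
})

test_that("AUC follows the Mann-Whitney construction with DeLong CI", {
  # perfect separation
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  # symmetric nesting -> chance performance (cases at ranks 2 and 3)
  r2 <- roc_auc(c(1, 2, 3, 4), c(0, 1, 1, 0))
  expect_equal(r2$auc_raw, 0.5, tolerance = 1e-9)
  # cross-check against a hand-rolled Mann-Whitney AUC with tie halving
  set.seed(23)
  scores <- round(rnorm(40), 1)
  labels <- rbinom(40, 1, 0.4)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  mw_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    cmp <- outer(pos, neg, function(p, n)
      (p > n) + 0.5 * (p == n))
    mean(cmp)
  }
  r3 <- roc_auc(scores, labels)
  expect_equal(r3$auc_raw, mw_auc(scores, labels), tolerance = 1e-9)
  expect_true(r3$ci["lower"] <= r3$auc & r3$auc <= r3$ci["upper"])
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(29)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  a0 <- roc_auc(s, l)$auc_raw
  expect_equal(roc_auc(exp(s), l)$auc_raw, a0, tolerance = 1e-12)
  expect_equal(roc_auc(-s, l)$auc_raw, 1 - a0, tolerance = 1e-12)
})

test_that("Bonferroni uses a strict inequality at alpha / family", {
  b <- bonferroni(c(0.0125, 0.01, 0.0124999, 0.05), family_size = 4)
  expect_equal(b$threshold, 0.0125)
  expect_identical(unname(b$significant), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(bonferroni(0.04, family_size = 1)$threshold, 0.05)
  # decisions are monotone in p
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p)$significant) <= 0))
})

test_that("binormal separation for a sensitivity/specificity pair", {
  expect_equal(binormal_d_for_sens_spec(0.5, 0.5), 0)
  d <- binormal_d_for_sens_spec(0.70, 0.90)
  expect_equal(d, qnorm(0.7) + qnorm(0.9), tolerance = 1e-12)
  expect_equal(d, 1.8, tolerance = 0.01)
  expect_error(binormal_d_for_sens_spec(1, 0.9), "strictly")

  # Monte-Carlo: threshold at qnorm(spec) above the control mean attains
  # the nominal sensitivity when the groups are d apart
  set.seed(1)
  n <- 2e5
  cases <- rnorm(n, mean = d, sd = 1)
  thr <- qnorm(0.90)
  expect_equal(mean(cases > thr), 0.70, tolerance = 0.01)
})

test_that("noncentral-t power matches simulation and boundary cases", {
  expect_equal(power_two_sample(0, 15, 15), 0.05, tolerance = 1e-6)
  expect_gt(power_two_sample(1.8, 20, 15), 0.99)

  # Monte-Carlo oracle: simulate the pooled two-sample t-test directly
  set.seed(2)
  d <- 1.0; n <- 15; reps <- 1e5
  x <- matrix(rnorm(reps * n), reps); y <- matrix(rnorm(reps * n, d), reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1); vy <- rowSums((y - my)^2) / (n - 1)
  sp <- sqrt((vx + vy) / 2)
  tstat <- (my - mx) / (sp * sqrt(2 / n))
  emp <- mean(2 * pt(-abs(tstat), 2 * n - 2) < 0.05)
  expect_equal(emp, power_two_sample(d, n, n), tolerance = 0.005)
})

test_that("binormal AUC identity holds in simulation", {
  set.seed(4)
  d <- 1.2; n <- 4e4
  scores <- c(rnorm(n), rnorm(n, d))
  labels <- rep(c(0, 1), each = n)
  pos <- scores[labels == 1]
  # large-sample Mann-Whitney estimate via ranks (memory-light)
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n * (n + 1) / 2) / (n * n)
  expect_equal(auc, binormal_auc(d), tolerance = 0.01)
})

test_that("full analysis bundle assembles tests, PIPR, ROC and correlations", {
  coh <- simulate_cohort(small_cohort_spec(seed = 42))
  traces <- preprocess_cohort(coh)
  tabs <- tables_from_traces(traces, coh$participants)
  b <- run_full_analysis(tabs, clinical = coh$clinical)
  expect_s3_class(b, "analysis_bundle")
  expect_setequal(unique(b$metrics$stimulus), c("melanopsin", "lms"))
  expect_length(b$group_tests, 8)
  expect_named(b$paired_tests, c("a", "b", "c", "d"))
  expect_true(all(c("pipr_6s", "pipr_maxdiff", "melanopsin_a", "lms_d")
                  %in% names(b$roc)))
  expect_true(all(vapply(b$roc, function(r)
    r$ci["lower"] <= r$auc && r$auc <= r$ci["upper"], logical(1))))
  expect_gt(length(b$correlations), 0)
  expect_true(all(vapply(b$correlations, function(cr)
    abs(cr$rho) <= 1, logical(1))))
  # missing stimulus tables -> partial bundle with a warning
  expect_warning(run_full_analysis(tabs[c("glaucoma_melanopsin",
                                          "control_melanopsin")]),
                 "missing")
})
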