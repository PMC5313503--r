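test_that("Cronbach's alpha matches direct formula evaluation", {
  # worked 4 subjects x 3 items: item variances 1/3 each (sum 1); totals
  # 3,2,1,0 with variance 5/3; alpha = 3/2 * (1 - 1/(5/3)) = 3/5
  x <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cronbach_alpha(x), 3 / 5)
  # duplicated pair of columns with variance -> 1
  expect_equal(cronbach_alpha(cbind(c(1, 0, 1), c(1, 0, 1))), 1.0)
  # zero pairwise covariance -> 0
  y <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cronbach_alpha(y), 0.0)
  expect_warning(a <- cronbach_alpha(cbind(c(1, 0), c(0, 1))))
  expect_true(is.nan(a))
  expect_error(cronbach_alpha(matrix(1, 3, 1)), class = "queds_input_error")
})

test_that("alpha is invariant under item reordering and grows with duplication", {
  set.seed(3)
  base <- matrix(rbinom(200, 1, 0.4), 20)
  x <- base + 0
  x[, 2] <- x[, 1]  # induce positive covariance
  expect_equal(cronbach_alpha(x), cronbach_alpha(x[, sample(ncol(x))]))
  expect_gte(cronbach_alpha(cbind(x, x[, 1])), cronbach_alpha(x))
})

test_that("average inter-item correlation matches hand computation", {
  x <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0))
  # pairwise correlations 1, 0, 0
  expect_equal(average_interitem_correlation(x), 1 / 3)
  expect_equal(average_interitem_correlation(cbind(c(1, 0, 1), c(1, 0, 1))), 1.0)
  expect_warning(r <- average_interitem_correlation(
    cbind(c(1, 1, 1), c(1, 0, 1), c(0, 1, 0))))
  expect_equal(r, -1.0)  # constant column dropped, remaining pair anti-correlated
  expect_error(
    suppressWarnings(average_interitem_correlation(cbind(c(1, 1), c(1, 0)))),
    class = "queds_input_error")
  # two long independent columns correlate near zero
  set.seed(9)
  big <- cbind(rbinom(4000, 1, 0.5), rbinom(4000, 1, 0.5))
  expect_lt(abs(average_interitem_correlation(big)), 0.05)
})

test_that("test-retest correlation behaves as a product-moment correlation", {
  expect_equal(test_retest(1:5, 1:5), 1.0)
  expect_equal(test_retest(1:5, -(1:5)), -1.0)
  t1 <- c(10, 12, 8, 15, 11); t2 <- c(11, 14, 7, 13, 12)
  # direct formula evaluation
  num <- sum((t1 - mean(t1)) * (t2 - mean(t2)))
  den <- sqrt(sum((t1 - mean(t1))^2) * sum((t2 - mean(t2))^2))
  expect_equal(test_retest(t1, t2), num / den)
  expect_warning(r <- test_retest(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.nan(r))
  expect_error(test_retest(1:4, 1:5), class = "queds_input_error")
})

test_that("known-groups t is the pooled-variance statistic with df n1+n2-2", {
  # toy groups: means 6 and 2, pooled variance 1 -> t = -4 / sqrt(2/3)
  out <- known_groups_ttest(c(5, 6, 7), c(1, 2, 3))
  expect_equal(out$t, -4 / sqrt(2 / 3))
  expect_equal(out$df, 4)
  expect_equal(known_groups_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # swapping groups flips the sign
  expect_equal(known_groups_ttest(c(1, 2, 3), c(5, 6, 7))$t,
               -known_groups_ttest(c(5, 6, 7), c(1, 2, 3))$t)
  expect_error(known_groups_ttest(3, c(1, 2)), class = "queds_input_error")
  expect_error(known_groups_ttest(c(2, 2), c(3, 3)), class = "queds_input_error")
})

test_that("ROC analysis matches pair counting and the Youden rule", {
  lab6 <- rep(c("clinical", "nonclinical"), each = 3)
  sc6 <- c(5, 3, 4, 1, 2, 3)
  roc <- roc_analysis(sc6, lab6)
  expect_equal(roc$auc, 8.5 / 9)  # 8 wins + 1 tie out of 9 pairs
  expect_equal(roc$auc, brute_auc(sc6, lab6))
  # perfectly separated
  expect_equal(roc_analysis(c(10, 9, 1, 2), c("clinical", "clinical",
                                              "nonclinical", "nonclinical"))$auc, 1.0)
  # label-permuted duplicates
  expect_equal(roc_analysis(c(1, 2, 3, 1, 2, 3), lab6)$auc, 0.5)
  expect_error(roc_analysis(1:3, rep("clinical", 3)), class = "queds_input_error")
  # threshold semantics: score >= t is positive
  expect_equal(unname(roc_at(roc, 4)), c(2 / 3, 1))
  expect_equal(unname(roc_at(roc, 3)[1]), 1)
})

test_that("AUC equals the exhaustive pair-counting oracle on random inputs", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    labels <- c("clinical", "nonclinical",
                sample(c("clinical", "nonclinical"), n - 2, replace = TRUE))
    scores <- sample(0:41, n, replace = TRUE)
    expect_equal(roc_analysis(scores, labels)$auc, brute_auc(scores, labels))
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- c(rnorm(30, 2), rnorm(40, 0))
  labels <- rep(c("clinical", "nonclinical"), c(30, 40))
  got <- roc_analysis(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("nonclinical", "clinical"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, want)
})

test_that("dependent-correlation z is zero at equality and matches the formula", {
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 100)$z, 0)
  # direct evaluation of the Fisher/covariance formula for the published
  # questionnaire-vs-criterion comparison (0.72 vs 0.39 sharing the total
  # score, r23 = 0.37, n = 113)
  r12 <- 0.72; r13 <- 0.39; r23 <- 0.37; n <- 113
  rbar2 <- (r12^2 + r13^2) / 2
  f <- (1 - r23) / (2 * (1 - rbar2))
  h <- (1 - f * rbar2) / (1 - rbar2)
  want <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 * (1 - r23) * h))
  out <- compare_dependent_correlations(r12, r13, r23, n)
  expect_equal(out$z, want)
  expect_gt(out$z, 0)
  expect_lt(out$p, 0.001)
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 50),
               class = "queds_input_error")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3),
               class = "queds_input_error")
})

test_that("independent-sample z is zero at equality and antisymmetric", {
  expect_equal(compare_independent_correlations(0.4, 50, 0.4, 80)$z, 0)
  a <- compare_independent_correlations(0.6, 60, 0.3, 90)
  b <- compare_independent_correlations(0.3, 90, 0.6, 60)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_independent_correlations(0.9, 50, -1, 50),
               class = "queds_input_error")
})

test_that("the batch validation report assembles the whole battery", {
  cfg <- calibrate(default_config())
  nc <- generate(cfg, 150, "nonclinical", seed = 21)
  cl <- generate(cfg, 40, "clinical", seed = 22)
  x <- rbind(nc$responses, cl$responses)
  groups <- c(nc$groups, cl$groups)
  cfg$rho <- 0.8
  rt <- generate_retest(nc, cfg, seed = 23)
  rep <- validation_report(x, groups, retest = rt$responses)
  expect_s3_class(rep, "validation_report")
  expect_named(rep$alpha, c("total", "cognitive", "somatic", "affective"))
  expect_lt(rep$known_groups$t, 0)
  expect_equal(rep$known_groups$df, 188)
  expect_gt(rep$roc$auc, 0.9)
  expect_equal(rep$n_retest, 150)
  expect_gt(rep$test_retest, 0.3)
})
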