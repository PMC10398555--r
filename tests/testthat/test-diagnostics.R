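test_that("confusion matrices tally predictions against reference labels", {
  cm <- confusion_from_labels(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_identical(c(cm$fp, cm$fn), c(0L, 0L))
  cm2 <- confusion_from_labels(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unlist(cm2[c("tp", "fp", "fn", "tn")]),
                   c(tp = 2L, fp = 2L, fn = 0L, tn = 0L))
  expect_error(confusion_from_labels(TRUE, c(TRUE, FALSE)), "length")
  expect_error(confusion_from_labels(logical(0), logical(0)), "empty")
})

test_that("confusion matrices reconstruct from published summary metrics", {
  cm2 <- reconstruct_confusion(195, 148, 0.811, 0.915)
  expect_identical(unlist(cm2[c("tp", "fp", "fn", "tn")]),
                   c(tp = 120L, fp = 4L, fn = 28L, tn = 43L))
  cm3 <- reconstruct_confusion(195, 148, 0.892, 0.915)
  expect_identical(unlist(cm3[c("tp", "fp", "fn", "tn")]),
                   c(tp = 132L, fp = 4L, fn = 16L, tn = 43L))
  # the rule-3 refinement removes 12 false negatives, no new false positives
  expect_identical(cm2$fn - cm3$fn, 12L)
  expect_identical(cm3$fp, cm2$fp)
  perfect <- reconstruct_confusion(100, 30, 1, 1)
  expect_identical(unlist(perfect[c("tp", "fp", "fn", "tn")]),
                   c(tp = 30L, fp = 0L, fn = 0L, tn = 70L))
  expect_error(reconstruct_confusion(100, 100, 0.8, 0.8), "n_diseased")
  expect_error(reconstruct_confusion(100, 30, 1.2, 0.8), "\\[0, 1\\]")
})

test_that("diagnostic reports reproduce the published predictive values", {
  rep2 <- diagnostic_report(confusion_matrix(120, 4, 28, 43))
  expect_equal(round(100 * rep2$ppv, 1), 96.8)
  expect_equal(round(100 * rep2$npv, 1), 60.6)
  rep3 <- diagnostic_report(confusion_matrix(132, 4, 16, 43))
  expect_equal(round(rep3$kappa, 2), 0.74)
  expect_equal(rep3$auc, (rep3$sensitivity + rep3$specificity) / 2)
})

test_that("a perfect classifier scores 1 on every metric", {
  r <- diagnostic_report(confusion_matrix(5, 0, 0, 7))
  expect_equal(unlist(r[c("sensitivity", "specificity", "ppv", "npv",
                          "kappa", "auc")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 kappa = 1, auc = 1))
})

test_that("degenerate margins yield explicit NA metrics with a warning", {
  expect_warning(r <- diagnostic_report(confusion_matrix(3, 2, 0, 0)),
                 "NPV undefined")
  expect_true(is.na(r$npv))
  expect_warning(r2 <- diagnostic_report(confusion_matrix(3, 0, 2, 0)),
                 "specificity undefined")
  expect_true(is.na(r2$specificity))
  expect_true(is.na(r2$auc))
})

test_that("reconstruction and reporting round-trip within rounding error", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    d <- sample(seq(10, n - 10), 1)
    se <- runif(1, 0.05, 0.95)
    sp <- runif(1, 0.05, 0.95)
    r <- diagnostic_report(reconstruct_confusion(n, d, se, sp))
    expect_lt(abs(r$sensitivity - se), 0.5 / d + 1e-12)
    expect_lt(abs(r$specificity - sp), 0.5 / (n - d) + 1e-12)
  }
})

test_that("predictive values obey Bayes' rule at the matrix prevalence", {
  set.seed(8)
  for (i in 1:20) {
    cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    r <- diagnostic_report(cm)
    prev <- r$prevalence
    expect_equal(r$ppv, r$sensitivity * prev /
                   (r$sensitivity * prev + (1 - r$specificity) * (1 - prev)))
    expect_equal(r$npv, r$specificity * (1 - prev) /
                   (r$specificity * (1 - prev) + (1 - r$sensitivity) * prev))
  }
})

test_that("Cohen's kappa matches hand values and known cases", {
  expect_equal(cohen_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # nested positives, 136 of 139 shared on n = 195
  a <- rep(c(TRUE, FALSE), c(136, 59))
  b <- rep(c(TRUE, FALSE), c(139, 56))
  expect_equal(round(cohen_kappa(a, b), 3), 0.963)
  # exact chance-level agreement: joint counts equal margin products
  a0 <- rep(c(TRUE, FALSE), c(50, 50))
  b0 <- c(rep(c(TRUE, FALSE), c(20, 30)), rep(c(TRUE, FALSE), c(20, 30)))
  expect_equal(cohen_kappa(a0, b0), 0)
})

test_that("kappa is symmetric and invariant to relabeling", {
  set.seed(9)
  for (i in 1:20) {
    a <- runif(60) < 0.5
    b <- runif(60) < 0.4
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
    expect_equal(cohen_kappa(a, b), cohen_kappa(!a, !b))
  }
})

test_that("kappa agrees with an independent implementation", {
  set.seed(10)
  for (i in 1:10) {
    a <- runif(80) < 0.6
    b <- xor(a, runif(80) < 0.25)
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa)
  }
})

test_that("ROC analysis handles separable and uninformative scores", {
  ref <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  sep <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  r <- roc_cutoff(sep, ref)
  expect_equal(r$auc, 1)
  expect_gt(r$cutoff, 0.3)
  expect_lt(r$cutoff, 0.7)
  flat <- roc_cutoff(rep(0.5, 6), ref)
  expect_equal(flat$auc, 0.5)
  expect_error(roc_cutoff(sep, rep(TRUE, 6)), "both classes")
})

test_that("trapezoid AUC equals the rank-statistic oracle", {
  set.seed(12)
  mw_auc <- function(scores, ref) {
    d <- scores[ref]
    h <- scores[!ref]
    cmp <- outer(d, h, ">") + 0.5 * outer(d, h, "==")
    mean(cmp)
  }
  # published-style toy: one overlapping pair
  toy_s <- c(0.1, 0.2, 0.35, 0.3, 0.6, 0.8)
  toy_r <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  toy <- roc_cutoff(toy_s, toy_r)
  expect_equal(toy$auc, mw_auc(toy_s, toy_r))
  # the reported cutoff attains the maximal Youden index
  expect_equal(toy$roc$youden[toy$roc$cutoff == toy$cutoff],
               max(toy$roc$youden))
  for (i in 1:10) {
    s <- round(runif(40), 2)    # ties likely
    rf <- runif(40) < 0.5
    if (!any(rf) || all(rf)) next
    expect_equal(roc_cutoff(s, rf)$auc, mw_auc(s, rf))
  }
})

test_that("Youden ties break toward the lowest cutoff", {
  # two cutoffs achieve the same Youden index; the lower keeps Se high
  s <- c(1, 2, 3, 4)
  ref <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_cutoff(s, ref)
  best <- r$roc$cutoff[r$roc$youden == max(r$roc$youden)]
  expect_equal(r$cutoff, min(best))
})

test_that("binary-rule AUC from the ROC equals (Se+Sp)/2", {
  set.seed(13)
  pred <- runif(100) < 0.4
  ref <- xor(pred, runif(100) < 0.2)
  rep <- diagnostic_report(confusion_from_labels(pred, ref))
  roc <- roc_cutoff(as.numeric(pred), ref)
  expect_equal(roc$auc, rep$auc)
})

test_that("AUC agrees with pROC on continuous scores", {
  set.seed(14)
  scores <- c(rnorm(40, 1), rnorm(40, 0))
  ref <- rep(c(TRUE, FALSE), each = 40)
  ours <- roc_cutoff(scores, ref)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(ref, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("Wald odds ratios reproduce the published model table", {
  q1 <- wald_or_ci(1.484, 0.61)
  expect_equal(round(q1$or, 2), 4.41)
  expect_equal(round(q1$lower, 2), 1.33)
  expect_lt(abs(q1$upper - 14.60) / 14.60, 0.015)
  q4 <- wald_or_ci(2.749, 0.54)
  expect_equal(round(q4$or, 2), 15.63)
  null <- wald_or_ci(0, 0.3)
  expect_equal(null$or, 1)
  expect_equal(null$lower * null$upper, 1)  # symmetric on the log scale
  expect_error(wald_or_ci(1, 0), "positive")
})
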