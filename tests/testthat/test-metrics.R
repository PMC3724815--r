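test_that("fold-averaged confusion matrices reproduce printed worked examples", {
  # 34-feature model, repeated-CV average
  m <- metrics_from_confusion(confusion_matrix(tp = 425, tn = 293.6,
                                               fp = 48.4, fn = 57))
  expect_equal(truncate_digits(m$acc, 2), 87.20)
  expect_equal(truncate_digits(m$sen, 2), 88.17)
  expect_equal(truncate_digits(m$spe, 2), 85.84)
  expect_equal(truncate_digits(m$mcc, 3), 0.737)
  expect_equal(truncate_digits(m$err_pos, 1), 11.8)
  expect_equal(truncate_digits(m$err_neg, 1), 14.1)
  # top-12-feature model
  m <- metrics_from_confusion(confusion_matrix(tp = 431.2, tn = 306.6,
                                               fp = 35.4, fn = 50.8))
  expect_equal(truncate_digits(m$acc, 2), 89.53)
  expect_equal(truncate_digits(m$sen, 2), 89.46)
  expect_equal(truncate_digits(m$spe, 2), 89.64)
  expect_equal(truncate_digits(m$mcc, 3), 0.786)
  expect_equal(truncate_digits(m$err_pos, 2), 10.53)
  expect_equal(truncate_digits(m$err_neg, 2), 10.35)
})

test_that("degenerate confusion matrices behave", {
  perfect <- metrics_from_confusion(confusion_matrix(50, 50, 0, 0))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$sen, 100)
  expect_equal(perfect$spe, 100)
  expect_equal(perfect$mcc, 1)
  chance <- metrics_from_confusion(confusion_matrix(10, 10, 10, 10))
  expect_equal(chance$mcc, 0)
  expect_equal(chance$acc, 50)
  no_neg <- metrics_from_confusion(confusion_matrix(10, 0, 0, 5))
  expect_true(is.na(no_neg$spe))
  expect_error(confusion_matrix(0, 0, 0, 0), "all-zero")
})

test_that("truncation reports toward zero at the printed precision", {
  expect_equal(truncate_digits(87.2087, 2), 87.20)
  expect_equal(truncate_digits(14.1520, 1), 14.1)
  expect_equal(truncate_digits(0.7379, 3), 0.737)
  expect_equal(truncate_digits(-0.7379, 3), -0.737)
  expect_equal(truncate_digits(87.20, 2), 87.20)
})

test_that("threshold-sweep AUC matches brute-force pairwise ranking", {
  expect_equal(roc_auc(c(0.9, 0.35, 0.4, 0.3),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.0)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force ties
      labels <- stats::runif(n) < 0.5
      if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
      expect_equal(roc_auc(scores, labels)$auc,
                   oracle_pairwise_auc(scores, labels))
    }
  })
})

test_that("ROC curve endpoints and monotonicity", {
  r <- roc_auc(stats::runif(40), rep(c(TRUE, FALSE), 20))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("permutation test: perfect separation is significant, relabeling invariant", {
  scores <- c(seq(0.6, 1, length.out = 20), seq(0, 0.4, length.out = 20))
  labels <- rep(c("TARGET", "NON_TARGET"), each = 20)
  res <- permutation_test_auc(scores, labels, n_perm = 2000, seed = 3)
  expect_equal(res$observed_auc, 1)
  expect_lte(res$p_value, 0.001)
  # invariant to swapping the label names (p computed on the same seed)
  flipped <- ifelse(labels == "TARGET", "NON_TARGET", "TARGET")
  res2 <- permutation_test_auc(1 - scores, flipped, n_perm = 200, seed = 3)
  expect_equal(res2$observed_auc, 1)
  expect_error(permutation_test_auc(scores, labels, n_perm = 0), "at least 1")
  # corrected variant never returns exactly zero
  expect_gt(permutation_test_auc(scores, labels, n_perm = 50, seed = 1,
                                 corrected = TRUE)$p_value, 0)
})

test_that("probability-vector and paired-AUC comparisons", {
  withr::with_seed(8, a <- stats::runif(50))
  same <- compare_probability_vectors(a, a)
  expect_gt(same$p_value, 0.9)
  shifted <- compare_probability_vectors(a, pmin(a + 0.2, 1))
  expect_lt(shifted$p_value, 0.01)
  expect_message(out <- paired_resample_test(rep(0.9, 5), rep(0.9, 5)),
                 "zero variance")
  expect_true(is.na(out$p_value))
  withr::with_seed(9, {
    x <- stats::runif(10, 0.8, 0.9)
    y <- x - stats::runif(10, 0.1, 0.15)
  })
  expect_lt(paired_resample_test(x, y)$p_value, 0.001)
})
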