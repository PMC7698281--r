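# Metric implementations against hand counts, pairwise oracles and pROC.

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_from_pr(0.5, 0.5), 0.5)
  for (x in c(0.1, 0.42, 0.9)) expect_equal(f1_from_pr(x, x), x)
  expect_equal(round(f1_from_pr(0.89, 0.85), 2), 0.87)
  expect_equal(round(f1_from_pr(0.52, 0.50), 2), 0.51)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_equal(f1_from_pr(c(0.89, 0.52), c(0.85, 0.50)),
               c(2 * 0.89 * 0.85 / 1.74, 2 * 0.52 * 0.50 / 1.02))
  expect_error(f1_from_pr(1.2, 0.5), "\\[0, 1\\]")
})

test_that("classification report matches hand counts on a toy case", {
  rep3 <- classification_report(c("normal", "normal", "csa"),
                                c("normal", "csa", "csa"))
  pc <- rep3$per_class
  expect_equal(pc$precision[pc$class == "csa"], 0.5)
  expect_equal(pc$recall[pc$class == "csa"], 1.0)
  expect_equal(pc$support[pc$class == "normal"], 2L)
  expect_equal(sum(pc$support), 3L)
  # perfect predictions: diagonal confusion, all observed-class f1 = 1
  y <- sample(EVENT_CLASSES, 60, TRUE)
  perf <- classification_report(y, y)
  expect_true(all(perf$per_class$f1[perf$per_class$support > 0] == 1))
  expect_equal(sum(perf$confusion) - sum(diag(perf$confusion)), 0L)
  expect_error(classification_report(c("a"), c("normal", "csa")), "lengths differ")
})

test_that("report agrees with the brute-force counting oracle", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    truth <- sample(EVENT_CLASSES, n, TRUE)
    pred <- sample(EVENT_CLASSES, n, TRUE)
    got <- classification_report(truth, pred)$per_class
    want <- oracle_report(truth, pred)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    expect_equal(got$support, want$support)
  }
})

test_that("row-normalized confusion percentages sum to 100", {
  set.seed(11)
  truth <- sample(EVENT_CLASSES, 500, TRUE)
  pred <- sample(EVENT_CLASSES, 500, TRUE)
  rp <- classification_report(truth, pred)
  sums <- rowSums(rp$confusion_pct)
  expect_true(all(abs(sums - 100) < 0.01))
  expect_equal(unname(rowSums(rp$confusion)), rp$per_class$support)
})

test_that("AUC equals the pairwise-comparison probability", {
  expect_equal(roc_curve_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  r <- roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0))
  expect_equal(r$auc, 1 - 0.75)
  set.seed(12)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    scores <- round(runif(n), 2)          # rounding forces ties
    truth <- sample(0:1, n, TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(roc_curve_auc(scores, truth)$auc,
                 oracle_auc_pairwise(scores, truth), tolerance = 1e-9)
  }
})

test_that("ROC curve is monotone and agrees with pROC", {
  set.seed(13)
  scores <- c(rnorm(40, 1), rnorm(40))
  truth <- rep(c(1, 0), each = 40)
  r <- roc_curve_auc(scores, truth)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("onset lag matches worked examples", {
  # predicted onset one second after the true onset
  lag1 <- detection_lag(data.frame(label = "csa", start_s = 4, end_s = 14),
                        data.frame(label = "csa", start_s = 5, end_s = 15))
  expect_equal(lag1$matches$lag, 1)
  # identical spans: zero lag
  expect_equal(detection_lag(data.frame(label = "cough", start_s = 2, end_s = 4),
                             data.frame(label = "cough", start_s = 2, end_s = 4))$matches$lag, 0)
  # early prediction: negative lag
  expect_equal(detection_lag(data.frame(label = "osa", start_s = 4, end_s = 14),
                             data.frame(label = "osa", start_s = 2, end_s = 12))$matches$lag, -2)
})

test_that("lag matching uses largest overlap and reports unmatched events", {
  truth <- data.frame(label = c("csa", "yawn"), start_s = c(4, 20), end_s = c(14, 26))
  pred <- data.frame(label = c("csa", "csa"), start_s = c(3, 12), end_s = c(5, 14))
  lr <- detection_lag(truth, pred)
  # the first prediction overlaps 1 s, the second 2 s: the larger one wins
  expect_equal(lr$matches$pred_start, 12)
  expect_equal(nrow(lr$unmatched), 1L)
  expect_equal(lr$unmatched$label, "yawn")
  # label-sequence interface built on labels_to_spans
  labs_true <- c(rep("normal", 4), rep("csa", 10), rep("normal", 16))
  labs_pred <- c(rep("normal", 5), rep("csa", 10), rep("normal", 15))
  lr2 <- detection_lag(labs_true, labs_pred)
  expect_equal(lr2$matches$lag, 1)
  expect_equal(lr2$mean_lag, 1)
})

test_that("label runs convert to half-open second spans", {
  sp <- labels_to_spans(c("normal", "csa", "csa", "normal", "cough"))
  expect_equal(sp$label, c("csa", "cough"))
  expect_equal(sp$start_s, c(1, 4))
  expect_equal(sp$end_s, c(3, 5))
  all_sp <- labels_to_spans(rep("normal", 5), drop_normal = FALSE)
  expect_equal(nrow(all_sp), 1L)
})
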