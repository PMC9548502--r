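test_that("AUC matches exhaustive pair counting with half-credit ties", {
  lab <- c(rep("benign", 4), rep("malignant", 4))
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6, 7, 8), lab)$auc, 1)
  expect_equal(roc_auc(rep(1, 8), lab)$auc, 0.5)
  # hand set with one tie across classes
  sc <- c(0.1, 0.4, 0.4, 0.7, 0.4, 0.8, 0.9, 0.95)
  expect_equal(roc_auc(sc, lab)$auc, auc_pairs(sc, lab), tolerance = 1e-15)

  expect_error(roc_auc(1:4, rep("benign", 4)), "both classes")
})

test_that("ROC polyline integrates exactly to the rank AUC", {
  for (i in 1:30) {
    set.seed(700 + i)
    n <- sample(4:60, 1)
    lab <- c("benign", "malignant",
             sample(c("benign", "malignant"), n - 2, replace = TRUE))
    sc <- round(rnorm(n), sample(0:2, 1))  # induce ties
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, auc_pairs(sc, lab), tolerance = 1e-12)
    # trapezoidal integral of the polyline
    trap <- sum(diff(r$roc_points$fpr) *
                  (head(r$roc_points$tpr, -1) + tail(r$roc_points$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(tail(r$roc_points$tpr, 1), 1)
    # complementing the scores complements the AUC when ties are absent
    if (!anyDuplicated(sc)) {
      expect_equal(roc_auc(-sc, lab)$auc, 1 - r$auc, tolerance = 1e-12)
    }
  }
})

test_that("Youden cutoff equals the brute-force threshold scan", {
  lab <- c(rep("benign", 5), rep("malignant", 5))
  sc <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) / 10
  y <- youden_cutoff(sc, lab)
  expect_equal(y$J, 1)
  expect_equal(y$cutoff, 0.6)  # lowest cutoff achieving J = 1

  yt <- youden_cutoff(rep(0.3, 10), lab)
  expect_equal(yt$J, 0)

  sc2 <- c(0.2, 0.8, 0.4, 0.3, 0.6, 0.5, 0.9, 0.7, 0.1, 0.65)
  y2 <- youden_cutoff(sc2, lab)
  o2 <- youden_scan(sc2, lab)
  expect_identical(y2$J, o2$J)
  expect_identical(y2$cutoff, o2$cutoff)

  for (i in 1:20) {
    set.seed(800 + i)
    n <- sample(6:40, 1)
    lab_r <- c("benign", "malignant",
               sample(c("benign", "malignant"), n - 2, replace = TRUE))
    sc_r <- round(runif(n), 2)
    got <- youden_cutoff(sc_r, lab_r)
    want <- youden_scan(sc_r, lab_r)
    expect_identical(got$J, want$J)
    expect_identical(got$cutoff, want$cutoff)
  }
})

test_that("confusion metrics derive from the 2x2 table", {
  # TP = 9, FP = 1, TN = 7, FN = 3 at cutoff 0.5
  scores <- c(rep(0.9, 9), rep(0.1, 3),   # malignant: 9 called, 3 missed
              rep(0.8, 1), rep(0.2, 7))   # benign: 1 called, 7 correct
  labels <- c(rep("malignant", 12), rep("benign", 8))
  m <- confusion_metrics(scores, labels, cutoff = 0.5)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 7 / 8)
  expect_equal(m$npv, 0.7)
  expect_equal(m$accuracy, 16 / 20)

  perf <- confusion_metrics(c(0, 0, 1, 1), c("benign", "benign",
                                             "malignant", "malignant"), 0.5)
  expect_true(all(unlist(perf[1:5]) == 1))
  inv <- confusion_metrics(c(1, 1, 0, 0), c("benign", "benign",
                                            "malignant", "malignant"), 0.5)
  expect_equal(inv$sensitivity, 0)
  expect_equal(inv$specificity, 0)
  # nothing called positive: PPV undefined, reported as missing
  none <- confusion_metrics(c(0.1, 0.2, 0.3, 0.4),
                            c("benign", "benign", "malignant", "malignant"),
                            cutoff = 0.9)
  expect_true(is.na(none$ppv))
})

test_that("stratified evaluation reuses the global cutoff per stratum", {
  set.seed(55)
  n <- 60
  md <- data.frame(subject_id = sprintf("S%d", 1:n),
                   label = rep(c("benign", "malignant"), each = n / 2),
                   ggn = rep(c(TRUE, FALSE), n / 2),
                   nodule_size_mm = runif(n, 5, 18),
                   stringsAsFactors = FALSE)
  # effect confined to the non-GGN stratum
  sc <- plogis(rnorm(n) + ifelse(md$label == "malignant" & !md$ggn, 3, 0))
  res <- stratified_evaluation(sc, md$label, md,
                               strata = c("ggn", "size20", "size10"))
  expect_gt(res$strata$non_ggn$auc, res$strata$ggn$auc)
  # all nodules are below 20 mm here, so that stratum equals the overall
  expect_equal(res$strata$size_le_20mm$auc, res$overall$auc)
  expect_identical(res$strata$size_le_20mm$at_cutoff, res$overall$at_cutoff)
  # waterfall is sorted and centered on the cutoff
  expect_true(all(diff(res$waterfall$score_minus_cutoff) >= 0))

  # single-class stratum is flagged insufficient, others still computed
  md2 <- md
  md2$ggn <- md2$label == "benign" & seq_len(n) <= 10
  res2 <- stratified_evaluation(sc, md2$label, md2, strata = "ggn")
  expect_true(isTRUE(res2$strata$ggn$insufficient))
  expect_false(isTRUE(res2$strata$non_ggn$insufficient))

  expect_error(stratified_evaluation(sc, md$label, md, strata = "bogus"),
               "unknown stratum")
})

test_that("expert agreement tables match a manual tally", {
  truth <- c("malignant", "malignant", "benign", "benign", "malignant",
             "benign")
  model <- c("malignant", "benign", "benign", "malignant", "malignant",
             "benign")
  expert <- c("malignant", "malignant", "malignant", "benign", "benign",
              "benign")
  res <- expert_agreement_table(truth, model, data.frame(ct_doc = expert),
                                subject_ids = sprintf("P%d", 1:6))
  expect_equal(unname(res$accuracy["model"]), 4 / 6)
  expect_equal(unname(res$accuracy["ct_doc"]), 4 / 6)
  expect_setequal(res$misclassified$model, c("P2", "P4"))
  expect_setequal(res$misclassified$ct_doc, c("P3", "P5"))
  expect_equal(sum(res$table$n), 6)
  # manual tally of one cell: truth=malignant, expert=malignant,
  # model=malignant occurs exactly once (P1)
  cell <- res$table[res$table$truth == "malignant" &
                      res$table$ct_doc == "malignant" &
                      res$table$model == "malignant", "n"]
  expect_equal(cell, 1)

  # a model identical to truth has no misclassifications
  res2 <- expert_agreement_table(truth, truth, data.frame(ct_doc = expert))
  expect_length(res2$misclassified$model, 0)

  expect_error(expert_agreement_table(truth, model[1:3],
                                      data.frame(ct_doc = expert)),
               "misaligned")
})
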