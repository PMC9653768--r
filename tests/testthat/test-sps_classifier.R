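fx <- load_reference_fixtures()

test_that("score assignment implements the three cytotoxicity modes", {
  counts <- condition_table(data.frame(
    compound_id = c("A", "B", "C"), bucket = "20x",
    concentration_label = "20x", truth = c("teratogen", "teratogen",
                                           "non_teratogen"),
    cytotoxic = c(FALSE, TRUE, FALSE)))
  counts$count <- c(100, NA, 3)

  comb <- assign_scores(counts, "combined")
  expect_equal(comb$score, c(100, 105, 3))  # max observed + 5
  expect_equal(comb$cytotox_assigned, c(FALSE, TRUE, FALSE))

  cyt <- assign_scores(counts, "cytotox_only")
  expect_equal(cyt$score, c(0, 1, 0))

  gene <- assign_scores(counts, "gene_only")
  expect_equal(gene$score, c(100, NA, 3))

  # no cytotoxic conditions: combined scores are the counts unchanged
  counts2 <- counts[!counts$cytotoxic, , drop = FALSE]
  expect_equal(assign_scores(counts2, "combined")$score, c(100, 3))

  # all conditions cytotoxic: the replacement maximum is undefined
  counts3 <- counts
  counts3$cytotoxic <- TRUE
  counts3$count <- NA_real_
  expect_error(assign_scores(counts3, "combined"), "undefined")
  # a non-cytotoxic condition must have a count
  counts4 <- counts
  counts4$count[3] <- NA
  expect_error(assign_scores(counts4, "combined"), "C")
})

test_that("the reference cytotoxic replacement is applied system-wide", {
  s20 <- reference_scores("20x", "combined", fx)
  expect_true(all(s20$score[s20$cytotox_assigned] == 4318))
  s1 <- reference_scores("1x", "combined", fx)
  expect_true(all(s1$score[s1$cytotox_assigned] == 4318))
})

test_that("20x substitution carries 1x scores with flags", {
  s1 <- reference_scores("1x", "combined", fx)
  s20 <- assign_scores(fx$conditions[fx$conditions$bucket == "20x", ],
                       "combined", cytotox_score = 4318)
  sub <- substitute_20x(s1, s20, fx$unavailable_20x)
  expect_equal(sub$score[sub$compound_id == "LFL"], 614 + 415)
  expect_equal(sub$score[sub$compound_id == "PHE"], 0)
  expect_true(all(sub$substituted_from_1x[sub$compound_id %in%
                                            fx$unavailable_20x]))
  expect_true(all(sub$bucket == "20x"))
  # empty substitution set is the identity
  expect_equal(substitute_20x(s1, s20, character(0)), s20)
  expect_error(substitute_20x(s1, s20, "NOPE"), "NOPE")
})

test_that("classification is strictly greater-than", {
  scores <- make_scores(c(1029, 1000, 84), rep("teratogen", 3))
  pred <- classify_scores(scores, 1000)
  expect_equal(pred$predicted, c(TRUE, FALSE, FALSE))
  expect_true(all(classify_scores(scores, 80)$predicted))
})

test_that("confusion metrics satisfy their defining identities", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  truth <- c("teratogen", "teratogen", "teratogen", "non_teratogen",
             "non_teratogen")
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$TP, 2); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)
  expect_equal(cm$accuracy, 3 / 5)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 1 / 2)
  expect_true(is.na(confusion_metrics(TRUE, "teratogen")$specificity))
})

test_that("the reference 20x false negatives are exactly the published four", {
  rep20 <- run_reference_classification("20x", "combined", fixtures = fx)
  pred <- rep20$predictions
  expect_setequal(pred$compound_id[pred$outcome == "FN"],
                  c("MEM", "PHE", "THD", "VIS"))
  expect_equal(rep20$FP, 0L)
})

test_that("AUC equals the brute-force pair-count oracle", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    truth <- sample(c("teratogen", "non_teratogen"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("teratogen", "non_teratogen")
    score <- sample(0:20, n, replace = TRUE)  # integer scores force ties
    expect_equal(roc_auc(score, truth), auc_oracle(score, truth))
  }
  expect_equal(roc_auc(c(5, 6, 1, 2), c("teratogen", "teratogen",
                                        "non_teratogen", "non_teratogen")), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c("teratogen", "non_teratogen"), 3)), 0.5)
  expect_error(roc_auc(1:3, rep("teratogen", 3)), "empty")
})

test_that("the reference 20x AUC is the published pair count", {
  s20 <- reference_scores("20x", "combined", fx)
  expect_equal(roc_auc(s20), 324 / 360)
  expect_equal(roc_auc(s20), auc_oracle(s20$score, s20$truth))
})

test_that("threshold search reports the optimal half-open interval", {
  s20 <- reference_scores("20x", "combined", fx)
  r20 <- search_threshold(s20)
  iv <- r20$optimal_threshold_interval
  expect_true(iv[1] <= 1000 && 1000 < iv[2])
  expect_equal(r20$threshold, iv[1])

  s1 <- reference_scores("1x", "combined", fx)
  r1 <- search_threshold(s1)
  iv1 <- r1$optimal_threshold_interval
  expect_true(iv1[1] <= 1 && 1 < iv1[2])

  toy <- make_scores(c(0, 0, 5, 5), c("non_teratogen", "non_teratogen",
                                      "teratogen", "teratogen"))
  rt <- search_threshold(toy)
  expect_equal(rt$accuracy, 1)
  expect_equal(rt$optimal_threshold_interval, c(0, 5))

  expect_error(search_threshold(make_scores(c(1, 1), c("teratogen",
                                                       "non_teratogen"))),
               "distinct")
})

test_that("searched reports are reproduced by classify + confusion", {
  set.seed(66)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    truth <- c("teratogen", "non_teratogen",
               sample(c("teratogen", "non_teratogen"), n - 2, replace = TRUE))
    scores <- make_scores(sample(0:8, n, replace = TRUE), truth)
    rep <- search_threshold(scores)
    cm <- confusion_metrics(classify_scores(scores, rep$threshold)$predicted,
                            truth)
    expect_equal(rep$accuracy, cm$accuracy)
    expect_equal(rep$sensitivity, cm$sensitivity)
    expect_equal(rep$specificity, cm$specificity)
  }
})

test_that("gene-only mode counts cytotoxic as negative and excludes from AUC", {
  g20 <- reference_scores("20x", "gene_only", fx)
  rep <- search_threshold(g20)
  expect_equal(round2(rep$sensitivity), 0.38)
  expect_equal(round2(rep$accuracy), 0.62)
  expect_equal(round2(rep$auc), 0.82)
  # cytotoxic conditions predicted negative at any threshold
  expect_false(any(classify_scores(g20, -1)$predicted[is.na(g20$score)]))
  # AUC ranking excludes them
  keep <- !is.na(g20$score)
  expect_equal(rep$auc, auc_oracle(g20$score[keep], g20$truth[keep]))
})

test_that("published outcome labels convert back to metrics", {
  cm <- confusion_from_labels(c("TP", "TP", "FN", "TN", "FP", NA))
  expect_equal(cm$TP, 2); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)
  expect_error(confusion_from_labels("XX"), "TP/TN/FP/FN")
})
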