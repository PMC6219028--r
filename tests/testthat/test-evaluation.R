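# Confusion metrics, ROC/AUC, and model evaluation reports.

test_that("sensitivity, specificity and accuracy follow their definitions", {
  perfect <- classification_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100))
  m <- classification_metrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 60)
  expect_equal(m$accuracy, 70)
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5)),
               class = "ivustex_error_undefined_rate")
  expect_error(classification_metrics(list(TP = 5, FN = 5, TN = 0, FP = 0)),
               class = "ivustex_error_undefined_rate")
})

test_that("accuracy is the prevalence-weighted blend of sensitivity and specificity", {
  withr::with_seed(71, {
    for (i in 1:25) {
      cts <- as.list(setNames(sample(0:30, 4, TRUE) + 1, c("TP", "TN", "FP", "FN")))
      m <- classification_metrics(cts)
      npos <- cts$TP + cts$FN; nneg <- cts$TN + cts$FP
      expect_equal(m$accuracy,
                   (m$sensitivity * npos + m$specificity * nneg) / (npos + nneg),
                   tolerance = 1e-12)
    }
  })
})

test_that("confusion counts add up and support factor labels", {
  truth <- factor(c("A", "A", "B", "B", "B"))
  pred <- factor(c("A", "B", "B", "B", "A"))
  ct <- confusion_counts(truth, pred, positive = "A")
  expect_equal(ct, list(TP = 1L, TN = 2L, FP = 1L, FN = 1L))
  expect_equal(ct$TP + ct$TN + ct$FP + ct$FN, 5L)
})

test_that("trapezoid AUC equals tie-adjusted pairwise concordance", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  # uninformative scorer: all scores tied
  expect_equal(roc_auc(rep(0.3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "ivustex_error_undefined_roc")

  withr::with_seed(81, {
    for (i in 1:50) {
      n <- sample(10:40, 1)
      scores <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)  # many ties
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(truth) || all(!truth)) truth[1:2] <- c(TRUE, FALSE)
      got <- roc_auc(scores, truth)
      expect_equal(got$auc, oracle_auc(scores, truth), tolerance = 1e-12)
      # curve runs from (0,0) to (1,1), monotone in both axes
      expect_equal(got$roc$fpr[1], 0)
      expect_equal(got$roc$tpr[nrow(got$roc)], 1)
      expect_true(all(diff(got$roc$fpr) >= 0) && all(diff(got$roc$tpr) >= 0))
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(82, {
    scores <- runif(60)
    truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    a0 <- roc_auc(scores, truth)$auc
    expect_equal(roc_auc(exp(3 * scores), truth)$auc, a0, tolerance = 1e-12)
    expect_equal(roc_auc(rank(scores), truth)$auc, a0, tolerance = 1e-12)
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(83, {
    scores <- round(runif(200), 2)
    truth <- runif(200) < 0.4
    ours <- roc_auc(scores, truth)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                          predictor = scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("evaluate_model reports per-net pools and the 4-class confusion", {
  f <- small_features()$features
  m <- small_model()
  rep <- evaluate_model(m, f)
  td <- tidy(rep)
  expect_identical(td$net, c("net1", "net2", "net3"))
  expect_true(all(td$sensitivity >= 0 & td$sensitivity <= 100))
  expect_true(all(td$auc >= 0 & td$auc <= 1))
  # net pools: net1 = low pixels, net2 = FT/FFT truth, net3 = NC/DC truth
  expect_equal(td$n[1], sum(f$intensity <= m$threshold))
  expect_equal(td$n[2], sum(f$label %in% c("FT", "FFT")))
  expect_equal(td$n[3], sum(f$label %in% c("NC", "DC")))
  expect_equal(sum(rep$confusion), nrow(f))
  # confusion-table diagonal matches the overall accuracy
  expect_equal(100 * sum(diag(rep$confusion)) / sum(rep$confusion),
               rep$overall_accuracy)
  # routed pools are no larger than truth pools for nets 2-3
  rep2 <- evaluate_model(m, f, pool = "routed")
  expect_lte(tidy(rep2)$n[2], td$n[2])
  expect_lte(tidy(rep2)$n[3], td$n[3])
})

test_that("shuffled labels drive accuracy to the prior and AUC toward 1/2", {
  f <- small_features()$features
  m <- small_model()
  shuffled <- f
  withr::with_seed(91, shuffled$label <- sample(shuffled$label))
  rep <- evaluate_model(m, shuffled)
  for (e in rep$nets) {
    expect_lt(abs(e$auc - 0.5), 0.06)
    prior <- max(e$counts$TP + e$counts$FN, e$counts$TN + e$counts$FP) / e$n
    expect_lt(e$accuracy / 100, prior + 0.06)
  }
})

test_that("reports round-trip through JSON", {
  f <- small_features()$features
  m <- small_model()
  rep <- evaluate_model(m, f)
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep, p)
  got <- read_report(p)
  expect_equal(tidy(got), tidy(rep), tolerance = 1e-12)
  expect_equal(got$overall_accuracy, rep$overall_accuracy, tolerance = 1e-12)
  expect_equal(as.vector(got$confusion), as.vector(rep$confusion))
  for (nm in names(rep$nets))
    expect_equal(got$nets[[nm]]$roc, rep$nets[[nm]]$roc, tolerance = 1e-12)
})
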