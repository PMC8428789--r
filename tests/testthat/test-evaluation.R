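test_that("confusion matrix counts truth rows against prediction columns", {
  truth <- rep(class_levels(), each = 5)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm), setNames(rep(5L, 3), class_levels()))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  cm2 <- confusion_matrix(c("benign", "benign", rep("early_stage", 3)),
                          rep("benign", 5))
  expect_equal(unname(cm2[, "benign"]), c(2L, 3L, 0L))
  expect_equal(sum(cm2[, -1]), 0L)

  expect_equal(sum(confusion_matrix(character(0), character(0))), 0L)
  expect_error(confusion_matrix("benign", c("benign", "benign")), "length")
  expect_error(confusion_matrix("malign", "benign"), "invalid")
})

test_that("per-class metrics reproduce the screening-cohort accuracy from counts", {
  # per-class correct counts 63/70, 60/70, 49/60 give 86% overall accuracy
  cm <- matrix(c(63L, 7L, 0L,
                 5L, 60L, 5L,
                 0L, 11L, 49L),
               nrow = 3, byrow = TRUE,
               dimnames = list(truth = class_levels(),
                               predicted = class_levels()))
  m <- per_class_metrics(cm)
  expect_equal(m$accuracy, 0.86)
  expect_equal(m$per_class$recall, c(63, 60, 49) / c(70, 70, 60))

  # identity-like matrix: all ones
  m1 <- per_class_metrics(diag(3L) * 1L)
  expect_equal(m1$per_class$precision, rep(1, 3))
  expect_equal(m1$per_class$recall, rep(1, 3))

  # a class never predicted has undefined precision
  cm0 <- matrix(c(5L, 0L, 0L, 5L, 0L, 0L, 0L, 0L, 5L), nrow = 3, byrow = TRUE)
  m0 <- per_class_metrics(cm0)
  expect_true(is.na(m0$per_class$precision[2]))
  expect_false(any(is.na(m0$per_class$recall)))

  expect_true(is.na(per_class_metrics(matrix(0L, 3, 3))$accuracy))
})

test_that("accuracy equals the recall mean weighted by class prevalence", {
  set.seed(61)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 8), 3, 3)
    m <- per_class_metrics(cm)
    w <- rowSums(cm) / sum(cm)
    expect_equal(m$accuracy, sum(w * m$per_class$recall, na.rm = TRUE))
  }
})

test_that("binary count metrics reproduce the stage-likelihood validation figures", {
  # 143 advanced (125 detected) vs 47 early (40 detected)
  b <- binary_metrics_from_counts(143, 125, 47, 40)
  expect_equal(b$accuracy, 165 / 190)
  expect_equal(b$sensitivity, 125 / 143)
  expect_equal(b$specificity, 40 / 47)
  expect_equal(round(100 * unlist(b), 2),
               c(accuracy = 86.84, sensitivity = 87.41, specificity = 85.11))

  expect_equal(unlist(binary_metrics_from_counts(10, 10, 10, 10)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(unlist(binary_metrics_from_counts(10, 5, 10, 5)),
               c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5))
  expect_error(binary_metrics_from_counts(10, 11, 10, 5), "exceed")
  expect_error(binary_metrics_from_counts(0, 0, 10, 5), "> 0")
})

test_that("binary accuracy always lies between sensitivity and specificity", {
  set.seed(62)
  for (i in 1:30) {
    pt <- sample(1:50, 1); nt <- sample(1:50, 1)
    pc <- sample(0:pt, 1); nc <- sample(0:nt, 1)
    b <- binary_metrics_from_counts(pt, pc, nt, nc)
    expect_gte(b$accuracy, min(b$sensitivity, b$specificity))
    expect_lte(b$accuracy, max(b$sensitivity, b$specificity))
  }
})

test_that("multiclass MCC matches an independent triple-sum implementation", {
  mcc_bruteforce <- function(C) {
    K <- nrow(C)
    num <- 0
    for (k in 1:K) for (l in 1:K) for (m in 1:K) {
      num <- num + C[k, k] * C[l, m] - C[k, l] * C[m, k]
    }
    d1 <- 0; d2 <- 0
    for (k in 1:K) {
      d1 <- d1 + sum(C[k, ]) * sum(C[-k, ])
      d2 <- d2 + sum(C[, k]) * sum(C[, -k])
    }
    if (d1 == 0 || d2 == 0) return(NA_real_)
    num / (sqrt(d1) * sqrt(d2))
  }
  expect_equal(multiclass_mcc(diag(3L) * 5L), 1)
  balanced_noise <- matrix(2L, 3, 3)
  expect_equal(multiclass_mcc(balanced_noise), 0)
  cm <- matrix(c(2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 2L), 3, byrow = TRUE)
  expect_equal(multiclass_mcc(cm), mcc_bruteforce(cm))
  set.seed(63)
  for (i in 1:15) {
    cm <- matrix(rpois(9, 5), 3, 3)
    expect_equal(multiclass_mcc(cm), mcc_bruteforce(cm))
  }
  expect_true(is.na(multiclass_mcc(matrix(0L, 3, 3))))
})

test_that("MCC is invariant under a simultaneous class permutation", {
  set.seed(64)
  cm <- matrix(rpois(9, 6), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(multiclass_mcc(cm[perm, perm]), multiclass_mcc(cm))
})

test_that("rank-based AUC handles separation, ties and pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  # 4 pos/neg pairs, 3 concordant: (0.35 > 0.1), (0.8 > 0.1), (0.8 > 0.4)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_true(is.na(roc_auc(c(1, 2), c(1, 1))))
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(65)
  scores <- runif(40)
  truth <- rbinom(40, 1, plogis(6 * scores - 3))
  if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
  a <- roc_auc(scores, truth)
  expect_equal(roc_auc(qlogis(scores / 1.0001 + 1e-5), truth), a)
  expect_equal(roc_auc(scores * 100 - 3, truth), a)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref)
})

test_that("wilson interval behaves at the extremes and covers the MLE", {
  ci <- wilson_ci(8, 10)
  expect_true(ci[["low"]] < 0.8 && 0.8 < ci[["high"]])
  expect_gte(wilson_ci(0, 10)[["low"]], 0)
  expect_lte(wilson_ci(10, 10)[["high"]], 1)
  expect_lt(wilson_ci(5, 1000)[["high"]], 0.02)
})

test_that("cohort evaluation joins, scores and collapses to binary", {
  results <- tibble::tibble(
    nodule_id = sprintf("n%02d", 1:9),
    final_score = c(0.2, 0.3, 0.4, 0.55, 0.6, 0.65, 0.75, 0.8, 0.45),
    label = c(rep("benign", 3), rep("early_stage", 3),
              rep("advanced_stage", 2), "benign")
  )
  truth <- tibble::tibble(
    nodule_id = sprintf("n%02d", 1:9),
    truth_label = rep(class_levels(), each = 3)
  )
  ev <- evaluate_cohort(results, truth)
  expect_equal(ev$n, 9)
  expect_equal(ev$accuracy, 8 / 9)
  expect_equal(unname(ev$auc[["benign"]]), 1)
  expect_equal(unname(ev$auc[["advanced_stage"]]), 15 / 18)
  # binary collapse: one advanced nodule was predicted benign
  expect_equal(ev$binary$sensitivity, 5 / 6)
  expect_equal(ev$binary$specificity, 1)
  gl <- glance(ev)
  expect_equal(gl$mcc, multiclass_mcc(ev$confusion))

  expect_error(evaluate_cohort(results[1:5, ], truth), "mismatch")
  perfect <- results
  perfect$label <- as.character(truth$truth_label)
  expect_equal(evaluate_cohort(perfect, truth)$accuracy, 1)
})
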