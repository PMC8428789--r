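# Classification metrics over diagnosed cohorts: 3-class confusion matrix,
# per-class precision/recall with Wilson intervals, accuracy, generalized
# (Gorodkin) multiclass MCC, one-vs-rest ROC AUCs and a benign-vs-malignant
# binary collapse.

.as_class_factor <- function(x, what) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), class_levels())
  if (length(bad) > 0) {
    stop("invalid ", what, " label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = class_levels())
}

#' Three-class confusion matrix
#'
#' @param truth,predicted Vectors of class labels (values from
#'   [class_levels()]), equal length. Rows of the result are truth, columns
#'   prediction.
#' @return A 3x3 integer matrix with dimnames `truth` x `predicted`.
#' @export
#' @examples
#' confusion_matrix(c("benign", "early_stage"), c("benign", "benign"))
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` have different lengths.", call. = FALSE)
  }
  tab <- table(truth = .as_class_factor(truth, "truth"),
               predicted = .as_class_factor(predicted, "predicted"))
  matrix(as.integer(tab), nrow = 3L,
         dimnames = list(truth = class_levels(),
                         predicted = class_levels()))
}

#' Wilson score interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Per-class precision and recall, and overall accuracy
#'
#' Precision is the diagonal count over its column sum (positive predictive
#' value), recall the diagonal count over its row sum (sensitivity);
#' accuracy is the trace over the total. A zero denominator yields `NA`
#' rather than an error. Wilson 95% intervals accompany each proportion.
#'
#' @param cm A 3x3 confusion matrix from [confusion_matrix()].
#' @param conf_level Confidence level for the Wilson intervals.
#' @return A list of class `"class_metrics"`: `per_class` tibble (`class`,
#'   `n_truth`, `n_predicted`, `correct`, `precision`, `recall` and their
#'   interval bounds) and scalar `accuracy` (`NA` for an empty matrix).
#' @export
per_class_metrics <- function(cm, conf_level = 0.95) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(3L, 3L)), all(cm >= 0))
  total <- sum(cm)
  diagd <- unname(diag(cm))
  rows <- unname(rowSums(cm))
  cols <- unname(colSums(cm))
  prop_ci <- function(x, n) {
    if (n > 0) wilson_ci(x, n, conf_level) else c(low = NA_real_,
                                                 high = NA_real_)
  }
  per_class <- purrr::map_dfr(seq_len(3L), function(i) {
    pci <- prop_ci(diagd[i], cols[i])
    rci <- prop_ci(diagd[i], rows[i])
    tibble::tibble(
      class = class_levels()[i],
      n_truth = as.integer(rows[i]), n_predicted = as.integer(cols[i]),
      correct = as.integer(diagd[i]),
      precision = if (cols[i] > 0) diagd[i] / cols[i] else NA_real_,
      precision_low = pci[["low"]], precision_high = pci[["high"]],
      recall = if (rows[i] > 0) diagd[i] / rows[i] else NA_real_,
      recall_low = rci[["low"]], recall_high = rci[["high"]]
    )
  })
  structure(
    list(per_class = per_class,
         accuracy = if (total > 0) sum(diagd) / total else NA_real_,
         n = total),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics> n =", x$n, "\n")
  print(x$per_class[, c("class", "precision", "recall")])
  cat(sprintf("overall accuracy: %s\n",
              ifelse(is.na(x$accuracy), "NA", sprintf("%.4f", x$accuracy))))
  invisible(x)
}

#' Binary accuracy, sensitivity and specificity from counts
#'
#' Computes the three standard binary metrics from correct-detection counts:
#' sensitivity = `pos_correct / pos_total`, specificity =
#' `neg_correct / neg_total`, accuracy = pooled correct over pooled total.
#'
#' @param pos_total,pos_correct Positive-class totals and correct counts.
#' @param neg_total,neg_correct Negative-class totals and correct counts.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' binary_metrics_from_counts(143, 125, 47, 40)
binary_metrics_from_counts <- function(pos_total, pos_correct,
                                       neg_total, neg_correct) {
  counts <- c(pos_total, pos_correct, neg_total, neg_correct)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers.", call. = FALSE)
  }
  if (pos_total <= 0 || neg_total <= 0) {
    stop("class totals must be > 0.", call. = FALSE)
  }
  if (pos_correct > pos_total || neg_correct > neg_total) {
    stop("correct counts cannot exceed class totals.", call. = FALSE)
  }
  tibble::tibble(
    accuracy = (pos_correct + neg_correct) / (pos_total + neg_total),
    sensitivity = pos_correct / pos_total,
    specificity = neg_correct / neg_total
  )
}

#' Generalized (Gorodkin) multiclass Matthews correlation coefficient
#'
#' Covariance form over the full confusion matrix:
#' `(c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))` with `c`
#' the trace, `s` the total, `t` the row (truth) sums and `p` the column
#' (prediction) sums. Returns `NA` when either variance term vanishes.
#'
#' @param cm A 3x3 confusion matrix.
#' @return Scalar in \[-1, 1\], or `NA`.
#' @export
multiclass_mcc <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  s <- sum(cm)
  if (s == 0) return(NA_real_)
  c0 <- sum(diag(cm))
  t <- rowSums(cm)
  p <- colSums(cm)
  denom2 <- (s^2 - sum(p^2)) * (s^2 - sum(t^2))
  if (denom2 <= 0) return(NA_real_)
  (c0 * s - sum(p * t)) / sqrt(denom2)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Probability that a random positive scores above a random negative, with
#' half credit for ties (average ranks).
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param truth Binary indicator (logical, or 0/1) of the positive class.
#' @return AUC in \[0, 1\]; `NA` when only one class is present.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` have different lengths.", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(truth))) {
    stop("missing values in `scores` or `truth`.", call. = FALSE)
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Class-membership score used for the one-vs-rest AUCs: higher score must
# mean "more like this class". The final diagnostic score is monotone for
# the extreme classes; for the middle (early-stage) class the negative
# distance to the class score-range midpoint is used.
.ovr_score <- function(score, class) {
  switch(class,
    benign = -score,
    early_stage = -abs(score - (.SCORE_EARLY + .SCORE_ADVANCED) / 2),
    advanced_stage = score,
    stop("unknown class: ", class, call. = FALSE)
  )
}

#' Evaluate diagnosed nodules against ground truth
#'
#' Joins per-nodule filter results with truth labels and computes the full
#' evaluation report: 3-class confusion matrix, per-class precision/recall
#' with Wilson intervals, overall accuracy, multiclass MCC, one-vs-rest
#' AUCs from the final scores, and the benign-vs-malignant binary collapse
#' (malignant = early + advanced is the positive class).
#'
#' @param results Tibble with `nodule_id`, `final_score` and `label`
#'   columns, as returned by [run_cohort()].
#' @param truth Tibble with `nodule_id` and `truth_label` columns.
#' @return A list of class `"cohort_evaluation"`.
#' @export
evaluate_cohort <- function(results, truth) {
  results <- tibble::as_tibble(results)
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("nodule_id", "final_score", "label") %in% names(results)),
            all(c("nodule_id", "truth_label") %in% names(truth)))
  only_res <- setdiff(results$nodule_id, truth$nodule_id)
  only_truth <- setdiff(truth$nodule_id, results$nodule_id)
  if (length(only_res) > 0 || length(only_truth) > 0) {
    stop("nodule_id mismatch between results and truth.",
         if (length(only_res) > 0)
           paste0(" Only in results: ",
                  paste(utils::head(only_res, 5), collapse = ", "), "."),
         if (length(only_truth) > 0)
           paste0(" Only in truth: ",
                  paste(utils::head(only_truth, 5), collapse = ", "), "."),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(results, truth[, c("nodule_id", "truth_label")],
                              by = "nodule_id")
  cm <- confusion_matrix(joined$truth_label, joined$label)
  metrics <- per_class_metrics(cm)
  auc <- vapply(class_levels(), function(cl) {
    roc_auc(.ovr_score(joined$final_score, cl), joined$truth_label == cl)
  }, numeric(1))
  malignant <- joined$truth_label %in% c("early_stage", "advanced_stage")
  pred_malignant <- joined$label %in% c("early_stage", "advanced_stage")
  binary <- if (any(malignant) && any(!malignant)) {
    binary_metrics_from_counts(
      pos_total = sum(malignant),
      pos_correct = sum(malignant & pred_malignant),
      neg_total = sum(!malignant),
      neg_correct = sum(!malignant & !pred_malignant)
    )
  } else {
    tibble::tibble(accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_)
  }
  structure(
    list(confusion = cm, per_class = metrics$per_class,
         accuracy = metrics$accuracy, mcc = multiclass_mcc(cm),
         auc = auc, binary = binary, n = nrow(joined)),
    class = "cohort_evaluation"
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat("<cohort_evaluation> n =", x$n, "\n\nConfusion matrix (truth x predicted):\n")
  print(x$confusion)
  cat("\n")
  print(x$per_class[, c("class", "precision", "recall")])
  cat(sprintf("\naccuracy %.4f | MCC %.4f\n", x$accuracy, x$mcc))
  cat("one-vs-rest AUC:",
      paste(sprintf("%s %.4f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat(sprintf("binary (malignant vs benign): acc %.4f sens %.4f spec %.4f\n",
              x$binary$accuracy, x$binary$sensitivity, x$binary$specificity))
  invisible(x)
}

#' @method tidy cohort_evaluation
#' @export
tidy.cohort_evaluation <- function(x, ...) x$per_class

#' @method glance cohort_evaluation
#' @export
glance.cohort_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy = x$accuracy, mcc = x$mcc,
    auc_benign = x$auc[["benign"]],
    auc_early = x$auc[["early_stage"]],
    auc_advanced = x$auc[["advanced_stage"]],
    binary_accuracy = x$binary$accuracy,
    binary_sensitivity = x$binary$sensitivity,
    binary_specificity = x$binary$specificity
  )
}

#' Write an evaluation report to JSON and a text table
#'
#' @param eval_obj A [evaluate_cohort()] result.
#' @param json_path,txt_path Output paths (either may be `NULL` to skip).
#' @return `eval_obj`, invisibly.
#' @export
write_evaluation_report <- function(eval_obj, json_path = NULL,
                                    txt_path = NULL) {
  stopifnot(inherits(eval_obj, "cohort_evaluation"))
  if (!is.null(json_path)) {
    doc <- list(
      n = eval_obj$n,
      confusion = list(classes = class_levels(),
                       counts = unname(eval_obj$confusion)),
      per_class = eval_obj$per_class,
      accuracy = eval_obj$accuracy,
      mcc = eval_obj$mcc,
      auc_one_vs_rest = as.list(eval_obj$auc),
      binary_collapse = as.list(eval_obj$binary)
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(txt_path)) {
    writeLines(utils::capture.output(print(eval_obj)), txt_path)
  }
  invisible(eval_obj)
}
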