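# Evaluation metrics: ROC AUC (Mann-Whitney form), PR AUC (average
# precision), the seven-metric classification report, model comparison.

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the probability that a random
#' positive scores above a random negative, with ties counted 1/2, via the
#' rank formula.
#'
#' @param scores numeric scores.
#' @param labels binary labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-rule average precision: `sum over ranked positives of
#' (R_k - R_{k-1}) * P_k`, with tied scores grouped so the value does not
#' depend on the order of ties. No trapezoidal interpolation is applied.
#'
#' @param scores numeric scores.
#' @param labels binary labels; at least one positive required.
#' @return AUPRC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("at least one positive required")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp_prev <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    prec <- tp / sum(sel)
    ap <- ap + (tp - tp_prev) / npos * prec
    tp_prev <- tp
  }
  ap
}

#' Seven-metric classification report
#'
#' Confusion counts at the rule `score > threshold`, plus the
#' threshold-free AUC and AUPRC: accuracy, precision, recall, F1 and
#' specificity are derived from the counts. Any zero-denominator cell is
#' reported as 0 and flagged in `degenerate`.
#'
#' @param scores numeric scores.
#' @param labels binary labels, both classes present.
#' @param threshold classification cut (default 0.5).
#' @return an object of class `metrics_report`: a list with `auc`, `auprc`,
#'   `accuracy`, `precision`, `recall`, `f1`, `specificity`,
#'   `threshold_used`, `n_pos`, `n_neg`, counts `tp/fp/fn/tn`, and
#'   `degenerate` (names of zero-denominator metrics).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pred <- scores > threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  degenerate <- character(0)
  div <- function(num, den, nm) {
    if (den == 0) { degenerate <<- c(degenerate, nm); return(0) }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  structure(list(
    auc = roc_auc(scores, labels),
    auprc = pr_auc(scores, labels),
    accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1,
    specificity = div(tn, tn + fp, "specificity"),
    threshold_used = threshold,
    n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
    tp = tp, fp = fp, fn = fn, tn = tn,
    degenerate = degenerate), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "auc %.3f  auprc %.3f  acc %.3f  prec %.3f  rec %.3f  f1 %.3f  spec %.3f (thr %.3f, %d+/%d-)\n",
    x$auc, x$auprc, x$accuracy, x$precision, x$recall, x$f1, x$specificity,
    x$threshold_used, x$n_pos, x$n_neg))
  if (length(x$degenerate))
    cat("  zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Compare fitted models on one test set
#'
#' Scores each model on the identical test matrix, picks each model's
#' Youden-optimal threshold, and reports all seven metrics per model.
#'
#' @param models named list of `variant_cnn` objects.
#' @param test_x test feature matrix.
#' @param test_labels binary test labels.
#' @return data frame, one row per model, with the metric columns and an
#'   `error` column (NA unless scoring that model failed).
#' @export
compare_models <- function(models, test_x, test_labels) {
  cols <- c("auc", "auprc", "accuracy", "precision", "recall", "f1",
            "specificity", "threshold_used")
  rows <- lapply(names(models), function(nm) {
    r <- tryCatch({
      s <- predict(models[[nm]], test_x)
      m <- classification_metrics(s, test_labels,
                                  choose_threshold(s, test_labels))
      c(as.list(unclass(m)[cols]), list(error = NA_character_))
    }, error = function(e) {
      c(stats::setNames(as.list(rep(NA_real_, length(cols))), cols),
        list(error = conditionMessage(e)))
    })
    data.frame(model = nm, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(model = character(0))
  rownames(out) <- NULL
  out
}
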