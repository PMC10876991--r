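# Top-level modelling interface: fit the semi-supervised classifier in one
# call and interrogate it through the usual S3 methods.

empty_pseudo_set <- function() {
  out <- data.frame(key = character(0), mean_prob = numeric(0),
                    label = integer(0), stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- 0L
  attr(out, "discarded") <- character(0)
  attr(out, "pair") <- threshold_pair(0)
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}

# ROC step-curve points (FPR, TPR) over all observed cut points
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1L) / sum(labels == 1L)
  fpr <- cumsum(labels[ord] == 0L) / sum(labels == 0L)
  last <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fpr[last]), tpr = c(0, tpr[last]))
}

#' Fit a semi-supervised regulatory-variant classifier
#'
#' One-call driver for the full self-training workflow on a labeled
#' variants-by-features annotation matrix plus an unlabeled pool:
#'
#' 1. a supervised baseline is fit on the labeled training set under
#'    `k`-fold cross-validation (best fold model by held-out AUC);
#' 2. out-of-fold probabilities for the unlabeled pool are filtered by a
#'    per-variant one-sample t-test against the 0.5 decision boundary;
#' 3. for every `delta` in `deltas`, the retained pool is pseudo-labeled
#'    at the symmetric pair `(0.5 + delta, 0.5 - delta)`, the model is
#'    retrained on the augmented set, and its AUC on the independent test
#'    set selects the winning threshold pair;
#' 4. the winning retrained model is the final scorer; a Youden-optimal
#'    classification threshold is chosen on its test scores.
#'
#' @param x numeric labeled matrix (variants x features; rownames are
#'   variant keys).
#' @param y binary labels for `x`.
#' @param unlabeled numeric pool matrix with the same columns; rownames
#'   disjoint from `x`.
#' @param test_x,test_y independent test set. If omitted, 20% of the
#'   labeled data is held out by [split_dataset()] before any training.
#' @param spec a [cnn_spec()] sized to `ncol(x)`.
#' @param deltas threshold-offset grid (default 0, 0.1, 0.2, 0.3, 0.4).
#' @param alpha t-test significance level (default 0.05).
#' @param k folds (default 5).
#' @param epochs,lr,batch_size training parameters (defaults 50, 0.001,
#'   32).
#' @param seed integer seed; the entire fit is deterministic given it.
#' @return an object of class `pseudovar` with components `supervised` and
#'   `model` (both `variant_cnn`), `report` (per-delta grid), `best_pair`,
#'   `pseudo`, `retained`, `fold_preds`, `metrics` /
#'   `metrics_supervised`, `threshold`, and the test data used.
#' @seealso [predict.pseudovar()], [summary.pseudovar()],
#'   [plot.pseudovar()]
#' @export
pseudovar <- function(x, y, unlabeled, test_x = NULL, test_y = NULL,
                      spec = cnn_spec(ncol(x)),
                      deltas = c(0, 0.1, 0.2, 0.3, 0.4), alpha = 0.05,
                      k = 5, epochs = 50, lr = 0.001, batch_size = 32,
                      seed = 1) {
  cl <- match.call()
  x <- as.matrix(x); unlabeled <- as.matrix(unlabeled)
  if (ncol(unlabeled) != ncol(x)) stop("unlabeled must share the columns of x")
  with_seed(seed, {
    split_seed <- sample.int(.Machine$integer.max, 1)
    sup_seed <- sample.int(.Machine$integer.max, 1)
    grid_seed <- sample.int(.Machine$integer.max, 1)
    if (is.null(test_x)) {
      sp <- split_dataset(x, test_frac = 0.2, seed = split_seed)
      test_x <- sp$test; test_y <- y[sp$test_idx]
      x <- sp$train; y <- y[sp$train_idx]
    }
    supervised <- augment_and_retrain(x, y, empty_pseudo_set(), unlabeled,
                                      spec = spec, k = k, seed = sup_seed,
                                      epochs = epochs, lr = lr,
                                      batch_size = batch_size)
    gs <- threshold_grid_search(x, y, unlabeled, test_x, test_y, spec = spec,
                                deltas = deltas, alpha = alpha, k = k,
                                seed = grid_seed, epochs = epochs, lr = lr,
                                batch_size = batch_size)
    s_sup <- predict(supervised, test_x)
    s_fin <- predict(gs$best_model, test_x)
    thr <- choose_threshold(s_fin, test_y)
    structure(list(
      call = cl, spec = spec, seed = seed,
      supervised = supervised, model = gs$best_model,
      report = gs$report, best_pair = gs$best_pair,
      pseudo = gs$pseudo, retained = gs$retained,
      fold_preds = gs$fold_preds,
      x = x, y = y, test_x = test_x, test_y = test_y,
      threshold = thr,
      metrics_supervised = classification_metrics(
        s_sup, test_y, choose_threshold(s_sup, test_y)),
      metrics = classification_metrics(s_fin, test_y, thr)),
      class = "pseudovar")
  })
}

#' Score new variants with a fitted semi-supervised model
#'
#' @param object a `pseudovar` fit.
#' @param newdata matrix with the model's input columns; defaults to the
#'   labeled training matrix.
#' @param type `"response"` for probabilities, `"class"` for 0/1 calls at
#'   the fit's Youden threshold.
#' @param ... unused.
#' @return numeric score vector or integer class vector.
#' @export
predict.pseudovar <- function(object, newdata = object$x,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  predict(object$model, newdata, type = type, threshold = object$threshold)
}

#' @export
print.pseudovar <- function(x, ...) {
  cat("Semi-supervised regulatory-variant classifier\n")
  cat(sprintf("  labeled train: %d (%d+/%d-)   pool: %d   test: %d\n",
              nrow(x$x), sum(x$y == 1), sum(x$y == 0),
              nrow(x$fold_preds$probs), nrow(x$test_x)))
  cat(sprintf("  pseudo-labels at (%.2f/%.2f): %d positive, %d negative (%d in band, %d failed t-test)\n",
              x$best_pair$upper, x$best_pair$lower,
              sum(x$pseudo$label == 1), sum(x$pseudo$label == 0),
              attr(x$pseudo, "n_discarded"),
              nrow(x$fold_preds$probs) - length(x$retained)))
  cat(sprintf("  test AUC %.3f (supervised baseline %.3f)\n",
              x$metrics$auc, x$metrics_supervised$auc))
  invisible(x)
}

#' Summarize a semi-supervised fit
#'
#' @param object a `pseudovar` fit.
#' @param ... unused.
#' @return the object, invisibly; prints the per-delta grid report and the
#'   seven-metric test report of the final and baseline models.
#' @export
summary.pseudovar <- function(object, ...) {
  print(object)
  cat("\nThreshold grid (AUC on the independent test set):\n")
  print(object$report, row.names = FALSE, digits = 4)
  cat("\nFinal model test metrics:\n")
  print(object$metrics)
  cat("Supervised baseline test metrics:\n")
  print(object$metrics_supervised)
  invisible(object)
}

#' @export
coef.pseudovar <- function(object, ...) object$model$weights

#' @export
fitted.pseudovar <- function(object, ...) predict(object$model, object$x)

#' @export
residuals.pseudovar <- function(object, ...) object$y - fitted(object)

#' Plot ROC curves of a semi-supervised fit
#'
#' Draws the independent-test ROC curve of the final model and, for
#' comparison, the supervised baseline.
#'
#' @param x a `pseudovar` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pseudovar <- function(x, ...) {
  r_fin <- roc_points(predict(x$model, x$test_x), x$test_y)
  r_sup <- roc_points(predict(x$supervised, x$test_x), x$test_y)
  plot(r_fin$fpr, r_fin$tpr, type = "s", col = "#D4A017", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       main = "Independent-test ROC", ...)
  lines(r_sup$fpr, r_sup$tpr, type = "s", col = "#2E7D32", lwd = 2)
  abline(0, 1, lty = 3, col = "grey50")
  legend("bottomright", bty = "n", lwd = 2, col = c("#D4A017", "#2E7D32"),
         legend = c(sprintf("semi-supervised (AUC %.3f)", x$metrics$auc),
                    sprintf("supervised (AUC %.3f)",
                            x$metrics_supervised$auc)))
  invisible(x)
}
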