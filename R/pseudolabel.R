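# Semi-supervised core: out-of-fold prediction of the unlabeled pool,
# t-test consistency filtering, symmetric-threshold pseudo-labeling,
# threshold grid search, and retraining on the augmented set.

make_folds <- function(n, k) {
  # seeded by the caller; disjoint, exhaustive partition
  fold <- rep(seq_len(k), length.out = n)
  fold[sample.int(n)]
}

#' Out-of-fold probabilities for an unlabeled pool
#'
#' Partitions the labeled set into `k` seeded folds; for each fold a model
#' is trained on the other `k - 1` folds and scores the entire unlabeled
#' pool, giving one probability column per fold.
#'
#' @param x,y labeled feature matrix and binary labels.
#' @param unlabeled_x unlabeled pool matrix (same columns as `x`); rownames
#'   are the pool's variant keys.
#' @param spec a [cnn_spec()] sized to `ncol(x)`.
#' @param k number of folds (default 5).
#' @param seed integer seed driving the fold partition and every fold
#'   model.
#' @param epochs,lr,batch_size training parameters passed to [cnn_fit()].
#' @return an object of class `fold_predictions`: list with `probs`
#'   (pool-by-k matrix, rownames = pool keys), `fold` (fold id of each
#'   labeled record) and `k`.
#' @export
crossval_fold_predictions <- function(x, y, unlabeled_x, spec = cnn_spec(ncol(x)),
                                      k = 5, seed = 1, epochs = 50, lr = 0.001,
                                      batch_size = 32) {
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the labeled-set size")
  with_seed(seed, {
    fold <- make_folds(nrow(x), k)
    sub_seeds <- sample.int(.Machine$integer.max, k)
    probs <- matrix(NA_real_, nrow(unlabeled_x), k,
                    dimnames = list(rownames(unlabeled_x),
                                    paste0("fold", seq_len(k))))
    for (j in seq_len(k)) {
      tr <- fold != j
      fit <- cnn_fit(x[tr, , drop = FALSE], y[tr], spec = spec,
                     epochs = epochs, lr = lr, batch_size = batch_size,
                     seed = sub_seeds[j])
      probs[, j] <- predict(fit, unlabeled_x)
    }
    structure(list(probs = probs, fold = fold, k = k),
              class = "fold_predictions")
  })
}

#' t-test consistency filter on fold probabilities
#'
#' For each pool variant, a two-sided one-sample Student's t-test of its
#' `k` out-of-fold probabilities against `null_mean` (the 0.5 decision
#' boundary); the variant is retained iff p < `alpha`, i.e. its fold
#' predictions sit consistently and significantly away from the boundary.
#' Zero-variance rows, where the t statistic is undefined, are retained
#' iff their common value differs from `null_mean` (perfect fold agreement
#' is maximal consistency).
#'
#' @param fp a `fold_predictions` object (or a bare probability matrix).
#' @param alpha significance level (default 0.05).
#' @param null_mean boundary tested against (default 0.5).
#' @return character vector of retained keys, with the per-variant
#'   p-values attached as attribute `"p_values"` (NA for zero-variance
#'   rows).
#' @export
ttest_consistency_filter <- function(fp, alpha = 0.05, null_mean = 0.5) {
  probs <- if (inherits(fp, "fold_predictions")) fp$probs else as.matrix(fp)
  if (ncol(probs) < 2L) stop("need at least 2 fold probabilities per variant")
  keys <- rownames(probs) %||% as.character(seq_len(nrow(probs)))
  pv <- apply(probs, 1L, function(p) {
    if (stats::sd(p) == 0) return(NA_real_)
    stats::t.test(p, mu = null_mean)$p.value
  })
  zero_var <- is.na(pv)
  keep <- (!zero_var & pv < alpha) |
    (zero_var & probs[, 1L] != null_mean)
  out <- keys[keep]
  attr(out, "p_values") <- stats::setNames(pv, keys)
  out
}

#' Symmetric pseudo-label threshold pair
#'
#' The pair `(0.5 + delta, 0.5 - delta)` around the decision boundary.
#'
#' @param delta offset in `[0, 0.5]`.
#' @return list with `upper`, `lower`, `delta`.
#' @export
threshold_pair <- function(delta) {
  if (delta < 0 || delta > 0.5) stop("delta must lie in [0, 0.5]")
  list(upper = 0.5 + delta, lower = 0.5 - delta, delta = delta)
}

#' Assign pseudo-labels by mean fold probability
#'
#' Averages each retained variant's `k` fold probabilities; means strictly
#' above `pair$upper` become pseudo-positives, strictly below `pair$lower`
#' pseudo-negatives, and everything in between is discarded.
#'
#' @param fp a `fold_predictions` object (or probability matrix).
#' @param pair a [threshold_pair()] — e.g. `threshold_pair(0.4)` for the
#'   0.9/0.1 rule.
#' @param retained optional key vector (e.g. from
#'   [ttest_consistency_filter()]); defaults to all rows.
#' @return an object of class `pseudo_label_set`: data frame with `key`,
#'   `mean_prob`, `label`, plus attributes `n_discarded`, `discarded`
#'   (keys in the open band) and `pair`.
#' @export
assign_pseudo_labels <- function(fp, pair, retained = NULL) {
  probs <- if (inherits(fp, "fold_predictions")) fp$probs else as.matrix(fp)
  keys <- rownames(probs) %||% as.character(seq_len(nrow(probs)))
  if (!is.null(retained)) {
    probs <- probs[keys %in% retained, , drop = FALSE]
    keys <- keys[keys %in% retained]
  }
  m <- rowMeans(probs)
  lab <- ifelse(m > pair$upper, 1L, ifelse(m < pair$lower, 0L, NA_integer_))
  keep <- !is.na(lab)
  out <- data.frame(key = keys[keep], mean_prob = m[keep],
                    label = lab[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "discarded") <- keys[!keep]
  attr(out, "pair") <- pair
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}

#' Merge pseudo-labels with the labeled set and retrain
#'
#' Concatenates the labeled training set with the pseudo-labeled pool rows
#' (equal weight), partitions the merged set into `k` seeded folds, trains
#' one model per fold on the other `k - 1` folds, and returns the fold
#' model with the highest held-out-fold AUC.
#'
#' @param x,y labeled feature matrix and labels.
#' @param pseudo a `pseudo_label_set`; its keys must be rownames of
#'   `unlabeled_x` and disjoint from the labeled keys.
#' @param unlabeled_x pool matrix supplying the pseudo-labeled feature
#'   rows.
#' @param spec,k,seed,epochs,lr,batch_size as in
#'   [crossval_fold_predictions()].
#' @return the best `variant_cnn`, with `cv_auc` (its held-out AUC) and
#'   `cv_report` (per-fold AUCs) attached.
#' @export
augment_and_retrain <- function(x, y, pseudo, unlabeled_x,
                                spec = cnn_spec(ncol(x)), k = 5, seed = 1,
                                epochs = 50, lr = 0.001, batch_size = 32) {
  lab_keys <- rownames(x)
  if (nrow(pseudo) > 0L) {
    if (!is.null(lab_keys) && any(pseudo$key %in% lab_keys))
      stop("pseudo-labeled keys overlap the labeled training keys")
    missing <- setdiff(pseudo$key, rownames(unlabeled_x))
    if (length(missing))
      stop("pseudo keys absent from unlabeled_x: ",
           paste(head(missing, 5), collapse = ", "))
    xm <- rbind(x, unlabeled_x[pseudo$key, , drop = FALSE])
    ym <- c(y, pseudo$label)
  } else {
    xm <- x; ym <- y
  }
  with_seed(seed, {
    fold <- make_folds(nrow(xm), k)
    sub_seeds <- sample.int(.Machine$integer.max, k)
    fits <- vector("list", k)
    aucs <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      tr <- fold != j
      fits[[j]] <- cnn_fit(xm[tr, , drop = FALSE], ym[tr], spec = spec,
                           epochs = epochs, lr = lr, batch_size = batch_size,
                           seed = sub_seeds[j])
      ho <- !tr
      if (length(unique(ym[ho])) == 2L)
        aucs[j] <- roc_auc(predict(fits[[j]], xm[ho, , drop = FALSE]), ym[ho])
    }
    if (all(is.na(aucs)))
      stop("no fold had both classes held out; cannot select a model")
    best <- which.max(aucs)
    fit <- fits[[best]]
    fit$cv_auc <- aucs[best]
    fit$cv_report <- data.frame(fold = seq_len(k), auc = aucs)
    fit
  })
}

#' Grid search over symmetric pseudo-label thresholds
#'
#' For each `delta`, pseudo-labels the t-test-retained pool at the pair
#' `(0.5 + delta, 0.5 - delta)`, retrains on the augmented set, and
#' evaluates the retrained model's AUC on the held-out test set. Fold
#' probabilities and the consistency filter are computed once and shared
#' across the grid. Ties in AUC are broken toward the larger delta
#' (fewer, higher-confidence pseudo-labels).
#'
#' @param x,y labeled training matrix and labels.
#' @param unlabeled_x unlabeled pool matrix.
#' @param test_x,test_y independent test set (disjoint from both).
#' @param spec,k,seed,epochs,lr,batch_size as in
#'   [crossval_fold_predictions()].
#' @param deltas grid of threshold offsets (default 0, 0.1, 0.2, 0.3,
#'   0.4).
#' @param alpha t-test significance level (default 0.05).
#' @return list with `best_pair` (a [threshold_pair()]), `best_model`,
#'   `report` (data frame: delta, upper, lower, n_pos, n_neg, n_discarded,
#'   auc), `fold_preds`, `retained`, and `pseudo` (the pseudo-label set of
#'   the winning delta).
#' @export
threshold_grid_search <- function(x, y, unlabeled_x, test_x, test_y,
                                  spec = cnn_spec(ncol(x)),
                                  deltas = c(0, 0.1, 0.2, 0.3, 0.4),
                                  alpha = 0.05, k = 5, seed = 1,
                                  epochs = 50, lr = 0.001, batch_size = 32) {
  if (length(deltas) == 0L) stop("empty threshold grid")
  with_seed(seed, {
    fp_seed <- sample.int(.Machine$integer.max, 1)
    retrain_seeds <- sample.int(.Machine$integer.max, length(deltas))
    fp <- crossval_fold_predictions(x, y, unlabeled_x, spec = spec, k = k,
                                    seed = fp_seed, epochs = epochs, lr = lr,
                                    batch_size = batch_size)
    retained <- ttest_consistency_filter(fp, alpha = alpha)
    rows <- vector("list", length(deltas))
    models <- vector("list", length(deltas))
    pseudos <- vector("list", length(deltas))
    for (i in seq_along(deltas)) {
      pair <- threshold_pair(deltas[i])
      ps <- assign_pseudo_labels(fp, pair, retained = retained)
      fit <- augment_and_retrain(x, y, ps, unlabeled_x, spec = spec, k = k,
                                 seed = retrain_seeds[i], epochs = epochs,
                                 lr = lr, batch_size = batch_size)
      auc <- roc_auc(predict(fit, test_x), test_y)
      rows[[i]] <- data.frame(delta = deltas[i], upper = pair$upper,
                              lower = pair$lower,
                              n_pos = sum(ps$label == 1L),
                              n_neg = sum(ps$label == 0L),
                              n_discarded = attr(ps, "n_discarded"),
                              auc = auc)
      models[[i]] <- fit
      pseudos[[i]] <- ps
    }
    report <- do.call(rbind, rows)
    # argmax AUC; ties toward larger delta
    best <- order(-report$auc, -report$delta)[1]
    list(best_pair = threshold_pair(deltas[best]),
         best_model = models[[best]],
         report = report,
         fold_preds = fp,
         retained = retained,
         pseudo = pseudos[[best]])
  })
}
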