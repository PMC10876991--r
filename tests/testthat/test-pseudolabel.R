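fit_args <- list(spec = small_spec(), epochs = 2)

small_pipeline_data <- function(seed = 1, n_unlabeled = 30) {
  cfg <- small_sim(n_pos = 25, n_neg = 25, seed = seed,
                   n_unlabeled = n_unlabeled)
  list(lab = simulate_annotation_dataset(cfg),
       pool = simulate_unlabeled_pool(cfg))
}

test_that("out-of-fold predictions form a seeded k-column partition", {
  d <- small_pipeline_data()
  fp <- crossval_fold_predictions(d$lab$x, d$lab$labels, d$pool$x,
                                  spec = small_spec(), k = 5, seed = 7,
                                  epochs = 2)
  expect_s3_class(fp, "fold_predictions")
  expect_equal(dim(fp$probs), c(30L, 5L))
  expect_true(all(fp$probs >= 0 & fp$probs <= 1))
  expect_equal(rownames(fp$probs), rownames(d$pool$x))
  # each labeled record sits in exactly one fold; folds are exhaustive
  expect_equal(length(fp$fold), nrow(d$lab$x))
  expect_setequal(unique(fp$fold), 1:5)
  fp2 <- crossval_fold_predictions(d$lab$x, d$lab$labels, d$pool$x,
                                   spec = small_spec(), k = 5, seed = 7,
                                   epochs = 2)
  expect_identical(fp$probs, fp2$probs)
  expect_error(crossval_fold_predictions(d$lab$x, d$lab$labels, d$pool$x,
                                         k = 51, spec = small_spec()),
               "exceeds")
})

test_that("t-test consistency filter matches hand-computed t statistics", {
  probs <- rbind(
    confident = c(0.90, 0.92, 0.91, 0.90, 0.93),
    boundary  = c(0.45, 0.55, 0.50, 0.60, 0.40),
    constant9 = c(0.90, 0.90, 0.90, 0.90, 0.90),
    constant5 = c(0.50, 0.50, 0.50, 0.50, 0.50))
  kept <- ttest_consistency_filter(probs)
  # hand oracle: t = (mean - 0.5) / (sd / sqrt(5)), p = 2*pt(-|t|, 4)
  p_hand <- function(v) {
    t <- (mean(v) - 0.5) / (sd(v) / sqrt(5))
    2 * pt(-abs(t), df = 4)
  }
  expect_lt(p_hand(probs["confident", ]), 0.05)
  expect_equal(p_hand(probs["boundary", ]), 1) # mean exactly 0.5 -> t = 0
  expect_setequal(kept, c("confident", "constant9"))
  pv <- attr(kept, "p_values")
  expect_equal(unname(pv["confident"]), p_hand(probs["confident", ]),
               tolerance = 1e-12)
  expect_true(is.na(pv["constant9"])) # variance undefined; retained by rule
  expect_error(ttest_consistency_filter(probs[, 1, drop = FALSE]),
               "at least 2")
})

test_that("pseudo-label assignment obeys the threshold pair and conserves counts", {
  probs <- matrix(c(0.95, 0.05, 0.50, 0.91, 0.89, 0.11), 6, 5,
                  dimnames = list(paste0("v", 1:6), NULL))
  ps <- assign_pseudo_labels(probs, threshold_pair(0.4))
  expect_s3_class(ps, "pseudo_label_set")
  expect_equal(ps$label[ps$key == "v1"], 1L) # mean 0.95 > 0.9
  expect_equal(ps$label[ps$key == "v2"], 0L) # mean 0.05 < 0.1
  expect_false("v3" %in% ps$key)             # boundary mean discarded
  expect_false("v5" %in% ps$key)             # 0.89 inside the band
  expect_equal(nrow(ps) + attr(ps, "n_discarded"), 6)
  # restriction to a retained subset
  ps2 <- assign_pseudo_labels(probs, threshold_pair(0.4),
                              retained = c("v1", "v3"))
  expect_equal(ps2$key, "v1")
  expect_equal(nrow(ps2) + attr(ps2, "n_discarded"), 2)
  expect_error(threshold_pair(0.6), "delta")
})

test_that("stricter thresholds never label more variants", {
  set.seed(13)
  probs <- matrix(runif(200 * 5), 200, 5)
  n_labeled <- sapply(c(0, 0.1, 0.2, 0.3, 0.4), function(d)
    nrow(assign_pseudo_labels(probs, threshold_pair(d))))
  expect_true(all(diff(n_labeled) <= 0))
  # delta 0 labels every variant whose mean is off the boundary
  expect_equal(n_labeled[1], sum(rowMeans(probs) != 0.5))
})

test_that("retraining merges disjoint sets and guards against leakage", {
  d <- small_pipeline_data(seed = 4)
  fp <- crossval_fold_predictions(d$lab$x, d$lab$labels, d$pool$x,
                                  spec = small_spec(), k = 5, seed = 3,
                                  epochs = 2)
  ps <- assign_pseudo_labels(fp, threshold_pair(0)) # label all off-boundary rows
  expect_gt(nrow(ps), 0)
  fit <- augment_and_retrain(d$lab$x, d$lab$labels, ps, d$pool$x,
                             spec = small_spec(), k = 5, seed = 9, epochs = 2)
  expect_s3_class(fit, "variant_cnn")
  expect_equal(nrow(fit$cv_report), 5)
  expect_equal(fit$cv_auc, max(fit$cv_report$auc, na.rm = TRUE))
  # best fold model trains on the merged set minus one held-out fold
  merged <- nrow(d$lab$x) + nrow(ps)
  expect_gte(fit$provenance$n, merged - ceiling(merged / 5))
  expect_lte(fit$provenance$n, merged - floor(merged / 5))
  # overlap between pseudo and labeled keys is an error
  clash <- ps
  clash$key[1] <- rownames(d$lab$x)[1]
  expect_error(augment_and_retrain(d$lab$x, d$lab$labels, clash, d$pool$x,
                                   spec = small_spec()), "overlap")
  ghost <- ps; ghost$key[1] <- "chrX:1:A:G"
  expect_error(augment_and_retrain(d$lab$x, d$lab$labels, ghost, d$pool$x,
                                   spec = small_spec()), "absent")
})

test_that("an empty pseudo set reduces retraining to plain fivefold training", {
  d <- small_pipeline_data(seed = 6)
  plain <- augment_and_retrain(d$lab$x, d$lab$labels,
                               pseudovar:::empty_pseudo_set(), d$pool$x,
                               spec = small_spec(), k = 5, seed = 21,
                               epochs = 2)
  expect_equal(plain$provenance$n, 40) # 4/5 of the 50 labeled records
  again <- augment_and_retrain(d$lab$x, d$lab$labels,
                               pseudovar:::empty_pseudo_set(), d$pool$x,
                               spec = small_spec(), k = 5, seed = 21,
                               epochs = 2)
  expect_identical(plain$weights, again$weights)
})

test_that("threshold grid search reports every delta and returns the argmax", {
  d <- small_pipeline_data(seed = 5, n_unlabeled = 40)
  te <- simulate_annotation_dataset(small_sim(n_pos = 15, n_neg = 15,
                                              seed = 99))
  gs <- threshold_grid_search(d$lab$x, d$lab$labels, d$pool$x,
                              te$x, te$labels, spec = small_spec(),
                              deltas = c(0, 0.2, 0.4), k = 5, seed = 31,
                              epochs = 2)
  expect_equal(nrow(gs$report), 3)
  expect_named(gs$report, c("delta", "upper", "lower", "n_pos", "n_neg",
                            "n_discarded", "auc"))
  best_auc <- gs$report$auc[gs$report$delta == gs$best_pair$delta]
  expect_equal(best_auc, max(gs$report$auc))
  # conservation at every stage of the grid
  n_pool <- nrow(d$pool$x)
  expect_true(all(gs$report$n_pos + gs$report$n_neg + gs$report$n_discarded ==
                    length(gs$retained)))
  expect_lte(length(gs$retained), n_pool)
  expect_error(threshold_grid_search(d$lab$x, d$lab$labels, d$pool$x,
                                     te$x, te$labels, spec = small_spec(),
                                     deltas = numeric(0)), "empty")
})
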