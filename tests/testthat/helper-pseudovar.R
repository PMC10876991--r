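# Shared fixtures: small architectures and generators sized for fast tests.

# 16-feature architecture: conv1 (k5, 4) -> 12x4; pool2 -> 6x4;
# conv2 (k3, 8) -> 4x8; pool2 -> 2x8; flatten 16; dense 8; out 1.
small_spec <- function() {
  cnn_spec(input_len = 16, conv1_kernel = 5, conv1_filters = 4, pool1 = 2,
           conv2_kernel = 3, conv2_filters = 8, pool2 = 2, dense_units = 8)
}

# minimal architecture for hand-computed forward passes:
# input 2 -> conv1 (k2, 2 maps) -> 1x2 -> pool1(1) -> conv2 (k1, 1 map)
# -> 1x1 -> pool2(1) -> flatten 1 -> dense 2 -> out
toy_spec <- function() {
  cnn_spec(input_len = 2, conv1_kernel = 2, conv1_filters = 2, pool1 = 1,
           conv2_kernel = 1, conv2_filters = 1, pool2 = 1, dense_units = 2)
}

small_sim <- function(n_pos = 40, n_neg = 40, effect = 3, seed = 1,
                      n_unlabeled = 0, prevalence = 0.5) {
  sim_config(n_pos, n_neg, n_features = 16, n_informative = 4,
             effect = effect, n_unlabeled = n_unlabeled,
             unlabeled_prevalence = prevalence, seed = seed)
}

# independent brute-force ROC AUC: all positive-negative pairs, ties 1/2
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# independent average-precision oracle: exhaustive sweep over unique scores
ap_bruteforce <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  ap <- 0; r_prev <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / npos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}
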