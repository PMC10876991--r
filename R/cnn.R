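# Supervised network: initialization, fitting, scoring, threshold choice.

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Glorot-uniform weights drawn from the current RNG stream.
cnn_init <- function(spec) {
  sh <- trace_shapes(spec)
  c1k <- spec$conv1_kernel; c1n <- spec$conv1_filters
  c2k <- spec$conv2_kernel; c2n <- spec$conv2_filters
  flat <- sh$flatten; D <- spec$dense_units
  list(
    W1 = glorot(c1k, c1n, c1k, c1k * c1n),
    b1 = numeric(c1n),
    # rows ordered (kernel offset j, input channel k) = (j-1)*c1n + k
    W2 = glorot(c2k * c1n, c2n, c2k * c1n, c2k * c2n),
    b2 = numeric(c2n),
    W3 = glorot(flat, D, flat, D),
    b3 = numeric(D),
    W4 = matrix(runif(D, -sqrt(6 / (D + 1)), sqrt(6 / (D + 1))), D, 1)[, 1],
    b4 = 0
  )
}

check_weights <- function(spec, weights) {
  sh <- trace_shapes(spec)
  expect <- list(W1 = c(spec$conv1_kernel, spec$conv1_filters),
                 b1 = spec$conv1_filters,
                 W2 = c(spec$conv2_kernel * spec$conv1_filters, spec$conv2_filters),
                 b2 = spec$conv2_filters,
                 W3 = c(sh$flatten, spec$dense_units),
                 b3 = spec$dense_units,
                 W4 = spec$dense_units,
                 b4 = 1L)
  for (nm in names(expect)) {
    w <- weights[[nm]]
    if (is.null(w)) stop("missing weight tensor ", nm)
    got <- if (is.matrix(w)) dim(w) else length(w)
    if (!identical(as.integer(got), as.integer(expect[[nm]])))
      stop("weight tensor ", nm, " has shape (", paste(got, collapse = ","),
           "), expected (", paste(expect[[nm]], collapse = ","), ")")
  }
  invisible(TRUE)
}

#' Construct a network object from explicit weights
#'
#' Low-level constructor, mainly useful for testing a forward pass against
#' hand-set weights. Weight shapes are validated against [trace_shapes()].
#'
#' @param spec a [cnn_spec()].
#' @param weights named list `W1, b1, W2, b2, W3, b3, W4, b4`; `W2` rows are
#'   ordered (kernel offset, input channel), flatten order is position-major
#'   over output channels.
#' @param history optional per-epoch training loss.
#' @param seed,provenance optional training provenance.
#' @return an object of class `variant_cnn`.
#' @export
cnn_model <- function(spec, weights, history = numeric(0), seed = NA_integer_,
                      provenance = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  check_weights(spec, weights)
  structure(list(spec = spec, weights = weights, history = history,
                 seed = seed, provenance = provenance),
            class = "variant_cnn")
}

#' Fit the 1-D convolutional variant classifier
#'
#' Trains the network of [cnn_spec()] on a variants-by-features matrix with
#' binary labels, minimizing binary cross-entropy with minibatch Adam.
#' Weight initialization (Glorot uniform), epoch shuffling and dropout masks
#' all derive from `seed`, so the same seed and data give bitwise-identical
#' weights.
#'
#' @param x numeric matrix, variants in rows, features in columns; column
#'   count must equal `spec$input_len`.
#' @param y binary (0/1) label vector, one per row; both classes required.
#' @param spec a [cnn_spec()]; defaults to the standard architecture sized
#'   to `ncol(x)`.
#' @param epochs number of training epochs (default 50).
#' @param lr Adam learning rate (default 0.001; beta1 0.9, beta2 0.999,
#'   epsilon 1e-8).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed; `NULL` uses (and advances) the global RNG.
#' @return a `variant_cnn` object with elements `spec`, `weights`,
#'   `history` (per-epoch mean loss), `seed`, `provenance`.
#' @export
#' @examples
#' sim <- simulate_annotation_dataset(
#'   sim_config(40, 40, n_features = 16, n_informative = 4, effect = 3, seed = 1))
#' fit <- cnn_fit(sim$x, sim$labels,
#'                spec = cnn_spec(16, conv1_filters = 4, conv2_filters = 8,
#'                                dense_units = 8),
#'                epochs = 5, seed = 1)
#' head(predict(fit, sim$x))
cnn_fit <- function(x, y, spec = cnn_spec(ncol(x)), epochs = 50, lr = 0.001,
                    batch_size = 32, seed = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) == 0L) stop("empty dataset")
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (ncol(x) != spec$input_len)
    stop("matrix has ", ncol(x), " columns but spec$input_len is ", spec$input_len)
  if (epochs < 1L) stop("epochs must be >= 1")
  with_seed(seed, {
    weights <- cnn_init(spec)
    perms <- vapply(seq_len(epochs), function(e) sample.int(nrow(x)),
                    integer(nrow(x)))
    out <- cnn_train_cpp(weights, unclass(spec), x, y, perms,
                         lr = lr, batch_size = as.integer(batch_size),
                         dropout_p = spec$dropout,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         clamp_eps = 1e-7)
    prov <- list(n = nrow(x), epochs = epochs, lr = lr,
                 batch_size = batch_size)
    w <- out$params
    for (nm in c("b1", "b2", "b3", "W4")) w[[nm]] <- as.numeric(w[[nm]])
    w$b4 <- as.numeric(w$b4)
    cnn_model(spec, w,
              history = as.numeric(out$history),
              seed = seed %||% NA_integer_, provenance = prov)
  })
}

#' Score variants with a fitted network
#'
#' The functional-significance score of a variant is the fitted network's
#' predicted probability that it belongs to the positive (regulatory)
#' class: a sigmoid output in `[0, 1]`. Dropout is disabled at inference,
#' and scores are invariant to row order and batching.
#'
#' @param object a fitted `variant_cnn`.
#' @param newdata numeric matrix with `spec$input_len` columns.
#' @param type `"response"` (probabilities) or `"class"` (0/1 at
#'   `threshold`).
#' @param threshold classification cut for `type = "class"`; the rule is
#'   strict: `score > threshold`.
#' @param ... unused.
#' @return numeric vector of scores (named by rownames of `newdata`), or a
#'   0/1 integer vector for `type = "class"`.
#' @export
predict.variant_cnn <- function(object, newdata, type = c("response", "class"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$input_len)
    stop("newdata has ", ncol(newdata), " columns but model input_len is ",
         object$spec$input_len)
  p <- as.numeric(cnn_score_cpp(object$weights, unclass(object$spec), newdata))
  names(p) <- rownames(newdata)
  if (type == "class") return(as.integer(p > threshold))
  p
}

#' @export
print.variant_cnn <- function(x, ...) {
  cat("Fitted 1-D convolutional variant classifier\n")
  print(x$spec)
  if (length(x$history))
    cat(sprintf("  trained %d epochs; final mean BCE loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}

#' Choose a classification threshold by Youden's J
#'
#' Maximizes sensitivity + specificity - 1 over cut points placed midway
#' between consecutive distinct observed scores (classification rule is
#' `score > threshold`). If all scores are identical the fallback
#' threshold is 0.5.
#'
#' @param scores numeric score vector.
#' @param labels binary labels, both classes present.
#' @return scalar threshold.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1L) return(0.5)
  cuts <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  j <- vapply(cuts, function(th) {
    pred <- scores > th
    sum(pred & labels == 1L) / npos + sum(!pred & labels == 0L) / nneg - 1
  }, numeric(1))
  cuts[which.max(j)]
}
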