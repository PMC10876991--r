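#' Architecture of the 1-D convolutional variant classifier
#'
#' Defines the eight-layer network used throughout the package: two
#' valid-mode (no padding, stride 1) 1-D convolutions with GELU activation,
#' each followed by non-overlapping max-pooling, then flatten, a GELU dense
#' layer, dropout, and a single sigmoid output unit. With the defaults
#' (input length 141) the layer output shapes are (137, 32), (68, 32),
#' (64, 64), (32, 64), 2048, 16 and 1.
#'
#' @param input_len number of input features per variant (default 141).
#' @param conv1_kernel,conv1_filters kernel size and number of kernels of the
#'   first convolution.
#' @param pool1,pool2 max-pooling window sizes (windows are non-overlapping;
#'   a trailing remainder shorter than the window is dropped).
#' @param conv2_kernel,conv2_filters kernel size and number of kernels of the
#'   second convolution (applied across all first-stage feature maps).
#' @param dense_units units in the fully connected layer.
#' @param dropout dropout probability applied after the dense layer during
#'   training only.
#' @return an object of class `cnn_spec`.
#' @seealso [trace_shapes()], [cnn_fit()]
#' @export
#' @examples
#' trace_shapes(cnn_spec())
cnn_spec <- function(input_len = 141,
                     conv1_kernel = 5, conv1_filters = 32, pool1 = 2,
                     conv2_kernel = 5, conv2_filters = 64, pool2 = 2,
                     dense_units = 16, dropout = 0.1) {
  spec <- list(input_len = as.integer(input_len),
               conv1_kernel = as.integer(conv1_kernel),
               conv1_filters = as.integer(conv1_filters),
               pool1 = as.integer(pool1),
               conv2_kernel = as.integer(conv2_kernel),
               conv2_filters = as.integer(conv2_filters),
               pool2 = as.integer(pool2),
               dense_units = as.integer(dense_units),
               dropout = as.numeric(dropout))
  sizes <- unlist(spec[1:8])
  if (any(sizes < 1L)) stop("all architecture sizes must be positive")
  if (spec$dropout < 0 || spec$dropout >= 1) stop("dropout must be in [0, 1)")
  class(spec) <- "cnn_spec"
  trace_shapes(spec) # validates feasibility
  spec
}

#' Trace per-layer output shapes of a network specification
#'
#' Computes the output shape of every layer: convolution length is
#' `len - kernel + 1` (valid mode, stride 1), pooling length is
#' `floor(len / pool)`, flatten is `len * maps`.
#'
#' @param spec a [cnn_spec()].
#' @return a named list of integer shapes: `conv1`, `pool1`, `conv2`,
#'   `pool2` as `(length, maps)` pairs, `flatten`, `dense`, `output` as
#'   scalars.
#' @export
trace_shapes <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  l1 <- spec$input_len - spec$conv1_kernel + 1L
  if (l1 < 1L) stop("architecture infeasible: conv1 output length < 1")
  p1 <- l1 %/% spec$pool1
  if (p1 < 1L) stop("architecture infeasible: pool1 output length < 1")
  l2 <- p1 - spec$conv2_kernel + 1L
  if (l2 < 1L) stop("architecture infeasible: conv2 output length < 1")
  p2 <- l2 %/% spec$pool2
  if (p2 < 1L) stop("architecture infeasible: pool2 output length < 1")
  list(conv1 = c(l1, spec$conv1_filters),
       pool1 = c(p1, spec$conv1_filters),
       conv2 = c(l2, spec$conv2_filters),
       pool2 = c(p2, spec$conv2_filters),
       flatten = p2 * spec$conv2_filters,
       dense = spec$dense_units,
       output = 1L)
}

#' @export
print.cnn_spec <- function(x, ...) {
  sh <- trace_shapes(x)
  cat("1-D CNN specification (input length ", x$input_len, ")\n", sep = "")
  cat(sprintf("  conv1 k=%d -> (%d, %d)  pool%d -> (%d, %d)\n",
              x$conv1_kernel, sh$conv1[1], sh$conv1[2], x$pool1, sh$pool1[1], sh$pool1[2]))
  cat(sprintf("  conv2 k=%d -> (%d, %d)  pool%d -> (%d, %d)\n",
              x$conv2_kernel, sh$conv2[1], sh$conv2[2], x$pool2, sh$pool2[1], sh$pool2[2]))
  cat(sprintf("  flatten %d -> dense %d (dropout %.2f) -> sigmoid 1\n",
              sh$flatten, sh$dense, x$dropout))
  invisible(x)
}

#' Gaussian Error Linear Unit
#'
#' Exact Gaussian-CDF form `x * pnorm(x)`, applied elementwise.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

#' Binary cross-entropy loss
#'
#' Mean negative Bernoulli log-likelihood
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))` with predicted probabilities
#' clamped to `[eps, 1 - eps]` so the loss stays finite.
#'
#' @param y binary (0/1) label vector.
#' @param p predicted probability vector of the same length.
#' @param eps clamp bound, default `1e-7`.
#' @return scalar loss value.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) stop("y and p must have the same length")
  if (length(y) == 0L) stop("empty input")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}
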