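# Feature selection: name-based subsetting, mutual-information and
# random-forest importance ranking, top-k selection.

new_feature_subset <- function(name, score, index, method) {
  ord <- order(-score, index)
  out <- data.frame(name = name[ord], score = score[ord], index = index[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("feature_subset", "data.frame")
  out
}

#' Subset a feature matrix by column name
#'
#' Keeps the columns whose names satisfy a predicate: a function over
#' names, a single character pattern (regular expression), or a character
#' vector of exact names. Row order and relative column order are
#' preserved.
#'
#' @param x numeric matrix with unique column names.
#' @param predicate function, pattern, or name vector.
#' @return the column-filtered matrix.
#' @export
subset_features_by_name <- function(x, predicate) {
  nms <- colnames(x)
  if (is.null(nms)) stop("x must have column names")
  keep <- if (is.function(predicate)) {
    vapply(nms, predicate, logical(1))
  } else if (is.character(predicate) && length(predicate) == 1L) {
    grepl(predicate, nms)
  } else if (is.character(predicate)) {
    nms %in% predicate
  } else stop("predicate must be a function or character")
  if (!any(keep)) stop("predicate matched zero feature names")
  x[, keep, drop = FALSE]
}

digamma_safe <- function(x) digamma(pmax(x, 1))

# Nearest-neighbour mutual information between a continuous feature and a
# discrete label (Ross 2014): I = psi(N) - <psi(N_y)> + <psi(k_i)> - <psi(m_i)>
# where the radius is the distance to the k-th same-class neighbour and m_i
# counts all points strictly inside it, self included.
mi_continuous_discrete <- function(x, y, k = 3L) {
  n <- length(x)
  classes <- unique(y)
  n_by <- vapply(classes, function(c) sum(y == c), integer(1))
  names(n_by) <- as.character(classes)
  psi_k <- numeric(n); psi_m <- numeric(n); use <- logical(n)
  for (i in seq_len(n)) {
    nc <- n_by[[as.character(y[i])]]
    if (nc < 2L) next
    ki <- min(k, nc - 1L)
    d_same <- sort(abs(x[y == y[i]] - x[i]))[-1]   # drop self
    r <- d_same[ki]
    m <- sum(abs(x - x[i]) < r)                    # strictly inside, self included
    use[i] <- TRUE
    psi_k[i] <- digamma(ki)
    psi_m[i] <- digamma_safe(m)
  }
  if (!any(use)) return(0)
  val <- digamma(n) - mean(digamma(n_by[as.character(y[use])])) +
    mean(psi_k[use]) - mean(psi_m[use])
  max(0, val)
}

# Plug-in MI (nats) for a discrete feature vs discrete label.
mi_discrete_discrete <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual-information feature scores
#'
#' Estimates the mutual information (in nats) between each feature column
#' and the binary label. Features with few distinct values are scored with
#' the plug-in discrete estimator; continuous features use a
#' nearest-neighbour estimator with `k` neighbours, after a tiny seeded
#' jitter that breaks ties. Scores are nonnegative; a constant feature
#' scores 0.
#'
#' @param x numeric matrix with column names.
#' @param labels binary labels, both classes present.
#' @param k neighbour count for the continuous estimator (default 3).
#' @param discrete_max a feature with at most this many distinct values is
#'   treated as discrete (default 5).
#' @param seed seed for the tie-breaking jitter.
#' @return a `feature_subset` data frame (name, score, index), sorted by
#'   descending score with ties broken by ascending column index.
#' @export
mutual_information_scores <- function(x, labels, k = 3L, discrete_max = 5L,
                                      seed = 0L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  scores <- with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      nu <- length(unique(v))
      if (nu <= 1L) return(0)
      if (nu <= discrete_max) return(mi_discrete_discrete(v, labels))
      v <- v + rnorm(length(v)) * 1e-10 * max(1, stats::sd(v))
      mi_continuous_discrete(v, labels, k = as.integer(k))
    }, numeric(1))
  })
  new_feature_subset(colnames(x), scores, seq_len(ncol(x)),
                     "mutual_information")
}

#' Random-forest impurity importance scores
#'
#' Fits a classification random forest (\pkg{ranger}, Gini impurity,
#' `sqrt(p)` candidate features per split) and returns the per-feature
#' impurity importance normalized to sum to 1.
#'
#' @param x numeric matrix with column names.
#' @param labels binary labels, both classes present.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed (forest growth is deterministic given it).
#' @return a `feature_subset` data frame (name, score, index).
#' @export
rf_importance_scores <- function(x, labels, n_trees = 500, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  df <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = factor(labels), num.trees = n_trees,
                        importance = "impurity",
                        mtry = max(1L, floor(sqrt(ncol(x)))),
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance[colnames(x)]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  new_feature_subset(colnames(x), as.numeric(imp), seq_len(ncol(x)),
                     "forest_importance")
}

#' Keep the top-k ranked features
#'
#' @param scores a `feature_subset` from [mutual_information_scores()] or
#'   [rf_importance_scores()].
#' @param k how many features to keep; `1 <= k <= nrow(scores)`. Ties at
#'   the boundary are resolved by the stable ordering already present
#'   (ascending original column index).
#' @return a `feature_subset` with `k` rows.
#' @export
select_top_k <- function(scores, k) {
  stopifnot(inherits(scores, "feature_subset"))
  if (k < 1L || k > nrow(scores)) stop("k must be in [1, ", nrow(scores), "]")
  out <- scores[seq_len(k), , drop = FALSE]
  attr(out, "method") <- attr(scores, "method")
  class(out) <- class(scores)
  out
}

#' @export
print.feature_subset <- function(x, n = 10L, ...) {
  cat("Feature ranking (", attr(x, "method"), "), ", nrow(x), " features\n",
      sep = "")
  print.data.frame(head(x, n))
  if (nrow(x) > n) cat("  ... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
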