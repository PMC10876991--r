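# Synthetic-data generators: every input the pipeline needs, with planted
# ground truth, so the full semi-supervised workflow is testable offline.

#' Configuration for the synthetic variant-annotation generator
#'
#' Describes a two-class generative model for variant feature matrices:
#' class-conditional Gaussians in which `n_informative` columns have mean
#' `effect` in the positive class and 0 in the negative class, and all
#' remaining columns are pure noise (mean 0) in both classes; every column
#' has standard deviation `noise_sd`. The same model generates an unlabeled
#' pool whose true class is drawn Bernoulli(`unlabeled_prevalence`) and
#' returned out-of-band, so pseudo-label precision and recall can be audited
#' without leaking truth into the pipeline.
#'
#' @param n_pos,n_neg labeled positives / negatives to generate.
#' @param n_features total feature columns (default 141, the standard input
#'   length of [cnn_spec()]).
#' @param n_informative number of label-informative columns (the first
#'   `n_informative` columns); must not exceed `n_features`.
#' @param effect mean shift (in feature units) of informative columns in the
#'   positive class.
#' @param noise_sd per-column standard deviation (default 1).
#' @param n_unlabeled size of the unlabeled pool.
#' @param unlabeled_prevalence fraction of hidden positives in the pool.
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_pos, n_neg, n_features = 141, n_informative = 10,
                       effect = 1, noise_sd = 1, n_unlabeled = 0,
                       unlabeled_prevalence = 0.5, seed = 1) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              effect = as.numeric(effect), noise_sd = as.numeric(noise_sd),
              n_unlabeled = as.integer(n_unlabeled),
              unlabeled_prevalence = as.numeric(unlabeled_prevalence),
              seed = as.integer(seed))
  if (any(c(cfg$n_pos, cfg$n_neg, cfg$n_features, cfg$n_unlabeled) < 0L))
    stop("counts must be >= 0")
  if (cfg$n_informative > cfg$n_features)
    stop("n_informative must not exceed n_features")
  if (cfg$n_informative < 0L) stop("n_informative must be >= 0")
  if (cfg$unlabeled_prevalence < 0 || cfg$unlabeled_prevalence > 1)
    stop("unlabeled_prevalence must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  class(cfg) <- "sim_config"
  cfg
}

feature_names_for <- function(p) sprintf("f%04d", seq_len(p))

# Deterministic synthetic variant keys "chrC:POS:REF:ALT"
synth_keys <- function(n, prefix_pos = 0L) {
  if (n == 0L) return(character(0))
  i <- seq_len(n)
  chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
  pos <- prefix_pos + i * 1000L
  bases <- c("A", "C", "G", "T")
  ref <- bases[((i - 1L) %% 4L) + 1L]
  alt <- bases[(i %% 4L) + 1L]
  paste(chrom, pos, ref, alt, sep = ":")
}

draw_class_matrix <- function(n, labels, cfg) {
  x <- matrix(rnorm(n * cfg$n_features, sd = cfg$noise_sd), n, cfg$n_features)
  if (cfg$n_informative > 0L && any(labels == 1L))
    x[labels == 1L, seq_len(cfg$n_informative)] <-
      x[labels == 1L, seq_len(cfg$n_informative), drop = FALSE] + cfg$effect
  colnames(x) <- feature_names_for(cfg$n_features)
  x
}

#' Simulate a labeled variant annotation matrix
#'
#' Draws `n_pos + n_neg` rows from the class-conditional Gaussian model of
#' [sim_config()]. Rownames are synthetic variant keys; the names of the
#' planted informative columns are attached as attribute `"informative"`.
#'
#' @param config a [sim_config()].
#' @return list with `x` (numeric matrix), `labels` (0/1 integer vector) and
#'   `keys` (rownames of `x`).
#' @export
simulate_annotation_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    labels <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
    x <- draw_class_matrix(n, labels, config)
    rownames(x) <- synth_keys(n)
    attr(x, "informative") <-
      feature_names_for(config$n_features)[seq_len(config$n_informative)]
    list(x = x, labels = labels, keys = rownames(x))
  })
}

#' Simulate an unlabeled variant pool with hidden truth
#'
#' Draws `n_unlabeled` rows from the same two generative distributions as
#' [simulate_annotation_dataset()], with the true class of each row drawn
#' Bernoulli(`unlabeled_prevalence`). The hidden labels are returned
#' separately and never written into the matrix.
#'
#' @param config a [sim_config()].
#' @return list with `x` (matrix, rownames disjoint from the labeled keys)
#'   and `hidden_labels` (0/1 vector, for auditing only).
#' @export
simulate_unlabeled_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_unlabeled
    hidden <- if (n > 0L) rbinom(n, 1L, config$unlabeled_prevalence) else integer(0)
    x <- draw_class_matrix(n, hidden, config)
    rownames(x) <- synth_keys(n, prefix_pos = 100000000L)
    list(x = x, hidden_labels = as.integer(hidden))
  })
}

#' Simulate eQTL-style association tables
#'
#' Emulates a pair of association tables: a significant table (small
#' P-values) that is a strict subset of a full table, in which exactly
#' `n_pass` of the additional rows are constructed to pass the negative
#' filter of [select_negatives()] (P > 0.1 and AF > 0.3) and every other
#' row is constructed to fail it.
#'
#' @param config a [sim_config()] (supplies the default sizes and seed).
#' @param n_sig rows in the significant table (default `config$n_pos`).
#' @param n_full rows in the full table (default `n_sig + config$n_neg`);
#'   must be at least `n_sig`.
#' @param n_pass how many rows of the full table pass the negative filter
#'   (default `config$n_neg`); must not exceed `n_full - n_sig`.
#' @param seed seed (default derived from `config$seed`).
#' @return list of two data frames, `significant` and `full`, with columns
#'   `key`, `p_value`, `af`.
#' @export
simulate_eqtl_tables <- function(config, n_sig = config$n_pos,
                                 n_full = n_sig + config$n_neg,
                                 n_pass = config$n_neg,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_full < n_sig) stop("n_full must be >= n_sig")
  if (n_pass > n_full - n_sig)
    stop("requested filter-passing rows exceed the non-significant rows available")
  with_seed(seed, {
    keys <- synth_keys(n_full, prefix_pos = 200000000L)
    n_extra <- n_full - n_sig
    # significant rows: P in (0, 0.05] -- always fail the P > 0.1 filter
    p_sig <- runif(n_sig, 0, 0.05)
    af_sig <- runif(n_sig, 0.01, 0.99)
    # planted passing rows: strictly P > 0.1 and AF > 0.3
    p_pass <- 0.1 + 0.9 * runif(n_pass, .Machine$double.eps, 1)
    af_pass <- 0.3 + 0.69 * runif(n_pass, .Machine$double.eps, 1)
    # remaining rows alternate between failing on P and failing on AF
    n_fail <- n_extra - n_pass
    fail_on_p <- seq_len(n_fail) %% 2L == 0L
    p_fail <- ifelse(fail_on_p, runif(n_fail, 0, 0.1),
                     0.1 + 0.9 * runif(n_fail))
    af_fail <- ifelse(fail_on_p, runif(n_fail, 0.01, 0.99),
                      runif(n_fail, 0.01, 0.3))
    full <- data.frame(
      key = keys,
      p_value = c(p_sig, p_pass, p_fail),
      af = c(af_sig, af_pass, af_fail),
      stringsAsFactors = FALSE)
    significant <- full[seq_len(n_sig), , drop = FALSE]
    list(significant = significant, full = full)
  })
}

#' Write a minimal VCF for a set of variant records
#'
#' Writes a VCF 4.2 file with a minimal header, coordinate-sorted within
#' each chromosome. Records must be 1-based biallelic SNVs/indels over
#' A/C/G/T.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id` ("." when absent).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
simulate_vcf <- function(variants, path) {
  variants <- as.data.frame(variants)
  if (nrow(variants) > 0L) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(variants)))
      stop("variants must have columns chrom, pos, ref, alt")
    if (any(variants$pos < 1L)) stop("pos must be >= 1 (1-based coordinates)")
    ok_allele <- function(a) grepl("^[ACGT]+$", a)
    if (!all(ok_allele(variants$ref)) || !all(ok_allele(variants$alt)))
      stop("alleles must be over {A,C,G,T}")
    if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
    if (is.null(variants$id)) variants$id <- "."
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pseudovar-synthetic",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) == 0L) character(0) else
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            variants$chrom, as.integer(variants$pos), variants$id,
            variants$ref, variants$alt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
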