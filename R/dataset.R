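# Dataset construction: VCF input, positive/negative labeling rules,
# train/test splitting, curated-negative sets.

#' Canonical variant key
#'
#' Variant identity throughout the package is the coordinate key
#' `chrom:pos:ref:alt` (1-based, fully closed, as in VCF).
#'
#' @param chrom,pos,ref,alt vectors, or a data frame with those columns as
#'   the first argument.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read variant records from a VCF file
#'
#' Reads a VCF 4.2 file (via \pkg{vcfR}) into one record per biallelic
#' variant; multi-allelic sites are split into one record per alternate
#' allele. Symbolic or non-ACGT alleles are rejected.
#'
#' @param path path to an uncompressed or gzipped VCF with a header.
#' @return data frame with columns `chrom`, `pos` (integer, 1-based), `id`,
#'   `ref`, `alt`, `key`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat"))
    stop("missing VCF header (##fileformat) in ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0), key = character(0),
                      stringsAsFactors = FALSE))
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed data line ", bad, ": non-numeric POS '", fix$POS[bad], "'")
  }
  if (any(pos < 1L)) stop("POS must be >= 1 (1-based coordinates)")
  # split multi-allelic sites
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  rec <- data.frame(
    chrom = rep(fix$CHROM, nalt),
    pos = rep(pos, nalt),
    id = rep(ifelse(is.na(fix$ID), ".", fix$ID), nalt),
    ref = rep(fix$REF, nalt),
    alt = unlist(alts),
    stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGT]+$", rec$ref) | !grepl("^[ACGT]+$", rec$alt)
  if (any(bad))
    stop("non-ACGT or symbolic allele in record(s): ",
         paste(head(variant_key(rec)[bad], 5), collapse = ", "))
  rec$key <- variant_key(rec)
  rec
}

#' Positive set by intersection of two variant collections
#'
#' The positive class is defined as the variants present in both inputs
#' (e.g. trait-associated variants that also have a significant
#' expression association), matched on the coordinate key.
#'
#' @param set_a,set_b character vectors of variant keys
#'   (`chrom:pos:ref:alt`).
#' @return data frame with columns `key` and `label` (all 1), sorted by key.
#' @export
intersect_positive <- function(set_a, set_b) {
  keys <- sort(intersect(unique(set_a), unique(set_b)))
  data.frame(key = keys, label = rep(1L, length(keys)),
             stringsAsFactors = FALSE)
}

#' Negative set from an association table
#'
#' Retains rows whose association is clearly null and whose allele is
#' common: P-value strictly greater than `p_min` and allele frequency
#' strictly greater than `af_min`. Boundary values are excluded.
#'
#' @param table data frame with columns `p_value` and `af` (and typically
#'   `key`).
#' @param p_min P-value cut (default 0.1).
#' @param af_min allele-frequency cut (default 0.3).
#' @return the retained rows with a `label` column (all 0).
#' @export
select_negatives <- function(table, p_min = 0.1, af_min = 0.3) {
  if (!all(c("p_value", "af") %in% names(table)))
    stop("table must have p_value and af columns")
  miss <- is.na(table$p_value) | is.na(table$af)
  if (any(miss)) {
    off <- if (!is.null(table$key)) table$key[miss] else which(miss)
    stop("missing p_value/af for: ", paste(head(off, 5), collapse = ", "))
  }
  out <- table[table$p_value > p_min & table$af > af_min, , drop = FALSE]
  out$label <- rep(0L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Split a dataset into training and test partitions
#'
#' Unstratified uniform shuffle driven only by `seed`; the test partition
#' holds `round(test_frac * n)` rows (half-up rounding) and is meant never
#' to be touched by any training step.
#'
#' @param ds data frame or matrix (rows are records).
#' @param test_frac fraction held out, strictly inside (0, 1); default 0.2.
#' @param seed integer seed.
#' @return list with elements `train` and `test` (disjoint, exhaustive) and
#'   the index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(ds, test_frac = 0.2, seed = 1) {
  n <- nrow(ds)
  if (is.null(n) || n < 2L) stop("dataset must have at least 2 rows")
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0, 1)")
  n_test <- round_half_up(test_frac * n)
  with_seed(seed, {
    perm <- sample.int(n)
    test_idx <- sort(perm[seq_len(n_test)])
    train_idx <- sort(perm[setdiff(seq_len(n), seq_len(n_test))])
    list(train = ds[train_idx, , drop = FALSE],
         test = ds[test_idx, , drop = FALSE],
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' Curated negatives near known positives
#'
#' Selects pool variants lying within `window` bp of some positive on the
#' same chromosome, weakly conserved (conservation strictly below
#' `cons_max`) and common (AF strictly above `af_min`); a retained variant
#' must not itself be a positive.
#'
#' @param positives data frame with `chrom`, `pos` (and `ref`, `alt` if
#'   available, used to exclude exact positives by key).
#' @param pool data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `conservation`, `af`.
#' @param window inclusive distance in bp (default 1000, i.e. +/- 1 kbp).
#' @param cons_max conservation cut (default 0.5).
#' @param af_min allele-frequency cut (default 0.3).
#' @return the retained pool rows with a `label` column (all 0).
#' @export
curated_negative_candidates <- function(positives, pool, window = 1000,
                                        cons_max = 0.5, af_min = 0.3) {
  if (!all(c("conservation", "af") %in% names(pool)))
    stop("pool must carry conservation and af columns")
  miss <- is.na(pool$conservation) | is.na(pool$af)
  if (any(miss)) {
    off <- if (!is.null(pool$key)) pool$key[miss] else which(miss)
    stop("missing conservation/af for: ", paste(head(off, 5), collapse = ", "))
  }
  near <- vapply(seq_len(nrow(pool)), function(i) {
    same <- positives$chrom == pool$chrom[i]
    any(same) && min(abs(positives$pos[same] - pool$pos[i])) <= window
  }, logical(1))
  pos_keys <- if (all(c("ref", "alt") %in% names(positives)))
    variant_key(positives) else character(0)
  pool_keys <- if (all(c("ref", "alt") %in% names(pool)))
    variant_key(pool) else rep(NA_character_, nrow(pool))
  keep <- near & pool$conservation < cons_max & pool$af > af_min &
    !(pool_keys %in% pos_keys)
  out <- pool[keep, , drop = FALSE]
  out$label <- rep(0L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Random-genome negative positions
#'
#' Samples `n` positions uniformly over the provided chromosome lengths
#' (chromosomes drawn proportional to length), rejecting positions within
#' `min_dist` of any positive on the same chromosome.
#'
#' @param n number of positions to draw.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param positives data frame with `chrom` and `pos`.
#' @param min_dist minimum distance (bp) from every positive.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap (default `100 * n + 100`).
#' @return data frame with `chrom`, `pos`, `label` (all 0).
#' @export
random_genome_negatives <- function(n, chrom_lengths, positives, min_dist,
                                    seed = 1, max_attempts = 100 * n + 100) {
  if (length(chrom_lengths) == 0L) stop("chrom_lengths must be non-empty")
  if (n < 0L) stop("n must be >= 0")
  with_seed(seed, {
    out_chrom <- character(0)
    out_pos <- integer(0)
    attempts <- 0L
    probs <- chrom_lengths / sum(chrom_lengths)
    while (length(out_pos) < n) {
      if (attempts >= max_attempts)
        stop("could not place ", n, " positions at min_dist ", min_dist,
             " within ", max_attempts, " attempts (infeasible)")
      attempts <- attempts + 1L
      ch <- sample(names(chrom_lengths), 1L, prob = probs)
      p <- sample.int(chrom_lengths[[ch]], 1L)
      same <- positives$chrom == ch
      if (any(same) && min(abs(positives$pos[same] - p)) < min_dist) next
      out_chrom <- c(out_chrom, ch)
      out_pos <- c(out_pos, p)
    }
    data.frame(chrom = out_chrom, pos = out_pos,
               label = rep(0L, n), stringsAsFactors = FALSE)
  })
}
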