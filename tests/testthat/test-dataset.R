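test_that("read_vcf parses, splits multi-allelic sites, and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t.\t.\t.",
    "chr1\t200\t.\tC\tA,G\t.\t.\t.",
    "chr2\t50\trs3\tT\tC\t.\t.\t."), path)
  rec <- read_vcf(path)
  expect_equal(nrow(rec), 4) # multi-allelic site split into two records
  two <- rec[rec$pos == 200, ]
  expect_equal(two$alt, c("A", "G"))
  expect_equal(unique(two$ref), "C")
  expect_equal(unique(two$chrom), "chr1")
  expect_false(anyDuplicated(rec$key) > 0)

  nohdr <- withr::local_tempfile(fileext = ".vcf")
  writeLines("chr1\t100\trs1\tA\tG\t.\t.\t.", nohdr)
  expect_error(read_vcf(nohdr), "header")

  badpos <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\tabc\trs1\tA\tG\t.\t.\t."), badpos)
  expect_error(suppressWarnings(read_vcf(badpos)), "POS")
})

test_that("positive intersection behaves as a set operation", {
  expect_equal(intersect_positive(c("A", "B", "C"), c("B", "C", "D"))$key,
               c("B", "C"))
  expect_equal(nrow(intersect_positive(c("A", "B"), c("C", "D"))), 0)
  same <- intersect_positive(letters[1:5], letters[1:5])
  expect_equal(nrow(same), 5)
  expect_true(all(same$label == 1L))
  # order is deterministic (sorted by key) regardless of input order
  expect_identical(intersect_positive(c("b", "a"), c("a", "b")),
                   intersect_positive(c("a", "b"), c("b", "a")))
})

test_that("negative filter applies strict P and AF cuts", {
  tab <- data.frame(key = paste0("v", 1:5),
                    p_value = c(0.05, 0.2, 0.1, 0.11, 0.5),
                    af = c(0.4, 0.35, 0.5, 0.3, 0.31))
  out <- select_negatives(tab)
  # row 1: P too small; row 3: P at boundary; row 4: AF at boundary
  expect_equal(out$key, c("v2", "v5"))
  expect_true(all(out$label == 0L))

  # equality with an independent brute-force row scan on random tables
  for (s in 1:5) {
    set.seed(s)
    rt <- data.frame(key = paste0("r", 1:50),
                     p_value = runif(50), af = runif(50))
    brute <- rt$key[sapply(seq_len(50), function(i)
      rt$p_value[i] > 0.1 && rt$af[i] > 0.3)]
    expect_equal(select_negatives(rt)$key, brute)
  }

  # idempotence
  once <- select_negatives(tab)
  expect_equal(select_negatives(once)$key, once$key)

  miss <- tab; miss$af[2] <- NA
  expect_error(select_negatives(miss), "v2")
})

test_that("train/test split is an exhaustive seeded partition", {
  ds <- data.frame(key = paste0("v", 1:10), val = rnorm(10))
  sp <- split_dataset(ds, test_frac = 0.2, seed = 4)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_setequal(c(sp$train$key, sp$test$key), ds$key)
  expect_equal(length(intersect(sp$train$key, sp$test$key)), 0)
  expect_identical(sp, split_dataset(ds, test_frac = 0.2, seed = 4))
  expect_false(identical(sp$test_idx,
                         split_dataset(ds, test_frac = 0.2, seed = 5)$test_idx))
  expect_error(split_dataset(ds, test_frac = 0), "test_frac")
  expect_error(split_dataset(ds, test_frac = 1), "test_frac")
  # half-up rounding of the test size
  expect_equal(nrow(split_dataset(ds[1:5, ], 0.5, seed = 1)$test), 3)
})

test_that("curated negatives respect window, conservation, and AF rules", {
  positives <- data.frame(chrom = "chr1", pos = 10000L, ref = "A", alt = "G")
  pool <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    pos = c(11500L, 10800L, 10800L, 10100L, 10000L),
    ref = c("C", "C", "C", "C", "A"),
    alt = c("T", "T", "T", "T", "G"),
    conservation = c(0.1, 0.6, 0.2, 0.1, 0.1),
    af = c(0.5, 0.5, 0.4, 0.5, 0.5))
  out <- curated_negative_candidates(positives, pool)
  # 1: 1500 bp away; 2: conserved; 4: wrong chromosome; 5: is the positive
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 10800L)
  expect_true(all(out$label == 0L))
  # inclusive window boundary
  edge <- pool[3, ]; edge$pos <- 11000L
  expect_equal(nrow(curated_negative_candidates(positives, edge)), 1)
  edge$pos <- 11001L
  expect_equal(nrow(curated_negative_candidates(positives, edge)), 0)
  # idempotence
  expect_equal(curated_negative_candidates(positives, out)$pos, out$pos)
  miss <- pool; miss$conservation[1] <- NA
  expect_error(curated_negative_candidates(positives, miss), "missing")
})

test_that("random-genome negatives respect the distance constraint", {
  positives <- data.frame(chrom = "chr1", pos = c(5000L, 9000L))
  lens <- c(chr1 = 20000, chr2 = 10000)
  out <- random_genome_negatives(5, lens, positives, min_dist = 1000, seed = 8)
  expect_equal(nrow(out), 5)
  on1 <- out[out$chrom == "chr1", ]
  if (nrow(on1) > 0)
    expect_true(all(sapply(on1$pos, function(p)
      min(abs(positives$pos - p))) >= 1000))
  expect_identical(out, random_genome_negatives(5, lens, positives,
                                                min_dist = 1000, seed = 8))
  # infeasible: positives blanket the whole toy genome
  expect_error(
    random_genome_negatives(3, c(chr1 = 100),
                            data.frame(chrom = "chr1", pos = 50L),
                            min_dist = 200, seed = 1, max_attempts = 50),
    "infeasible")
})
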