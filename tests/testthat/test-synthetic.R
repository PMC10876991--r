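test_that("generators are deterministic and plant the configured structure", {
  cfg <- sim_config(30, 20, n_features = 12, n_informative = 3, effect = 2,
                    n_unlabeled = 25, seed = 42)
  a <- simulate_annotation_dataset(cfg)
  b <- simulate_annotation_dataset(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$x), c(50L, 12L))
  expect_equal(sum(a$labels == 1), 30)
  expect_equal(attr(a$x, "informative"), colnames(a$x)[1:3])
  expect_false(anyDuplicated(rownames(a$x)) > 0)

  p1 <- simulate_unlabeled_pool(cfg)
  p2 <- simulate_unlabeled_pool(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$x), 25)
  expect_equal(length(intersect(rownames(p1$x), rownames(a$x))), 0)

  # informative columns shifted by `effect` in positives, centered in negatives
  big <- simulate_annotation_dataset(
    sim_config(2000, 2000, n_features = 10, n_informative = 4, effect = 2,
               seed = 7))
  mpos <- colMeans(big$x[big$labels == 1, 1:4])
  mneg <- colMeans(big$x[big$labels == 0, 1:4])
  expect_true(all(abs(mpos - 2) < 0.1))
  expect_true(all(abs(mneg) < 0.1))
  expect_true(all(abs(colMeans(big$x[, 5:10])) < 0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, 10, n_features = 5, n_informative = 6),
               "n_informative")
  expect_error(sim_config(10, 10, unlabeled_prevalence = 1.2), "prevalence")
  expect_error(sim_config(-1, 10), "counts")
  expect_error(sim_config(10, 10, noise_sd = 0), "noise_sd")
})

test_that("with no effect any classifier sits at chance on held-out data", {
  cfg <- sim_config(1000, 1000, n_features = 20, n_informative = 5,
                    effect = 0, seed = 3)
  d <- simulate_annotation_dataset(cfg)
  sp <- split_dataset(d$x, 0.5, seed = 9)
  ytr <- d$labels[sp$train_idx]; yte <- d$labels[sp$test_idx]
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, sp$train), ytr, family = stats::binomial()))
  s <- as.numeric(cbind(1, sp$test) %*% fit$coefficients)
  expect_gt(roc_auc(s, yte), 0.44)
  expect_lt(roc_auc(s, yte), 0.56)
})

test_that("a strong planted effect is almost perfectly separable", {
  # equal mean-shift on every informative column: the sum over informative
  # columns is the Bayes discriminant, with analytic AUC pnorm(d / sqrt(2)),
  # d = sqrt(20 * 5^2) -- indistinguishable from 1 here
  cfg <- sim_config(1000, 1000, n_features = 30, n_informative = 20,
                    effect = 5, seed = 5)
  d <- simulate_annotation_dataset(cfg)
  disc <- rowSums(d$x[, attr(d$x, "informative")])
  expect_gt(roc_auc(disc, d$labels), 0.999)
})

test_that("unlabeled pool hides truth at the configured prevalence", {
  cfg <- sim_config(10, 10, n_features = 8, n_informative = 2,
                    n_unlabeled = 5000, unlabeled_prevalence = 0.4, seed = 21)
  p <- simulate_unlabeled_pool(cfg)
  # within 3 binomial SDs of 0.4
  tol <- 3 * sqrt(0.4 * 0.6 / 5000)
  expect_lt(abs(mean(p$hidden_labels) - 0.4), tol)

  p0 <- simulate_unlabeled_pool(
    sim_config(10, 10, n_unlabeled = 200, unlabeled_prevalence = 0, seed = 2))
  expect_true(all(p0$hidden_labels == 0L))
})

test_that("eqtl tables plant an exact filter-passing count and nest properly", {
  cfg <- sim_config(13, 7, seed = 11)
  tabs <- simulate_eqtl_tables(cfg, n_sig = 13, n_full = 20, n_pass = 7)
  expect_equal(nrow(tabs$full), 20)
  expect_true(all(tabs$significant$key %in% tabs$full$key))
  expect_equal(nrow(select_negatives(tabs$full)), 7)
  expect_true(all(tabs$full$p_value >= 0 & tabs$full$p_value <= 1))
  expect_true(all(tabs$full$af > 0 & tabs$full$af < 1))
  expect_identical(tabs, simulate_eqtl_tables(cfg, n_sig = 13, n_full = 20,
                                              n_pass = 7))
  expect_error(simulate_eqtl_tables(cfg, n_sig = 13, n_full = 20, n_pass = 8),
               "exceed")
})

test_that("VCF writing round-trips through the reader", {
  v <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                  pos = c(500L, 1200L, 300L),
                  id = c("rs2", "rs1", "."),
                  ref = c("A", "T", "G"), alt = c("G", "C", "A"),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  simulate_vcf(v, path)
  back <- read_vcf(path)
  # coordinate-sorted within chromosome
  expect_equal(back$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(back$pos, c(300L, 1200L, 500L))
  expect_setequal(back$key, variant_key(v))

  # empty list -> header-only file, zero records
  p2 <- withr::local_tempfile(fileext = ".vcf")
  simulate_vcf(v[0, ], p2)
  expect_equal(readLines(p2)[1], "##fileformat=VCFv4.2")
  expect_equal(nrow(read_vcf(p2)), 0)

  # 1-based invariant and allele checks enforced before writing
  bad <- v; bad$pos[1] <- 0L
  expect_error(simulate_vcf(bad, p2), "1-based")
  bad <- v; bad$alt[1] <- "A"
  expect_error(simulate_vcf(bad, p2), "differ")
})

test_that("null columns pass a location test at the nominal type-I rate", {
  cfg <- sim_config(100, 100, n_features = 200, n_informative = 0,
                    effect = 0, seed = 17)
  d <- simulate_annotation_dataset(cfg)
  pv <- apply(d$x, 2, function(col)
    stats::t.test(col[d$labels == 1], col[d$labels == 0])$p.value)
  frac <- mean(pv < 0.05)
  expect_gt(frac, 0.0)   # some rejections expected over 200 columns
  expect_lt(frac, 0.12)  # ~3 binomial SDs above the nominal 0.05
})
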