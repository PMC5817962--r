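test_that("TMM factors are 1 for identical or proportional columns", {
  set.seed(8)
  y <- as.integer(rpois(60, 40) + 1L)  # large enough to survive trimming
  same <- cbind(s1 = y, s2 = y)
  rownames(same) <- paste0("g", 1:60)
  expect_equal(unname(tmm_factors(same)), c(1, 1), tolerance = 1e-12)

  prop <- cbind(s1 = y, s2 = 3L * y)
  rownames(prop) <- paste0("g", 1:60)
  expect_equal(unname(tmm_factors(prop)), c(1, 1), tolerance = 1e-12)
})

test_that("untrimmed TMM factor equals the hand-computed weighted mean of M", {
  # 6 genes, second sample has one 20x-inflated gene
  y1 <- c(100L, 200L, 300L, 400L, 500L, 50L)
  y2 <- c(100L, 200L, 300L, 400L, 500L, 1000L)
  counts <- cbind(s1 = y1, s2 = y2)
  rownames(counts) <- paste0("g", 1:6)
  f <- tmm_factors(counts, trim_m = 0, trim_a = 0, ref_column = 1)

  # arithmetic oracle, straight from the definition
  N1 <- sum(y1); N2 <- sum(y2)
  M <- log2((y2 / N2) / (y1 / N1))
  w <- 1 / ((N2 - y2) / (N2 * y2) + (N1 - y1) / (N1 * y1))
  f2_raw <- 2^(sum(w * M) / sum(w))
  expected <- c(1, f2_raw) / exp(mean(log(c(1, f2_raw))))
  expect_equal(unname(f), expected, tolerance = 1e-10)
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  pilot <- small_pilot(n_genes = 600, reps = 4, lib = 5e4, seed = 77)
  ours <- tmm_factors(pilot$counts)
  theirs <- edgeR::calcNormFactors(pilot$counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("TMM falls back to unit factors when too few genes survive", {
  counts <- cbind(s1 = c(5L, 0L, 0L, 0L, 12L),
                  s2 = c(0L, 7L, 0L, 0L, 30L))
  rownames(counts) <- paste0("g", 1:5)
  w <- capture_warnings(f <- tmm_factors(counts))  # one warning per sample
  expect_true(all(grepl("factor set to 1", w)))
  expect_equal(unname(f), c(1, 1))
})

test_that("logCPM matches its formula and scale invariances", {
  # zero count, effective library 1e6, prior 0.5
  col <- matrix(c(0L, 1000000L), nrow = 2,
                dimnames = list(c("g1", "g2"), "s1"))
  lc <- log_cpm(col, c(s1 = 1), prior_count = 0.5)
  expect_equal(lc["g1", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-9)

  # doubling counts and library (prior 0) leaves logCPM unchanged
  y <- toy_counts()
  f1 <- rep(1, 4)
  expect_equal(log_cpm(y, f1, prior_count = 0),
               log_cpm(2L * y, f1, prior_count = 0), tolerance = 1e-12)

  same <- cbind(a = y[, 1], b = y[, 1])
  lc2 <- log_cpm(same, c(1, 1))
  expect_equal(lc2[, 1], lc2[, 2])
})

test_that("common dispersion hits the boundary for replicated identical columns", {
  y <- toy_counts()[, 1]
  counts <- cbind(a1 = y, a2 = y, a3 = y)
  design <- data.frame(sample = colnames(counts), condition = "A")
  phi <- estimate_common_dispersion(counts, design, rep(1, 3))
  expect_lt(phi, 2e-6)
})

test_that("common dispersion recovers simulated values", {
  # Poisson data: estimate collapses toward zero
  set.seed(19)
  mu <- rexp(2000, 1 / 50)
  pois <- vapply(1:16, function(j) rpois(2000, mu), numeric(2000))
  dimnames(pois) <- list(paste0("g", 1:2000),
                         c(paste0("A_", 1:8), paste0("B_", 1:8)))
  storage.mode(pois) <- "integer"
  design <- data.frame(sample = colnames(pois),
                       condition = rep(c("A", "B"), each = 8))
  expect_lte(estimate_common_dispersion(pois, design, tmm_factors(pois)), 0.01)

  # NB data at phi = 0.1 (near-constant gamma): estimate in [0.08, 0.12]
  pilot <- generate_pilot(pilot_spec(n_genes = 2000,
                                     replicates_per_condition = 8,
                                     target_library_size = 2e5,
                                     dispersion_shape = 1e4,
                                     dispersion_scale = 1e-5, seed = 23))
  phi <- estimate_common_dispersion(pilot$counts, pilot$design,
                                    tmm_factors(pilot$counts))
  expect_gt(phi, 0.08)
  expect_lt(phi, 0.12)
})

test_that("tagwise dispersions shrink toward the common value as the prior grows", {
  pilot <- small_pilot(n_genes = 40, reps = 6, lib = 2e4, seed = 301)
  counts <- pilot$counts
  design <- pilot$design
  factors <- tmm_factors(counts)
  phi_c <- estimate_common_dispersion(counts, design, factors)

  # infinite prior: every gene sits at the common estimate
  tw_inf <- estimate_tagwise_dispersion(counts, design, factors, phi_c,
                                        prior_weight = 1e9)
  expect_true(all(abs(log(tw_inf) - log(phi_c)) < 0.05))

  # zero prior: per-gene maximizer, checked against an independent
  # grid-search oracle on the library-equalized pseudo-counts
  eff <- colSums(counts) * factors
  n_star <- exp(mean(log(eff)))
  pseudo <- round(sweep(counts, 2, n_star / eff, "*"))
  tw0 <- estimate_tagwise_dispersion(counts, design, factors, phi_c,
                                     prior_weight = 0)
  grid <- exp(seq(log(1e-6), log(10), length.out = 200))
  for (g in seq_len(nrow(counts))) {
    ya <- pseudo[g, design$condition == "A"]
    yb <- pseudo[g, design$condition == "B"]
    cll <- vapply(grid, function(phi)
      oracle_cond_loglik(ya, phi) + oracle_cond_loglik(yb, phi), numeric(1))
    expect_lt(abs(log(tw0[g]) - log(grid[which.max(cll)])), 0.15)
  }

  # monotone pull toward the common value
  dist <- vapply(c(0, 5, 50, 500), function(w) {
    tw <- estimate_tagwise_dispersion(counts, design, factors, phi_c,
                                      prior_weight = w)
    mean(abs(log(tw) - log(phi_c)))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-8))
})

test_that("exact test reproduces the binomial enumeration in the Poisson limit", {
  # phi = 0, 1 vs 1, counts (0, 10): Binomial(10, 1/2); only {0, 10} are
  # as extreme as the observed partition, so p = 2/1024
  p <- pilotpower:::.exact_nb_pvalue(0, 10, 1, 1, 0)
  expect_equal(p, 2 / 1024, tolerance = 1e-12)
})

test_that("exact test equals brute-force enumeration on random instances", {
  set.seed(12345)
  for (i in 1:100) {
    s <- sample(1:500, 1)
    a <- sample(0:s, 1)
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    phi <- runif(1, 1e-4, 2)
    expect_equal(pilotpower:::.exact_nb_pvalue(a, s, n1, n2, phi),
                 oracle_exact_pvalue(a, s, n1, n2, phi),
                 tolerance = 1e-9)
  }
})

test_that("equal group sums with equal replicate numbers give p = 1", {
  counts <- toy_counts()  # columns have equal sums; groups are identical
  design <- toy_design(counts)
  et <- exact_test(counts, design, list(mode = "common", common = 0.1),
                   rep(1, 4), c("A", "B"))
  sums_a <- rowSums(counts[, 1:2])
  sums_b <- rowSums(counts[, 3:4])
  expect_true(all(et$pvalue[sums_a == sums_b] == 1))
})

test_that("swapping condition labels negates logFC and preserves p-values", {
  pilot <- small_pilot(n_genes = 150, reps = 3, lib = 2e4, seed = 55)
  factors <- tmm_factors(pilot$counts)
  disp <- list(mode = "common", common = 0.08)
  ab <- exact_test(pilot$counts, pilot$design, disp, factors, c("A", "B"))
  ba <- exact_test(pilot$counts, pilot$design, disp, factors, c("B", "A"))
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)
})

test_that("exact test p-values are conservative under the Poisson null", {
  set.seed(77)
  mu <- rexp(5000, 1 / 40)
  counts <- vapply(1:4, function(j) rpois(5000, mu), numeric(5000))
  dimnames(counts) <- list(paste0("g", 1:5000), c("a1", "a2", "b1", "b2"))
  storage.mode(counts) <- "integer"
  design <- toy_design(counts)
  et <- exact_test(counts, design, 0, rep(1, 4), c("A", "B"))
  for (alpha in c(0.01, 0.05)) {
    expect_lte(mean(et$pvalue <= alpha), alpha + 0.01)
  }
})

test_that("BH adjustment matches the hand step-up rule and an oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:5) {
    p <- runif(200)^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  }
  # bulk oracle agreement on many short random vectors
  set.seed(10)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_identical(all.equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12),
                     TRUE)
  }
})

test_that("run_de applies the dispersion-mode rule and the zero-gene contract", {
  pilot <- small_pilot(n_genes = 120, reps = 5, lib = 1.5e4, seed = 61)
  counts <- pilot$counts
  counts["g00001", ] <- 0L  # force an all-zero gene
  design <- pilot$design

  res5 <- run_de(counts, design)
  expect_identical(attr(res5, "provenance")$dispersion_mode, "tagwise")
  expect_identical(res5$pvalue[res5$gene == "g00001"], 1)
  expect_identical(res5$padj[res5$gene == "g00001"], 1)
  expect_identical(res5$logFC[res5$gene == "g00001"], 0)
  expect_true(all(res5$padj >= res5$pvalue - 1e-12))

  sub <- subsample_replicates(counts, design, 4, seed = 2)
  res4 <- run_de(sub$counts, sub$design)
  expect_identical(attr(res4, "provenance")$dispersion_mode, "common")
  expect_identical(nrow(res4), nrow(counts))
})

test_that("run_de declares nothing on null data in most seeds", {
  hits <- vapply(1:20, function(s) {
    pilot <- generate_pilot(pilot_spec(n_genes = 1000,
                                       replicates_per_condition = 5,
                                       target_library_size = 2e4,
                                       pi_de = 0, seed = 100 + s))
    res <- run_de(pilot$counts, pilot$design)
    sum(res$padj < 0.05)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("the native pipeline tracks the edgeR classic pipeline", {
  skip_if_not_installed("edgeR")
  pilot <- small_pilot(n_genes = 800, reps = 4, lib = 1e5, seed = 91)
  res <- run_de(pilot$counts, pilot$design)

  y <- edgeR::DGEList(counts = pilot$counts,
                      group = pilot$design$condition)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)

  phi_ours <- attr(res, "provenance")$phi_common
  expect_gt(phi_ours / y$common.dispersion, 0.5)
  expect_lt(phi_ours / y$common.dispersion, 2)

  expect_gt(cor(res$logFC, et$table$logFC), 0.98)
  ours <- res$gene[res$padj < 0.05]
  theirs <- rownames(et$table)[p.adjust(et$table$PValue, "BH") < 0.05]
  jaccard <- length(intersect(ours, theirs)) / length(union(ours, theirs))
  expect_gt(jaccard, 0.7)
})
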