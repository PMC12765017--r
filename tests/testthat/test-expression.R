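make_em <- function(counts) {
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  expression_matrix(counts)
}

test_that("median-of-ratios size factors: symmetry, scaling, brute-force oracle", {
  m <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  em <- normalize_median_of_ratios(make_em(m))
  expect_equal(unname(em$size_factors), rep(1, 3), tolerance = 1e-12)

  m2 <- cbind(c(10, 20, 30, 40), c(20, 40, 60, 80))
  em2 <- normalize_median_of_ratios(make_em(m2))
  expect_equal(unname(em2$size_factors[2] / em2$size_factors[1]), 2, tolerance = 1e-12)

  set.seed(501)
  m3 <- matrix(rpois(120, 40), 20, 6)
  em3 <- normalize_median_of_ratios(make_em(m3))
  expect_equal(unname(em3$size_factors), unname(size_factor_oracle(m3)),
               tolerance = 1e-12)
  expect_equal(em3$layers$normalized,
               sweep(em3$counts, 2, em3$size_factors, "/"))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(502)
  m <- matrix(rnbinom(600, mu = 50, size = 5) + 1, 100, 6)
  em <- normalize_median_of_ratios(make_em(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 takes the median in log space, which interpolates the middle pair
  # geometrically rather than arithmetically at an even reference count
  expect_equal(unname(em$size_factors), unname(ref), tolerance = 2e-3)
})

test_that("normalization errors and invariance properties", {
  m <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(normalize_median_of_ratios(make_em(m)), "cannot normalize")
  # scaling one sample scales only its factor when reference genes unchanged
  set.seed(503)
  m <- matrix(rpois(80, 50) + 1, 20, 4)
  sf1 <- normalize_median_of_ratios(make_em(m))$size_factors
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  sf2 <- normalize_median_of_ratios(make_em(m2))$size_factors
  expect_equal(unname(sf2[3] / sf1[3]),
               5 * unname((sf2[1] / sf1[1])), tolerance = 0.15)
})

test_that("TPM columns sum to one million and honor gene lengths", {
  counts <- matrix(c(10, 20, 5), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  em <- expression_matrix(counts, gene_lengths = c(a = 1000, b = 2000, c = 500))
  em <- compute_tpm(em)
  expect_equal(unname(em$layers$tpm[, 1]), rep(1e6 / 3, 3))
  set.seed(504)
  counts2 <- matrix(rpois(50, 30) + 1, 10, 5,
                    dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  em2 <- compute_tpm(expression_matrix(counts2, sample(500:3000, 10)))
  expect_equal(unname(colSums(em2$layers$tpm)), rep(1e6, 5), tolerance = 1e-6)
  expect_error(compute_tpm(expression_matrix(counts2)), "gene_lengths")
})

test_that("low-expression filter uses inclusive thresholds", {
  counts <- rbind(
    exactly = c(10, 10, 10, 10, 10, 0, 0, 0), # 10 reads in exactly 5 samples
    below   = rep(9, 8),
    strong  = rep(100, 8)
  )
  colnames(counts) <- paste0("s", 1:8)
  kept <- filter_low_expression(expression_matrix(counts))$gene_ids
  expect_setequal(kept, c("exactly", "strong"))
  set.seed(505)
  m <- matrix(rpois(400, 8), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  kept2 <- filter_low_expression(expression_matrix(m))$gene_ids
  oracle <- rownames(m)[apply(m, 1, function(r) sum(r >= 10) >= 5)]
  expect_identical(kept2, oracle)
})

test_that("variable-gene selection applies strict mean and variance gates", {
  le <- rbind(
    constant = rep(5, 6),
    swing    = rep(c(0, 10), 3),   # mean 5, var 30
    lowmean  = rep(c(0, 3), 3)     # mean 1.5
  )
  colnames(le) <- paste0("s", 1:6)
  expect_identical(select_variable_genes(le), "swing")
  expect_identical(select_variable_genes(le[1, , drop = FALSE]), character(0))
  # invariant to sample and gene order
  perm <- le[c(3, 1, 2), c(4, 2, 6, 1, 3, 5)]
  expect_setequal(select_variable_genes(perm), select_variable_genes(le))
})

test_that("clustering is deterministic, co-clusters duplicates and recovers subtypes", {
  co <- small_cohort(seed = 21)
  em <- normalize_median_of_ratios(co$expression)
  hv <- select_variable_genes(em$layers$log2, var_threshold = 1)
  expect_gt(length(hv), 10)
  cr1 <- cluster_samples(em$layers$log2, hv, n_clusters = 3, seed = 5)
  cr2 <- cluster_samples(em$layers$log2, hv, n_clusters = 3, seed = 5)
  expect_identical(cr1$labels, cr2$labels)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cr1$labels, co$truth_subtype[names(cr1$labels)])
  expect_equal(ari, 1.0)
  # appended duplicate samples land in their originals' cluster
  le <- em$layers$log2
  dup <- le[, 1:3]
  colnames(dup) <- paste0(colnames(dup), "_dup")
  cr3 <- cluster_samples(cbind(le, dup), hv, n_clusters = 3, seed = 5)
  expect_equal(unname(cr3$labels[paste0(colnames(le)[1:3], "_dup")]),
               unname(cr3$labels[colnames(le)[1:3]]))
})

test_that("differential-gene flags use strict thresholds and record direction", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(2.0, -3.1, 2.5, 0.5),
                    padj = c(0.01, 0.001, 0.05, 0.001))
  res <- select_differential_genes(tab)
  expect_equal(res$passes, c(FALSE, TRUE, FALSE, FALSE)) # boundary |lfc|=2 and p=0.05 fail
  expect_equal(res$direction[2], "up_group2")
  set.seed(506)
  tab2 <- data.frame(gene = paste0("g", 1:100),
                     log2fc = rnorm(100, sd = 3), padj = runif(100))
  res2 <- select_differential_genes(tab2)
  expect_equal(res2$passes, abs(tab2$log2fc) > 2 & tab2$padj < 0.05)
})
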