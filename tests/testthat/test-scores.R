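toy_sets <- function(n_genes = 40) {
  score_gene_sets(tds_genes = sprintf("TDSG%02d", 1:16),
                  erk_genes = sprintf("ERKG%02d", 1:52))
}

test_that("z-scoring centers, scales and zeroes constant genes", {
  le <- rbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  colnames(le) <- paste0("s", 1:4)
  z <- zscore_by_gene(le)
  expect_equal(unname(z["a", ]), c(-1.162, -0.387, 0.387, 1.162), tolerance = 1e-3)
  expect_equal(unname(z["b", ]), rep(0, 4))
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sd(z["a", ]), 1)
  expect_error(zscore_by_gene(le[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("MPAS matches its closed form and a brute-force loop", {
  sets <- toy_sets()
  z0 <- matrix(0, 10, 3, dimnames = list(sets$mpas_genes, paste0("s", 1:3)))
  expect_equal(as.numeric(mpas(z0, sets)), rep(0, 3))
  z1 <- z0; z1[, 2] <- 1
  expect_equal(as.numeric(mpas(z1, sets))[2], sqrt(10), tolerance = 1e-12)
  set.seed(601)
  zr <- matrix(rnorm(30), 10, 3, dimnames = dimnames(z0))
  oracle <- vapply(1:3, function(j) sum(zr[, j]) / sqrt(10), numeric(1))
  expect_equal(as.numeric(mpas(zr, sets)), oracle)
  expect_equal(attr(mpas(zr, sets), "n_genes_used"), 10)
})

test_that("ERK score is the mean z over available signature genes", {
  sets <- toy_sets()
  present <- sets$erk_genes[1:41] # 11 of 52 unresolvable in the annotation
  set.seed(602)
  z <- matrix(rnorm(41 * 4), 41, 4, dimnames = list(present, paste0("s", 1:4)))
  sc <- erk_score(z, sets)
  expect_equal(attr(sc, "n_genes_used"), 41)
  expect_equal(as.numeric(sc), unname(colMeans(z)))
  expect_error(erk_score(z[0, , drop = FALSE], sets), "no ERK")
})

test_that("TDS centering, linearity and brute-force double loop", {
  sets <- toy_sets()
  set.seed(603)
  le <- matrix(rnorm(16 * 7, 6), 16, 7,
               dimnames = list(sets$tds_genes, paste0("s", 1:7)))
  # a sample sitting at every gene's median scores zero
  med <- apply(le, 1, median)
  le2 <- cbind(le, smed = med)
  expect_equal(unname(tds(le2, sets, median_samples = colnames(le2))[["smed"]]),
               0, tolerance = 1e-12)
  # brute-force double loop
  sc <- tds(le, sets)
  oracle <- vapply(seq_len(ncol(le)), function(j) {
    s <- 0
    for (g in rownames(le)) s <- s + (le[g, j] - median(le[g, ]))
    s
  }, numeric(1))
  expect_equal(unname(sc), oracle)
  # +1 on one gene of a max-valued sample in an odd cohort leaves the median
  # untouched, so that sample's score rises by exactly 1
  jmax <- which.max(le[1, ])
  le3 <- le; le3[1, jmax] <- le3[1, jmax] + 1
  expect_equal(tds(le3, sets)[[jmax]], sc[[jmax]] + 1, tolerance = 1e-12)
  expect_error(tds(le[-1, ], sets), "TDSG01")
})

test_that("score invariance to per-gene additive shifts", {
  sets <- toy_sets()
  set.seed(604)
  genes <- c(sets$mpas_genes, sets$erk_genes[1:20])
  le <- matrix(rnorm(length(genes) * 6, 5), length(genes), 6,
               dimnames = list(genes, paste0("s", 1:6)))
  le_shift <- le; le_shift["CCND1", ] <- le_shift["CCND1", ] + 42
  expect_equal(mpas(zscore_by_gene(le), sets), mpas(zscore_by_gene(le_shift), sets))
  expect_equal(erk_score(zscore_by_gene(le), sets),
               erk_score(zscore_by_gene(le_shift), sets))
})

test_that("correlation screen identity, antitone and planted-gene recovery", {
  set.seed(605)
  score <- setNames(rnorm(12), paste0("s", 1:12))
  le <- matrix(rnorm(12 * 20), 20, 12,
               dimnames = list(paste0("g", 1:20), names(score)))
  le["g1", ] <- score
  le["g2", ] <- -score
  res <- correlate_with_vector(score, le, method = "spearman")
  expect_equal(res$coefficient[res$gene == "g1"], 1)
  expect_equal(res$coefficient[res$gene == "g2"], -1)
  expect_error(correlate_with_vector(setNames(rep(1, 12), names(score)), le),
               "constant")
  # planted monotone genes dominate the FDR ranking
  set.seed(606)
  score2 <- setNames(rnorm(30), paste0("t", 1:30))
  le2 <- matrix(rnorm(30 * 200), 200, 30,
                dimnames = list(paste0("g", 1:200), names(score2)))
  planted <- paste0("g", 1:10)
  for (g in planted) le2[g, ] <- score2 + rnorm(30, sd = 0.3)
  res2 <- correlate_with_vector(score2, le2)
  top10 <- res2$gene[order(res2$fdr)][1:10]
  expect_gte(length(intersect(top10, planted)), 9)
})

test_that("pre-ranked enrichment matches a hand-computed running sum", {
  genes <- paste0("g", 1:8)
  scores <- c(4, 3, 2.5, 2, 1.5, 1, 0.5, 0.2)
  gs <- c("g1", "g3", "g6")
  # hand oracle: weighted hit increments |score|/sum(|hit scores|), miss
  # decrements 1/5
  w <- scores / (4 + 2.5 + 1)
  hand <- cumsum(c(w[1], -1/5, w[3], -1/5, -1/5, w[6], -1/5, -1/5))
  res <- preranked_enrichment(genes, scores, gs, n_permutations = 50, seed = 1)
  expect_equal(res$running_sum, hand, tolerance = 1e-12)
  expect_equal(res$es, hand[which.max(abs(hand))])
  # top-k set with positive scores peaks at position k
  gs2 <- genes[1:3]
  res2 <- preranked_enrichment(genes, scores, gs2, n_permutations = 50, seed = 1)
  expect_gt(res2$es, 0)
  expect_equal(which.max(abs(res2$running_sum)), 3)
  expect_error(preranked_enrichment(genes, scores, c("zz"), 10, 1), "intersection")
})

test_that("enrichment statistic is deterministic given the seed", {
  set.seed(607)
  genes <- paste0("g", 1:100)
  scores <- sort(rnorm(100), decreasing = TRUE)
  gs <- sample(genes, 15)
  a <- preranked_enrichment(genes, scores, gs, n_permutations = 200, seed = 9)
  b <- preranked_enrichment(genes, scores, gs, n_permutations = 200, seed = 9)
  expect_identical(a, b)
})
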