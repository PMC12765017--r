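test_that("96-class labels and the purine strand convention", {
  labels <- context_96_labels()
  expect_length(labels, 96)
  expect_false(anyDuplicated(labels) > 0)
  # G>A at 5'-TGT-3' is C>T at A[C>T]A on the pyrimidine strand
  expect_equal(classify_snv("G", "A", "TGT"), "A[C>T]A")
  expect_equal(classify_snv("C", "T", "ACA"), "A[C>T]A")
  expect_error(classify_snv("C", "T", "AGA"), "does not match")
})

test_that("spectra conserve counts and are order/strand invariant", {
  set.seed(701)
  co <- small_cohort(seed = 41)
  snvs <- co$wes_tumor_variants
  sp <- build_spectrum(snvs, co$reference_context)
  is_snv <- nchar(snvs$ref) == 1 & nchar(snvs$alt) == 1
  expect_equal(sum(sp), sum(is_snv))
  # permuting input rows leaves the spectrum unchanged
  sp2 <- build_spectrum(snvs[sample(nrow(snvs)), ], co$reference_context)
  expect_equal(sp[, colnames(sp2)], sp2[, colnames(sp2)])
})

test_that("a planted C>T-only mixture yields only C>T / G>A substitutions", {
  co <- generate_cohort(cohort_config(
    n_tumors_subtype1 = 3, n_tumors_subtype2 = 2, n_normals = 2, n_genes = 100,
    n_somatic_per_sample = 50, n_germline_per_sample = 20,
    signature_mixture = c(ct_only = 1), seed = 9))
  v <- co$wes_tumor_variants
  snv <- v[nchar(v$ref) == 1 & nchar(v$alt) == 1, ]
  pair <- paste(snv$ref, snv$alt, sep = ">")
  expect_true(all(pair %in% c("C>T", "G>A")))
  sp <- build_spectrum(snv, co$reference_context)
  ct_bins <- grepl("C>T", rownames(sp))
  expect_equal(sum(sp[!ct_bins, ]), 0)
})

test_that("NMF recovers planted orthogonal-support signatures at k = 2", {
  set.seed(702)
  labels <- context_96_labels()
  s1 <- rep(0, 96); s1[1:48] <- runif(48); s1 <- s1 / sum(s1)
  s2 <- rep(0, 96); s2[49:96] <- runif(48); s2 <- s2 / sum(s2)
  # mixture of pure and blended exposures: the pure samples make the planted
  # signatures the extreme rays of the data cone, so the factorization is
  # identifiable (a blends-only design admits other exact factorizations)
  expo <- rbind(cbind(runif(3, 500, 4000), 0),
                cbind(0, runif(3, 500, 4000)),
                cbind(runif(6, 500, 4000), runif(6, 500, 4000)))
  V <- cbind(s1, s2) %*% t(expo) # exact nonnegative combination
  rownames(V) <- labels; colnames(V) <- paste0("s", 1:12)
  fit <- extract_signatures(V, k = 2, seed = 3, n_restarts = 8, max_iter = 4000)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- outer(1:2, 1:2, Vectorize(function(i, j)
    cs(fit$signatures[, i], cbind(s1, s2)[, j])))
  best <- max(min(sims[1, 1], sims[2, 2]), min(sims[1, 2], sims[2, 1]))
  expect_gte(best, 0.99)
  expect_true(all(fit$exposures >= 0))
  expect_equal(unname(colSums(fit$signatures)), c(1, 1), tolerance = 1e-9)
})

test_that("rank-1 NMF on identical spectra returns the common profile", {
  set.seed(703)
  prof <- runif(96); prof <- prof / sum(prof)
  V <- matrix(round(prof * 1000), 96, 5,
              dimnames = list(context_96_labels(), paste0("s", 1:5)))
  fit <- extract_signatures(V, k = 1, seed = 1, n_restarts = 3)
  expect_equal(unname(fit$signatures[, 1]), unname(V[, 1] / sum(V[, 1])),
               tolerance = 1e-4)
})

test_that("NMF is deterministic and its error decreases with rank", {
  set.seed(704)
  V <- matrix(rpois(96 * 8, 20), 96, 8,
              dimnames = list(context_96_labels(), paste0("s", 1:8)))
  a <- extract_signatures(V, k = 2, seed = 5, n_restarts = 3)
  b <- extract_signatures(V, k = 2, seed = 5, n_restarts = 3)
  expect_identical(a, b)
  e2 <- a$reconstruction_error
  e3 <- extract_signatures(V, k = 3, seed = 5, n_restarts = 3)$reconstruction_error
  expect_lte(e3, e2 * (1 + 1e-6))
})

test_that("reference matching finds identical entries and labels novelty", {
  cat <- read_signature_catalog()
  m <- match_reference(cat[, "SBS26_like", drop = FALSE], cat)
  expect_equal(m$best_match, "SBS26_like")
  expect_equal(m$cosine, 1, tolerance = 1e-12)
  expect_false(m$novel)
  # orthogonal profile -> novel
  ortho <- matrix(0, 96, 1, dimnames = list(context_96_labels(), "x"))
  flatish <- cat %*% rep(1, ncol(cat))
  ortho[which.min(flatish), 1] <- 1 # mass on the least-supported class
  m2 <- match_reference(ortho, cat, novel_threshold = 0.80)
  expect_true(m2$novel)
  expect_error(match_reference(ortho, cat[, 0, drop = FALSE]), "empty")
})

test_that("noisy catalog copies are matched back to their source", {
  cat <- read_signature_catalog()
  set.seed(705)
  correct <- 0
  for (i in 1:60) {
    src <- sample(colnames(cat), 1)
    noisy <- rgamma(96, shape = cat[, src] * 1000)
    noisy <- noisy / sum(noisy)
    m <- match_reference(matrix(noisy, 96, 1,
                                dimnames = list(rownames(cat), "q")), cat)
    if (m$best_match == src) correct <- correct + 1
  }
  expect_gte(correct / 60, 0.95)
})
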