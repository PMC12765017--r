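# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (enumeration, literal formula
# evaluation, quadratic-space dynamic programming) and never call the
# package code paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumeration_oracle <- function(group1, group2) {
  tot <- group1 + group2
  n <- sum(tot)
  n1 <- sum(group1)
  ends <- cumsum(tot)
  starts <- c(1, head(ends, -1) + 1)
  mid <- (starts + ends) / 2
  vals <- rep(mid, tot)
  Wobs <- sum(rep(mid, group1))
  EW <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  Ws <- colSums(matrix(vals[combos], nrow = n1))
  mean(abs(Ws - EW) >= abs(Wobs - EW) - 1e-9)
}

# Literal gene-by-gene median-of-ratios size factors.
size_factor_oracle <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  apply(counts[ref, , drop = FALSE], 2, function(col) median(col / geo))
}

# Quadratic-space Gotoh global alignment score; gap of length L costs
# open + L * ext.
gotoh_score_oracle <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A residue unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE), collapse = "")
}

# Random variant table for filter-predicate oracles.
random_rna_variants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sample(paste0("S", 1:5), n, replace = TRUE),
    chrom = "chrS",
    pos = sample.int(1e5, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    filter_status = sample(c("PASS", "germline_risk"), n, replace = TRUE, prob = c(.8, .2)),
    depth = sample(5:60, n, replace = TRUE),
    alt_count = sample(0:30, n, replace = TRUE),
    allele_fraction = round(runif(n), 3),
    consequence = sample(c("missense", "synonymous", "splice_region",
                           "splice_acceptor", "splice_donor", "stop_gained"),
                         n, replace = TRUE),
    gene_id = sample(paste0("G", 1:40), n, replace = TRUE),
    transcript_id = "t1",
    hgvsp = "",
    source = "rna",
    stringsAsFactors = FALSE
  )
}

small_cohort <- function(seed = 11, ...) {
  generate_cohort(cohort_config(
    n_tumors_subtype1 = 6, n_tumors_subtype2 = 4, n_normals = 3,
    n_genes = 300, n_somatic_per_sample = 30, n_germline_per_sample = 30,
    seed = seed, ...))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
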