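#' Gene sets for the three expression scores
#'
#' Bundles the gene identifiers used by the thyroid differentiation score
#' (16 thyroid metabolism/function genes, supplied by configuration), the
#' MAPK pathway activation score (the 10 canonical downstream MAPK targets),
#' and the ERK output signature (up to 52 RAF-MEK-ERK target genes, of which
#' only the subset resolvable in the annotation is used and the number used
#' is recorded).
#'
#' @param tds_genes Character vector of exactly 16 gene ids.
#' @param mpas_genes Character vector of exactly 10 gene ids; defaults to
#'   CCND1, DUSP4, DUSP6, EPHA2, EPHA4, ETV4, ETV5, PHLDA1, SPRY2, SPRY4.
#' @param erk_genes Character vector of up to 52 gene ids.
#' @return List of class `score_gene_sets`.
#' @export
score_gene_sets <- function(tds_genes,
                            mpas_genes = c("CCND1", "DUSP4", "DUSP6", "EPHA2",
                                           "EPHA4", "ETV4", "ETV5", "PHLDA1",
                                           "SPRY2", "SPRY4"),
                            erk_genes = character()) {
  if (length(tds_genes) != 16 || anyDuplicated(tds_genes)) {
    stop("tds_genes must be 16 unique gene ids")
  }
  if (length(mpas_genes) != 10 || anyDuplicated(mpas_genes)) {
    stop("mpas_genes must be 10 unique gene ids")
  }
  if (length(erk_genes) > 52 || anyDuplicated(erk_genes)) {
    stop("erk_genes must be <= 52 unique gene ids")
  }
  structure(list(tds_genes = tds_genes, mpas_genes = mpas_genes,
                 erk_genes = erk_genes),
            class = "score_gene_sets")
}

#' Per-gene z-scores across the cohort
#'
#' Centers and scales each gene's log2 expression by its cohort mean and
#' (n-1) standard deviation. Genes with zero variance yield an all-zero row
#' rather than NaN.
#'
#' @param log_expr log2 expression matrix, genes x samples (>= 2 samples).
#' @return Matrix of the same shape.
#' @export
zscore_by_gene <- function(log_expr) {
  if (ncol(log_expr) < 2) stop("z-scoring needs >= 2 samples")
  m <- rowMeans(log_expr)
  s <- apply(log_expr, 1, stats::sd)
  z <- sweep(log_expr, 1, m)
  z <- sweep(z, 1, ifelse(s > 0, s, 1), "/")
  z[s == 0, ] <- 0
  z
}

#' MAPK pathway activation score
#'
#' Per sample, the sum of z-scores over the MPAS genes present in the matrix
#' divided by the square root of the number present:
#' \eqn{MPAS = \sum_i z_i / \sqrt{n}}.
#'
#' @param z Z-score matrix from [zscore_by_gene()].
#' @param sets A `score_gene_sets`.
#' @return Numeric vector per sample with attribute `n_genes_used`.
#' @export
mpas <- function(z, sets) {
  present <- intersect(sets$mpas_genes, rownames(z))
  if (length(present) == 0) stop("no MPAS genes present in the matrix")
  out <- colSums(z[present, , drop = FALSE]) / sqrt(length(present))
  attr(out, "n_genes_used") <- length(present)
  out
}

#' ERK output score
#'
#' Per sample, the mean z-score over the ERK signature genes present in the
#' matrix (the signature lists up to 52 genes; only those resolvable in the
#' annotation contribute, and the count used is recorded).
#'
#' @inheritParams mpas
#' @return Numeric vector per sample with attribute `n_genes_used`.
#' @export
erk_score <- function(z, sets) {
  present <- intersect(sets$erk_genes, rownames(z))
  if (length(present) == 0) stop("no ERK signature genes present in the matrix")
  out <- colMeans(z[present, , drop = FALSE])
  attr(out, "n_genes_used") <- length(present)
  out
}

#' Thyroid differentiation score
#'
#' For each of the 16 thyroid function genes the median log2 expression
#' across the analysis set is computed; each sample's TDS is the sum over
#' the 16 genes of (log2 value - gene median). High TDS indicates a well
#' differentiated, thyroid-function-retaining expression profile. Missing
#' TDS genes are an error (never silently dropped), since the score is only
#' comparable when computed over the full panel.
#'
#' @param log_expr log2 expression matrix, genes x samples.
#' @param sets A `score_gene_sets`.
#' @param median_samples Optional sample ids over which gene medians are
#'   taken (e.g. tumors only); defaults to all columns.
#' @return Numeric vector per sample.
#' @export
tds <- function(log_expr, sets, median_samples = NULL) {
  missing <- setdiff(sets$tds_genes, rownames(log_expr))
  if (length(missing)) {
    stop("TDS genes missing from the matrix: ", paste(missing, collapse = ", "))
  }
  x <- log_expr[sets$tds_genes, , drop = FALSE]
  ref <- if (is.null(median_samples)) x else x[, median_samples, drop = FALSE]
  med <- apply(ref, 1, stats::median)
  colSums(sweep(x, 1, med))
}

#' Transcriptome-wide correlation screen against a per-sample score
#'
#' Correlates every gene's expression with a score vector (Spearman by
#' default, Pearson optional), with two-sided p-values and Benjamini-
#' Hochberg FDR across all tested genes. Spearman p-values use the
#' t-approximation for n >= 10 and exact enumeration over permutations for
#' n <= 8 (t-approximation at n = 9).
#'
#' @param score Named numeric vector, one value per sample (>= 4 samples,
#'   non-constant).
#' @param log_expr Expression matrix with matching sample columns.
#' @param method `"spearman"` or `"pearson"`.
#' @return Data frame: `gene`, `coefficient`, `p`, `fdr`, ordered as the
#'   input genes.
#' @export
correlate_with_vector <- function(score, log_expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(score))) log_expr <- log_expr[, names(score), drop = FALSE]
  n <- length(score)
  if (n < 4) stop("need >= 4 samples")
  if (stats::sd(score) == 0) stop("score vector is constant")
  sv <- if (method == "spearman") rank(score) else score
  cf <- apply(log_expr, 1, function(g) {
    gv <- if (method == "spearman") rank(g) else g
    if (stats::sd(gv) == 0) return(NA_real_)
    stats::cor(sv, gv)
  })
  p <- vapply(seq_along(cf), function(i) {
    r <- cf[i]
    if (is.na(r)) return(NA_real_)
    if (method == "spearman" && n <= 8) {
      return(spearman_exact_p(sv, rank(log_expr[i, ])))
    }
    if (abs(r) >= 1) return(0)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }, numeric(1))
  data.frame(gene = rownames(log_expr), coefficient = unname(cf),
             p = p, fdr = bh_fdr(p), row.names = NULL)
}

# Exact two-sided Spearman p by full enumeration of permutations (n <= 8).
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- permutations_of(n)
  robs <- stats::cor(rx, ry)
  rs <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rs) >= abs(robs) - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pre-ranked gene set enrichment statistic
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight = |score|
#' with exponent 1) over a ranked gene list, with a permutation p-value from
#' random gene-label sets of the same size. The p-value is two-sided on |ES|:
#' p = (1 + #{|ES_perm| >= |ES_obs|}) / (n_permutations + 1).
#'
#' @param ranked_genes Character vector of gene ids, ordered by the ranking
#'   metric (no duplicates).
#' @param scores Numeric ranking metric aligned with `ranked_genes`.
#' @param gene_set Character vector of gene ids (non-empty intersection with
#'   the ranking required).
#' @param n_permutations Number of random-set permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `es`, `p`, `n_hits`, `running_sum`.
#' @export
preranked_enrichment <- function(ranked_genes, scores, gene_set,
                                 n_permutations = 1000, seed = 1) {
  if (anyDuplicated(ranked_genes)) stop("ranking has duplicate gene ids")
  hits <- ranked_genes %in% gene_set
  if (!any(hits)) stop("gene set has empty intersection with the ranking")
  es_of <- function(hit) {
    w <- abs(scores)
    inc <- ifelse(hit, w / sum(w[hit]), 0)
    dec <- ifelse(hit, 0, 1 / sum(!hit))
    rs <- cumsum(inc - dec)
    rs[which.max(abs(rs))]
  }
  es <- es_of(hits)
  rsum <- {
    w <- abs(scores)
    cumsum(ifelse(hits, w / sum(w[hits]), 0) - ifelse(hits, 0, 1 / sum(!hits)))
  }
  k <- sum(hits)
  set.seed(seed)
  perm <- replicate(n_permutations, {
    h <- logical(length(ranked_genes))
    h[sample.int(length(ranked_genes), k)] <- TRUE
    es_of(h)
  })
  p <- (1 + sum(abs(perm) >= abs(es))) / (n_permutations + 1)
  list(es = es, p = p, n_hits = k, running_sum = rsum)
}
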