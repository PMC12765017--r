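#' Construct a gene-by-sample expression matrix container
#'
#' Light S3 container for raw counts plus derived layers. Layers
#' (`normalized`, `log2`, `tpm`) are filled in by the normalization
#' functions; `size_factors` appear after [normalize_median_of_ratios()].
#'
#' @param counts Nonnegative integer matrix, genes x samples, with unique
#'   row (gene) and column (sample) names.
#' @param gene_lengths Optional positive integer vector of gene lengths in
#'   bases, named by gene or in row order (needed for [compute_tpm()]).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) names(gene_lengths) <- rownames(counts)
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene_lengths must be positive and cover all genes")
    }
  }
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         sample_ids = colnames(counts), gene_lengths = gene_lengths,
         layers = list(), size_factors = NULL),
    class = "expression_matrix"
  )
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; layers:", if (length(x$layers)) paste(names(x$layers), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Median-of-ratios normalization
#'
#' Per-sample size factors computed as the median, over reference genes, of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples. Reference genes are those with strictly positive counts in every
#' sample (the geometric mean of a gene with any zero is zero and the gene
#' is excluded). The normalized layer is counts divided by the sample's size
#' factor; the log2 layer is log2(normalized + 1).
#'
#' @param em An `expression_matrix`.
#' @return The input with `size_factors` set and `normalized`/`log2` layers.
#' @export
normalize_median_of_ratios <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$counts) < 2) stop("need >= 2 samples to normalize")
  ref <- rowSums(em$counts > 0) == ncol(em$counts)
  if (!any(ref)) stop("no gene has nonzero counts in every sample; cannot normalize")
  refc <- em$counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(refc)))
  em$size_factors <- apply(refc / geo, 2, stats::median)
  em$layers$normalized <- sweep(em$counts, 2, em$size_factors, "/")
  em$layers$log2 <- log2(em$layers$normalized + 1)
  em
}

#' Transcripts-per-million layer
#'
#' TPM for gene g in sample j is 1e6 times the length-normalized read rate,
#' rate = count / (length in kb), divided by the sample's total rate.
#'
#' @param em An `expression_matrix` with `gene_lengths`.
#' @return The input with a `tpm` layer added.
#' @export
compute_tpm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$gene_lengths)) stop("gene_lengths are required for TPM")
  rate <- em$counts / (em$gene_lengths / 1000)
  em$layers$tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  em
}

#' Filter genes by minimum read support
#'
#' Retains genes with at least `min_reads` reads in at least `min_samples`
#' samples (both thresholds inclusive), the standard pre-filter before
#' differential expression.
#'
#' @param em An `expression_matrix`.
#' @param min_reads,min_samples Inclusive thresholds (defaults 10 reads in
#'   5 samples).
#' @return A new `expression_matrix` restricted to retained genes (derived
#'   layers are dropped; re-normalize after filtering).
#' @export
filter_low_expression <- function(em, min_reads = 10, min_samples = 5) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- rowSums(em$counts >= min_reads) >= min_samples
  expression_matrix(em$counts[keep, , drop = FALSE],
                    if (!is.null(em$gene_lengths)) em$gene_lengths[keep] else NULL)
}

#' Select highly variable genes on the log2 scale
#'
#' A gene is selected when the mean of its log2 values exceeds
#' `mean_threshold` and the unbiased sample variance of its log2 values
#' exceeds `var_threshold` (both strict), mirroring the mean/variance gating
#' used to pick the gene subset for sample clustering.
#'
#' @param log_expr Numeric matrix of log2(normalized + 1) values, genes x
#'   samples.
#' @param mean_threshold,var_threshold Strict lower bounds (defaults 2, 6).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
select_variable_genes <- function(log_expr, mean_threshold = 2, var_threshold = 6) {
  m <- rowMeans(log_expr)
  v <- apply(log_expr, 1, stats::var)
  rownames(log_expr)[m > mean_threshold & v > var_threshold]
}

#' Embed and cluster samples on a variable-gene submatrix
#'
#' Computes a 2-D embedding of the samples restricted to `selected_genes`
#' and partitions the embedding into `n_clusters` groups with k-means.
#' The default embedding is the first two principal components, whose
#' between-cluster distances k-means can rely on; `method = "umap"` gives a
#' UMAP-style neighbor embedding (via the uwot package; 15 neighbors,
#' min_dist 0.1), better suited to visualization than to partitioning,
#' since neighbor embeddings distort between-cluster distances. Both are
#' deterministic given `seed`.
#'
#' @param log_expr log2 expression matrix, genes x samples.
#' @param selected_genes Gene ids to embed on (>= 2).
#' @param n_clusters Number of clusters to cut.
#' @param seed Integer seed.
#' @param method `"pca"` (default) or `"umap"` (falls back to PCA if uwot
#'   is unavailable).
#' @param scale_rows Standardize each selected gene across samples before
#'   embedding (default TRUE), so every selected gene contributes on a
#'   comparable scale.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return List of class `cluster_result`: `embedding` (samples x 2),
#'   `labels` (named integer vector), `selected_genes`, `params`.
#' @export
cluster_samples <- function(log_expr, selected_genes, n_clusters, seed,
                            method = c("pca", "umap"), scale_rows = TRUE,
                            n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  if (length(selected_genes) < 2) stop("need >= 2 selected genes")
  if (ncol(log_expr) < n_clusters) stop("fewer samples than clusters requested")
  missing <- setdiff(selected_genes, rownames(log_expr))
  if (length(missing)) stop("selected genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  sub <- log_expr[selected_genes, , drop = FALSE]
  if (scale_rows) sub <- zscore_by_gene(sub)
  x <- t(sub) # samples x genes
  if (method == "umap" && !requireNamespace("uwot", quietly = TRUE)) method <- "pca"
  if (method == "umap") {
    nn <- min(n_neighbors, nrow(x) - 1)
    set.seed(seed)
    emb <- uwot::umap(x, n_neighbors = nn, min_dist = min_dist,
                      n_threads = 1, n_sgd_threads = 1)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    emb <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    if (ncol(emb) < 2) emb <- cbind(emb, 0)
  }
  rownames(emb) <- colnames(log_expr)
  colnames(emb) <- c("dim1", "dim2")
  set.seed(seed)
  km <- stats::kmeans(emb, centers = n_clusters, nstart = 25)
  labels <- stats::setNames(km$cluster, colnames(log_expr))
  structure(list(embedding = emb, labels = labels,
                 selected_genes = selected_genes,
                 params = list(method = method, n_clusters = n_clusters,
                               seed = seed, n_neighbors = n_neighbors,
                               min_dist = min_dist)),
            class = "cluster_result")
}

#' Flag differentially expressed genes from a fold-change / p table
#'
#' Applies the strict thresholds |log2FC| > `lfc_threshold` and adjusted
#' p < `p_threshold`; direction follows the sign of the fold change
#' (positive = up in group 1). The fold-change/p engine itself is pluggable
#' (any per-gene table will do).
#'
#' @param stats_table Data frame with columns `gene`, `log2fc`, `padj`.
#' @param lfc_threshold,p_threshold Strict thresholds (defaults 2, 0.05).
#' @return The table with `direction` ("up_group1"/"up_group2") and logical
#'   `passes` columns added.
#' @export
select_differential_genes <- function(stats_table, lfc_threshold = 2, p_threshold = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(stats_table)))
  if (any(stats_table$padj < 0 | stats_table$padj > 1, na.rm = TRUE)) {
    stop("adjusted p-values out of [0, 1]")
  }
  stats_table$direction <- ifelse(stats_table$log2fc >= 0, "up_group1", "up_group2")
  stats_table$passes <- abs(stats_table$log2fc) > lfc_threshold &
    !is.na(stats_table$padj) & stats_table$padj < p_threshold
  stats_table
}
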