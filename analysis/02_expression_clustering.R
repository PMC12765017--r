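#!/usr/bin/env Rscript
# Normalize the simulated counts (median of ratios), select variable genes
# on the log2 scale, embed and cluster the samples, and compare the cluster
# labels with the planted subtype truth. Writes results/clusters.csv.

library(caninetc)

counts <- read_counts_tsv("results/cohort/counts.tsv")
em <- normalize_median_of_ratios(expression_matrix(counts))

# variance gate matched to the generator's noise level (see methods vignette)
hv <- select_variable_genes(em$layers$log2, mean_threshold = 2, var_threshold = 1)
cat("variable genes selected:", length(hv), "\n")

cr <- cluster_samples(em$layers$log2, hv, n_clusters = 3, seed = 1)
truth <- ifelse(grepl("^T1_", names(cr$labels)), "subtype1",
                ifelse(grepl("^T2_", names(cr$labels)), "subtype2", "normal"))
print(table(cluster = cr$labels, truth = truth))
if (requireNamespace("mclust", quietly = TRUE)) {
  cat("adjusted Rand index vs truth:",
      mclust::adjustedRandIndex(cr$labels, truth), "\n")
}

out <- data.frame(sample = names(cr$labels),
                  dim1 = cr$embedding[, 1], dim2 = cr$embedding[, 2],
                  cluster = unname(cr$labels))
write.csv(out, "results/clusters.csv", row.names = FALSE)
cat("wrote results/clusters.csv\n")

# differential flags between the two tumor clusters from a simple
# normalized-mean fold change + rank-sum p table
le <- em$layers$log2
t1 <- colnames(le)[grepl("^T1_", colnames(le))]
t2 <- colnames(le)[grepl("^T2_", colnames(le))]
stats_tab <- data.frame(
  gene = rownames(le),
  log2fc = rowMeans(le[, t1]) - rowMeans(le[, t2]),
  padj = bh_fdr(apply(le, 1, function(g)
    suppressWarnings(wilcox.test(g[t1], g[t2])$p.value)))
)
deg <- select_differential_genes(stats_tab)
cat("genes passing |log2FC| > 2 and adjusted p < 0.05:", sum(deg$passes),
    "( up in cluster 1:", sum(deg$passes & deg$direction == "up_group1"),
    "; up in cluster 2:", sum(deg$passes & deg$direction == "up_group2"), ")\n")
write.csv(deg[deg$passes, ], "results/differential_genes.csv", row.names = FALSE)
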