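#!/usr/bin/env Rscript
# Cross-species protein-position mapping: align each simulated ortholog
# pair, project a batch of substitution variants from the source (dog)
# protein onto the target (human) protein, and verify against the planted
# residue correspondence. Writes results/ortholog_projection.tsv.

library(caninetc)

cfg <- read_cohort_config("results/cohort/config.yaml")
cohort <- generate_cohort(cfg)

# one substitution per ortholog, placed on a mapped residue
variants <- do.call(rbind, lapply(cohort$ortholog_pairs, function(o) {
  p <- which(!is.na(o$truth_map))[25]
  refres <- substr(o$source_seq, p, p)
  alt <- setdiff(c("A", "V"), refres)[1]
  data.frame(gene_id = o$gene, hgvsp = paste0("p.", refres, p, alt),
             truth_target_pos = o$truth_map[p])
}))

proj <- project_variants(variants, "results/cohort/orthologs.fasta")
proj$truth_target_pos <- variants$truth_target_pos
proj$agrees <- proj$target_pos == proj$truth_target_pos
print(proj, row.names = FALSE)
cat("projections agreeing with planted correspondence:",
    sum(proj$agrees), "/", nrow(proj), "\n")
write.table(proj, "results/ortholog_projection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/ortholog_projection.tsv\n")
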