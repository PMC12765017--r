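#!/usr/bin/env Rscript
# Variant post-processing on the simulated cohort: the exome somatic filter
# cascade against the matched normals, the RNA-seq variant filter, recovery
# of the planted germline/somatic truth, and per-sample mutational burden.
# Writes results/somatic_variants.tsv and results/tmb.csv.

library(caninetc)

wes_tumor <- read_variants_vcf("results/cohort/wes_tumor.vcf", "wes_tumor")
wes_normal <- read_variants_vcf("results/cohort/wes_normal.vcf", "wes_normal")
rna <- read_variants_vcf("results/cohort/rna.vcf", "rna")
truth <- read.delim("results/cohort/truth_genotype.tsv")

res <- germline_resources(matched_normals = wes_normal)
somatic <- wes_somatic_filter(wes_tumor, res)
vid <- paste(somatic$sample_id, somatic$chrom, somatic$pos, somatic$ref,
             somatic$alt, sep = ":")
truth_som <- truth$variant_id[truth$genotype == "somatic"]
cat("somatic filter:", nrow(somatic), "calls retained of", nrow(wes_tumor), "\n")
cat("  precision vs planted truth:", round(mean(vid %in% truth_som), 4),
    "; recall:", round(mean(truth_som %in% vid), 4), "\n")

rna_kept <- rna_variant_filter(rna, res)
cat("RNA filter:", nrow(rna_kept), "of", nrow(rna),
    "calls pass DP/alt-count/AF/splice rules\n")

write_maf_tsv(somatic, "results/somatic_variants.tsv")

# burden per sample over a 50 Mb exome capture
tmb <- vapply(split(somatic, somatic$sample_id), compute_tmb,
              megabases_sequenced = 50, numeric(1))
cat(sprintf("mutational burden: mean %.2f +/- %.2f non-synonymous/Mb\n",
            mean(tmb), sd(tmb)))
write.csv(data.frame(sample = names(tmb), tmb_per_mb = tmb),
          "results/tmb.csv", row.names = FALSE)
cat("wrote results/somatic_variants.tsv and results/tmb.csv\n")
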