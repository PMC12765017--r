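#!/usr/bin/env Rscript
# Simulate the study-scale cohort every later stage consumes: 25 + 5 tumors
# of the two subtypes plus 5 normal thyroid samples, with planted subtype
# markers, a thyroid-differentiation gradient, germline/somatic variant
# truth, fusion artifacts and size-dependent survival. Writes the full file
# bundle under results/cohort/.

library(caninetc)

cfg <- cohort_config(seed = 20260926L)
cohort <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
manifest <- write_cohort(cohort, "results/cohort")
write_cohort_config(cfg, "results/cohort/config.yaml")

cat("Simulated cohort:\n")
cat("  samples:", length(cohort$expression$sample_ids),
    "(", sum(cohort$truth_subtype == "subtype1"), "subtype-1 tumors,",
    sum(cohort$truth_subtype == "subtype2"), "subtype-2 tumors,",
    sum(cohort$truth_subtype == "normal"), "normals )\n")
cat("  genes:", length(cohort$expression$gene_ids), "\n")
cat("  tumor exome calls:", nrow(cohort$wes_tumor_variants),
    "| RNA calls:", nrow(cohort$rna_variants), "\n")
cat("  fusion calls:", nrow(cohort$fusion_calls), "\n")
cat("  files written:\n")
print(manifest)
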