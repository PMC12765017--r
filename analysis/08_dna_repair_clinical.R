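#!/usr/bin/env Rscript
# DNA-repair pathway genotyping on the packaged cohort variant table, the
# MSI-score association on the simulated cohort, the ordinal
# clinicopathologic comparisons on the packaged clinical table, and the
# size-dependent survival model. Writes results/drp_summary.csv and
# results/clinical_tests.csv.

library(caninetc)

## cohort DNA-repair variant table -------------------------------------------
tab <- read_drp_table()
roster <- read_cohort_roster()
sets <- repair_pathway_sets(read_gmt(system.file(
  "extdata", "dna_repair_pathways.gmt", package = "caninetc")))
tab <- map_pathways(tab, sets)
summ <- summarize_drp(tab, roster)
cat(sprintf("repair-pathway variants: %d variants in %d genes across %d/%d tumors (%.0f%%)\n",
            summ$n_variants, summ$n_genes, summ$n_samples_mutated,
            length(roster), 100 * summ$fraction_of_cohort))
cat("genotype partition:\n"); print(summ$genotype_counts)
cat("pathway memberships:\n"); print(summ$pathway_counts)
write.csv(data.frame(metric = c("n_variants", "n_genes", "n_samples_mutated",
                                "fraction_of_cohort"),
                     value = c(summ$n_variants, summ$n_genes,
                               summ$n_samples_mutated, summ$fraction_of_cohort)),
          "results/drp_summary.csv", row.names = FALSE)

## MSI association on the simulated cohort ------------------------------------
cl <- read.csv("results/cohort/clinical.csv")
msi <- msi_association(setNames(cl$msi_score, cl$sample_id),
                       cl$sample_id[cl$drp_mutant])
cat(sprintf("MSI score, repair-mutant (n=%d) vs non-mutant (n=%d): W = %.0f, p = %.4g\n",
            msi$n_mutant, msi$n_nonmutant, msi$W, msi$p))

## ordinal clinicopathologic comparisons --------------------------------------
clin <- read_clinical_table()
cmp <- function(column, levels) {
  ftc <- table(factor(clin[[column]][clin$subtype_calcitonin == "FTC"], levels))
  mtc <- table(factor(clin[[column]][clin$subtype_calcitonin == "MTC"], levels))
  mann_whitney(as.vector(mtc), as.vector(ftc), mode = "exact")$p
}
tests <- data.frame(
  comparison = c("histologic_pattern", "differentiation", "nuclear_atypia",
                 "her2_asco", "her2_pena", "calcitonin_ihc"),
  p = c(cmp("histologic_pattern", c("follicular", "follicular-compact", "compact")),
        cmp("differentiation", c("well", "moderate", "poor")),
        cmp("nuclear_atypia", c("mild", "moderate", "marked")),
        cmp("her2_asco", c("0", "1", "2", "3")),
        cmp("her2_pena", c("0", "1", "2", "3")),
        cmp("calcitonin_ihc", c("negative", "positive"))))
print(tests, row.names = FALSE)
write.csv(tests, "results/clinical_tests.csv", row.names = FALSE)

## survival: tumor size and outcome on the simulated cohort -------------------
big <- cl$tumor_diameter_cm > median(cl$tumor_diameter_cm)
km <- km_logrank(cl$survival_days, cl$event,
                 ifelse(big, "large", "small"),
                 exclude = cl$metastasis_at_diagnosis,
                 hr_reference = "small")
cat(sprintf("survival, large vs small tumors (metastatic excluded, n=%d dropped):\n",
            km$n_excluded))
cat(sprintf("  log-rank p = %.3g; HR = %.2f [%.2f, %.2f]\n",
            km$logrank_p, km$hr, km$hr_ci[1], km$hr_ci[2]))
cat("wrote results/drp_summary.csv and results/clinical_tests.csv\n")
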