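#!/usr/bin/env Rscript
# 96-type substitution spectra of the recovered somatic variants, de novo
# signature extraction by KL-divergence NMF, and matching against the
# packaged (synthetic stand-in) reference catalog.
# Writes results/spectra.csv and results/signature_matches.csv.

library(caninetc)

wes_tumor <- read_variants_vcf("results/cohort/wes_tumor.vcf", "wes_tumor")
wes_normal <- read_variants_vcf("results/cohort/wes_normal.vcf", "wes_normal")
somatic <- wes_somatic_filter(wes_tumor,
                              germline_resources(matched_normals = wes_normal))

# rebuild the trinucleotide context map from the generator config
cfg <- read_cohort_config("results/cohort/config.yaml")
cohort <- generate_cohort(cfg)
spectra <- build_spectrum(somatic, cohort$reference_context)
cat("spectra built for", ncol(spectra), "samples;",
    sum(spectra), "substitutions binned\n")
write.csv(data.frame(type = rownames(spectra), spectra, check.names = FALSE),
          "results/spectra.csv", row.names = FALSE)

fit <- extract_signatures(spectra, k = 3, seed = 11, n_restarts = 10)
cat("rank-3 factorization, KL reconstruction error:",
    round(fit$reconstruction_error, 1), "\n")

catalog <- read_signature_catalog()
matches <- match_reference(fit, catalog)
print(matches, row.names = FALSE)
write.csv(matches, "results/signature_matches.csv", row.names = FALSE)
cat("wrote results/spectra.csv and results/signature_matches.csv\n")
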