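Package: caninetc
Title: Genomic and Transcriptomic Characterization of Canine Thyroid Carcinoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for two-subtype (follicular versus medullary)
    canine thyroid carcinoma cohorts: median-of-ratios normalization,
    variable-gene selection and sample clustering; thyroid differentiation
    (TDS), MAPK pathway activation (MPAS) and ERK output scores with
    transcriptome-wide correlation screens and pre-ranked enrichment;
    somatic and RNA variant filter cascades with tumor mutational burden;
    96-type mutational spectra with de novo signature extraction by
    Kullback-Leibler nonnegative matrix factorization and reference-catalog
    matching; gene-fusion artifact filtering and recurrence counting;
    cross-species protein-position mapping via global pairwise alignment;
    DNA-repair-pathway genotype classification; and the exact and asymptotic
    clinicopathologic statistics (tied Mann-Whitney, Kruskal-Wallis,
    Kaplan-Meier/log-rank/Cox). A synthetic cohort generator reproduces the
    statistical structure every stage assumes, so the full pipeline is
    exercisable without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    survival,
    tools,
    utils,
    vcfR
Suggests:
    DESeq2,
    fgsea,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    uwot,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
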