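test_that("generation is byte-identical for the same config and seed", {
  cfg <- cohort_config(n_tumors_subtype1 = 4, n_tumors_subtype2 = 3,
                       n_normals = 2, n_genes = 150,
                       n_somatic_per_sample = 20, n_germline_per_sample = 20,
                       seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_genes = 0), "n_genes")
  expect_error(cohort_config(censoring_rate = 1.5), "censoring_rate")
  expect_error(cohort_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(cohort_config(signature_mixture = c(ct_only = 0.5)), "sum to 1")
  expect_error(cohort_config(signature_mixture = c(nope = 1)), "built-in")
})

test_that("a zero marker effect leaves subtype marker means indistinguishable", {
  co <- generate_cohort(cohort_config(
    n_tumors_subtype1 = 10, n_tumors_subtype2 = 10, n_normals = 2,
    n_genes = 200, marker_log2_effect = 0, n_marker_genes_per_subtype = 50,
    seed = 13))
  em <- normalize_median_of_ratios(co$expression)
  le <- em$layers$log2
  s1 <- names(co$truth_subtype)[co$truth_subtype == "subtype1"]
  s2 <- names(co$truth_subtype)[co$truth_subtype == "subtype2"]
  markers <- grep("^M1_", rownames(le), value = TRUE)
  d <- rowMeans(le[markers, s1]) - rowMeans(le[markers, s2])
  tt <- t.test(d)
  expect_gt(tt$p.value, 0.01)
})

test_that("cohort invariants: truth coverage, roster consistency, contexts", {
  co <- small_cohort(seed = 71)
  all_ids <- unique(c(
    paste(co$wes_tumor_variants$sample_id, co$wes_tumor_variants$chrom,
          co$wes_tumor_variants$pos, co$wes_tumor_variants$ref,
          co$wes_tumor_variants$alt, sep = ":"),
    paste(co$wes_normal_variants$sample_id, co$wes_normal_variants$chrom,
          co$wes_normal_variants$pos, co$wes_normal_variants$ref,
          co$wes_normal_variants$alt, sep = ":")))
  expect_true(all(names(co$truth_genotype) %in% all_ids))
  expect_true(all(co$clinical$sample_id %in% co$expression$sample_ids))
  expect_true(all(grepl("^[ACGT]{3}$", co$reference_context)))
  # germline variants appear in both tumor and matched normal; somatic only in tumor
  germ <- names(co$truth_genotype)[co$truth_genotype == "germline"]
  norm_ids <- paste(co$wes_normal_variants$sample_id, co$wes_normal_variants$chrom,
                    co$wes_normal_variants$pos, co$wes_normal_variants$ref,
                    co$wes_normal_variants$alt, sep = ":")
  expect_true(all(germ %in% norm_ids))
  som <- names(co$truth_genotype)[co$truth_genotype == "somatic"]
  expect_false(any(som %in% norm_ids))
})

test_that("pooled somatic spectra track the configured signature mixture", {
  co <- generate_cohort(cohort_config(
    n_tumors_subtype1 = 10, n_tumors_subtype2 = 5, n_normals = 2,
    n_genes = 100, n_somatic_per_sample = 150, n_germline_per_sample = 10,
    seed = 23))
  res <- germline_resources(matched_normals = co$wes_normal_variants)
  som <- wes_somatic_filter(co$wes_tumor_variants, res)
  sp <- rowSums(build_spectrum(som, co$reference_context))
  expect_gte(sum(sp), 2000)
  sigs <- builtin_signatures()
  w <- co$config$signature_mixture
  mix <- Reduce(`+`, Map(`*`, w, sigs[names(w)]))
  cosine <- sum(sp * mix) / sqrt(sum(sp^2) * sum(mix^2))
  expect_gte(cosine, 0.95)
})

test_that("survival times reflect the planted size-dependent hazard", {
  co <- generate_cohort(cohort_config(
    n_tumors_subtype1 = 150, n_tumors_subtype2 = 50, n_normals = 2,
    n_genes = 60, n_somatic_per_sample = 5, n_germline_per_sample = 5,
    size_log_hazard_ratio = 0.4, censoring_rate = 0.2, seed = 31))
  cl <- co$clinical
  fit <- survival::coxph(survival::Surv(survival_days, event) ~ tumor_diameter_cm,
                         data = cl)
  est <- unname(coef(fit))
  expect_gt(est, 0.2)
  expect_lt(est, 0.6)
})

test_that("write/read round trip preserves counts and variant keys", {
  co <- small_cohort(seed = 81)
  d <- withr::local_tempdir()
  manifest <- write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, manifest$file))))
  counts <- read_counts_tsv(file.path(d, "counts.tsv"))
  expect_equal(counts, co$expression$counts)
  wt <- read_variants_vcf(file.path(d, "wes_tumor.vcf"), "wes_tumor")
  key <- function(v) sort(paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  expect_equal(key(wt), key(co$wes_tumor_variants))
  # depths and allele fractions survive the round trip
  ord <- order(wt$sample_id, wt$pos)
  ord0 <- order(co$wes_tumor_variants$sample_id, co$wes_tumor_variants$pos)
  expect_equal(wt$depth[ord], co$wes_tumor_variants$depth[ord0])
  fus <- read_fusion_tsv(file.path(d, "fusions.tsv"))
  expect_equal(nrow(fus), nrow(co$fusion_calls))
})

test_that("manifest checksums change exactly when file contents change", {
  co <- small_cohort(seed = 82)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_cohort(co, d1)
  m2 <- write_cohort(co, d2)
  expect_equal(m1$md5, m2$md5)
  # perturb one record and re-checksum
  lines <- readLines(file.path(d2, "clinical.csv"))
  lines[2] <- sub(",", ",X", lines[2])
  writeLines(lines, file.path(d2, "clinical.csv"))
  m3 <- tools::md5sum(file.path(d2, "clinical.csv"))
  expect_false(unname(m3) == m1$md5[m1$file == "clinical.csv"])
})

test_that("config YAML round trip", {
  skip_if_not_installed("yaml")
  cfg <- cohort_config(n_tumors_subtype1 = 7, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f)
  cfg2 <- read_cohort_config(f)
  expect_equal(cfg, cfg2)
})
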