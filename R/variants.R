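#' @name variant-tables
#' @title Variant tables
#' @description
#' Variants travel through the pipeline as plain data frames with one row
#' per (variant, annotation) and the columns: `sample_id`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `filter_status`, `depth`, `alt_count`,
#' `allele_fraction`, `consequence`, `gene_id`, `transcript_id`, `hgvsp`,
#' `source` (one of `wes_tumor`, `wes_normal`, `rna`). Not every stage needs
#' every column; each operation states its requirements.
NULL

# Consequence terms treated as splice variants by the RNA filter.
SPLICE_TERMS <- c("splice_acceptor", "splice_donor", "splice_region")

# Consequence terms counted as non-synonymous protein-coding for burden.
NONSYNONYMOUS_TERMS <- c("missense", "stop_gained", "stop_lost", "start_lost",
                         "frameshift", "inframe_insertion", "inframe_deletion")

variant_site_key <- function(v) {
  paste(v$chrom, v$pos, toupper(v$ref), toupper(v$alt), sep = ":")
}

#' Germline subtraction resources
#'
#' The three site collections the somatic filter subtracts: per-sample
#' matched-normal calls, a panel-of-normals site blacklist, and an external
#' population germline resource. Sites are keyed as chrom:pos:REF:ALT with
#' uppercase alleles.
#'
#' @param matched_normals Data frame of normal-sample variant calls (columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`); `sample_id` must name the
#'   tumor the normal is matched to.
#' @param panel_of_normals,population_sites Character vectors of site keys,
#'   or data frames with `chrom`, `pos`, `ref`, `alt`.
#' @return List of class `germline_resources`.
#' @export
germline_resources <- function(matched_normals = NULL, panel_of_normals = character(),
                               population_sites = character()) {
  as_keys <- function(x) {
    if (is.data.frame(x)) variant_site_key(x) else as.character(x)
  }
  mn <- if (is.null(matched_normals) || nrow(matched_normals) == 0) {
    data.frame(sample_id = character(), key = character())
  } else {
    data.frame(sample_id = matched_normals$sample_id,
               key = variant_site_key(matched_normals))
  }
  structure(list(matched_normals = mn,
                 panel_of_normals = unique(as_keys(panel_of_normals)),
                 population_sites = unique(as_keys(population_sites))),
            class = "germline_resources")
}

#' Somatic filter cascade for tumor whole-exome variants
#'
#' Retains tumor variants that carry the caller's PASS filter status and are
#' absent from (i) the sample's matched-normal calls, (ii) the
#' panel-of-normals blacklist, and (iii) the external population germline
#' resource. Row order is preserved. Every tumor sample must have an entry
#' in the matched-normal index (possibly with zero calls) -- an absent
#' matched normal is an error naming the sample, since without one the
#' germline subtraction is incomplete.
#'
#' @param tumor_variants Variant data frame (`source = "wes_tumor"` rows).
#' @param resources A [germline_resources()] object.
#' @param matched_samples Character vector of tumor sample ids that have a
#'   matched normal; defaults to the samples present in the matched-normal
#'   index.
#' @return The retained (somatic) subset of `tumor_variants`.
#' @export
wes_somatic_filter <- function(tumor_variants, resources,
                               matched_samples = NULL) {
  stopifnot(inherits(resources, "germline_resources"))
  if (is.null(matched_samples)) {
    matched_samples <- unique(resources$matched_normals$sample_id)
  }
  unmatched <- setdiff(unique(tumor_variants$sample_id), matched_samples)
  if (length(unmatched)) {
    stop("no matched normal for sample(s): ", paste(unmatched, collapse = ", "))
  }
  key <- variant_site_key(tumor_variants)
  in_normal <- paste(tumor_variants$sample_id, key) %in%
    paste(resources$matched_normals$sample_id, resources$matched_normals$key)
  keep <- tumor_variants$filter_status == "PASS" &
    !in_normal &
    !(key %in% resources$panel_of_normals) &
    !(key %in% resources$population_sites)
  tumor_variants[keep, , drop = FALSE]
}

#' Filter cascade for RNA-seq variant calls
#'
#' RNA calls have no matched normal; instead the filter requires read depth
#' strictly greater than `min_depth`, alternate allele count strictly greater
#' than `min_alt`, a non-splice consequence, allele fraction within
#' [`af_low`, `af_high`] (inclusive), and absence from the panel-of-normals
#' and population germline sites.
#'
#' @param rna_variants Variant data frame with `depth`, `alt_count`,
#'   `allele_fraction`, `consequence` populated.
#' @param resources A [germline_resources()] object (matched normals unused).
#' @param min_depth,min_alt Strict lower bounds (defaults 10, 5).
#' @param af_low,af_high Inclusive allele-fraction bounds (defaults 0.25,
#'   0.85).
#' @return The retained subset, order preserved.
#' @export
rna_variant_filter <- function(rna_variants, resources,
                               min_depth = 10, min_alt = 5,
                               af_low = 0.25, af_high = 0.85) {
  stopifnot(inherits(resources, "germline_resources"))
  key <- variant_site_key(rna_variants)
  keep <- rna_variants$depth > min_depth &
    rna_variants$alt_count > min_alt &
    !(rna_variants$consequence %in% SPLICE_TERMS) &
    rna_variants$allele_fraction >= af_low &
    rna_variants$allele_fraction <= af_high &
    !(key %in% resources$panel_of_normals) &
    !(key %in% resources$population_sites)
  rna_variants[keep, , drop = FALSE]
}

#' Reduce multi-transcript annotations to the canonical isoform
#'
#' Each variant (sample, chrom, pos, ref, alt) may carry one annotation row
#' per overlapping transcript; this keeps exactly the row whose
#' `transcript_id` is the gene's canonical transcript. Variants whose gene
#' is absent from the table, or whose canonical transcript has no annotation
#' row, keep their first row and are flagged rather than dropped.
#'
#' @param variants Variant data frame with `gene_id`, `transcript_id`.
#' @param transcript_table Data frame with columns `gene_id`,
#'   `canonical_transcript`.
#' @return One row per variant with a logical `canonical_flagged` column
#'   (TRUE = no canonical annotation was available).
#' @export
map_canonical <- function(variants, transcript_table) {
  stopifnot(all(c("gene_id", "canonical_transcript") %in% names(transcript_table)))
  canon <- stats::setNames(transcript_table$canonical_transcript,
                           transcript_table$gene_id)
  vkey <- paste(variants$sample_id, variant_site_key(variants))
  out <- do.call(rbind, lapply(split(seq_len(nrow(variants)), vkey), function(idx) {
    rows <- variants[idx, , drop = FALSE]
    ct <- canon[rows$gene_id[1]]
    hit <- !is.na(ct) && any(rows$transcript_id == ct)
    row <- if (hit) rows[which(rows$transcript_id == ct)[1], , drop = FALSE]
           else rows[1, , drop = FALSE]
    row$canonical_flagged <- !hit
    row
  }))
  # restore input variant order (first occurrence of each variant)
  first <- !duplicated(vkey)
  out <- out[match(vkey[first], paste(out$sample_id, variant_site_key(out))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' Count of non-synonymous protein-coding somatic variants divided by the
#' number of megabases sequenced (the summed length of the exome capture
#' target, supplied by the caller).
#'
#' @param somatic_variants Variant data frame with `consequence`.
#' @param megabases_sequenced Positive capture size in Mb.
#' @return Mutations per megabase (a single number).
#' @export
compute_tmb <- function(somatic_variants, megabases_sequenced) {
  if (megabases_sequenced <= 0) stop("megabases_sequenced must be positive")
  sum(somatic_variants$consequence %in% NONSYNONYMOUS_TERMS) / megabases_sequenced
}

#' Select genes for the cohort mutation oncoplot
#'
#' A gene enters the oncoplot when it satisfies any of: (a) it is a known
#' cancer gene mutated in at least `recurrence_fraction` of the samples
#' (ceiling convention: at least `ceil(fraction * n_samples)` distinct
#' samples); (b) it is mutated in exactly one sample and at least one of its
#' variants is predicted to be a cancer driver; (c) it is a thyroid-panel
#' gene with recurrent mutations at the same threshold as (a). All
#' applicable reasons are recorded.
#'
#' @param variants Variant data frame with `gene_id`, `sample_id`.
#' @param cancer_genes,thyroid_genes Character vectors of gene ids.
#' @param driver_predictions Named character vector, variant key
#'   (`sample:chrom:pos:ref:alt`) -> `"driver"`/`"passenger"`; unscored
#'   variants default to passenger.
#' @param n_samples Cohort size used as the recurrence denominator (the
#'   per-assay sample count).
#' @param recurrence_fraction Recurrence threshold (default 0.10).
#' @return Data frame `gene`, `reasons` (comma-joined), `n_samples_mutated`.
#' @export
select_oncoplot_genes <- function(variants, cancer_genes, driver_predictions,
                                  thyroid_genes, n_samples,
                                  recurrence_fraction = 0.10) {
  need <- ceiling(recurrence_fraction * n_samples)
  vkey <- paste(variants$sample_id, variant_site_key(variants), sep = ":")
  is_driver <- !is.na(driver_predictions[vkey]) & driver_predictions[vkey] == "driver"
  per_gene <- split(seq_len(nrow(variants)), variants$gene_id)
  rows <- lapply(names(per_gene), function(g) {
    idx <- per_gene[[g]]
    nsamp <- length(unique(variants$sample_id[idx]))
    reasons <- character()
    if (g %in% cancer_genes && nsamp >= need) reasons <- c(reasons, "recurrent_cancer_gene")
    if (nsamp == 1 && any(is_driver[idx])) reasons <- c(reasons, "singleton_driver")
    if (g %in% thyroid_genes && nsamp >= need) reasons <- c(reasons, "recurrent_thyroid_gene")
    if (!length(reasons)) return(NULL)
    data.frame(gene = g, reasons = paste(reasons, collapse = ","),
               n_samples_mutated = nsamp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), reasons = character(),
                      n_samples_mutated = integer())
  }
  rownames(out) <- NULL
  out
}
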