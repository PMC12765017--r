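#' Default same-gene-family predicate for fusion partners
#'
#' Two symbols are treated as members of the same gene family when they are
#' identical after stripping a trailing integer suffix (PBX2 / PBX3 -> PBX).
#' This is an approximation of gene-family membership sufficient for the
#' artifact class it screens; callers can substitute any predicate.
#'
#' @param a,b Gene symbols.
#' @return Logical.
#' @export
same_family_suffix <- function(a, b) {
  strip <- function(s) sub("[0-9]+$", "", s)
  sa <- strip(a); sb <- strip(b)
  nzchar(sa) && nzchar(sb) && sa == sb
}

#' Apply the four fusion-artifact filters
#'
#' Removes, in order and recording the first matching reason per call:
#' (a) `same_family` -- both partners from the same gene family;
#' (b) `unofficial_name` -- a partner without an official gene symbol
#' (membership in `official_symbols` when supplied, otherwise a
#' placeholder-prefix rule rejecting LOC/ENSCAF-style ids);
#' (c) `cohort_frequency` -- the fusion is called in more than
#' `cohort_fraction` of the tumor samples (strict, tumors-only denominator);
#' (d) `present_in_normals` -- the fusion is also called in a normal tissue
#' sample. The fusion identity for frequency/normal/recurrence bookkeeping
#' is the ordered 5'->3' pair; the family test compares the two partners
#' directly.
#'
#' @param calls Data frame with columns `sample_id`, `gene_5p`, `gene_3p`
#'   (and optionally `junction_reads`, `spanning_frags`).
#' @param normal_sample_ids Sample ids that are normal tissue.
#' @param official_symbols Character vector of official symbols, or `NULL`
#'   to use the placeholder-prefix rule.
#' @param n_tumor_samples Number of tumor samples in the cohort (the
#'   denominator for criterion c).
#' @param cohort_fraction Strict frequency threshold (default 0.80).
#' @param family_predicate Function (a, b) -> logical for criterion a.
#' @return List of class `fusion_filter_report`: `retained`, `removed`
#'   (with a `reason` column), `recurrence` (named counts of distinct tumor
#'   samples per retained fusion).
#' @export
filter_fusions <- function(calls, normal_sample_ids, official_symbols = NULL,
                           n_tumor_samples,
                           cohort_fraction = 0.80,
                           family_predicate = same_family_suffix) {
  fid <- paste(calls$gene_5p, calls$gene_3p, sep = "--")
  is_normal <- calls$sample_id %in% normal_sample_ids
  official <- function(sym) {
    if (!is.null(official_symbols)) return(sym %in% official_symbols)
    !grepl("^(LOC[0-9]|ENSCAF)", sym)
  }
  # per-fusion tumor frequency and presence in normals
  tumor_n <- tapply(calls$sample_id[!is_normal], fid[!is_normal],
                    function(s) length(unique(s)))
  in_normal <- unique(fid[is_normal])
  reason <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (family_predicate(calls$gene_5p[i], calls$gene_3p[i])) {
      reason[i] <- "same_family"
    } else if (!official(calls$gene_5p[i]) || !official(calls$gene_3p[i])) {
      reason[i] <- "unofficial_name"
    } else if (!is.na(tumor_n[fid[i]]) &&
               tumor_n[fid[i]] / n_tumor_samples > cohort_fraction) {
      reason[i] <- "cohort_frequency"
    } else if (fid[i] %in% in_normal) {
      reason[i] <- "present_in_normals"
    }
  }
  retained <- calls[is.na(reason) & !is_normal, , drop = FALSE]
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  structure(list(retained = retained, removed = removed,
                 recurrence = count_recurrence(retained)),
            class = "fusion_filter_report")
}

#' Flag retained fusions involving known cancer genes
#'
#' @param retained Data frame of retained fusion calls.
#' @param cancer_genes Character vector of cancer gene symbols.
#' @return The input with a logical `cancer_gene_fusion` column.
#' @export
crossref_cancer_fusions <- function(retained, cancer_genes) {
  retained$cancer_gene_fusion <- retained$gene_5p %in% cancer_genes |
    retained$gene_3p %in% cancer_genes
  retained
}

#' Count distinct samples per fusion
#'
#' Recurrence is the number of distinct samples in which the ordered
#' 5'->3' fusion was called (repeat calls within a sample count once).
#'
#' @param retained Data frame of fusion calls.
#' @return Named integer vector, fusion id (`GENE5--GENE3`) -> sample count,
#'   sorted decreasing.
#' @export
count_recurrence <- function(retained) {
  if (nrow(retained) == 0) return(stats::setNames(integer(0), character(0)))
  fid <- paste(retained$gene_5p, retained$gene_3p, sep = "--")
  cnt <- tapply(retained$sample_id, fid, function(s) length(unique(s)))
  sort(stats::setNames(as.integer(cnt), names(cnt)), decreasing = TRUE)
}
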