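#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], character(1))
  sets
}

#' DNA repair pathway gene sets
#'
#' Wraps the four pathway gene sets -- mismatch repair (MMR), base excision
#' repair (BER), nucleotide excision repair (NER) and double-strand break
#' repair (DSBR) -- used to map variant-bearing genes to repair pathways.
#' Genes may belong to multiple pathways. The packaged default
#' (`system.file("extdata", "dna_repair_pathways.gmt", package = "caninetc")`)
#' covers the genes of the cohort's repair-pathway variant table.
#'
#' @param sets Named list with exactly the keys MMR, BER, NER, DSBR.
#' @return List of class `repair_pathway_sets`.
#' @export
repair_pathway_sets <- function(sets) {
  need <- c("MMR", "BER", "NER", "DSBR")
  if (!setequal(names(sets), need)) {
    stop("pathway sets must have exactly the keys: ", paste(need, collapse = ", "))
  }
  structure(sets[need], class = "repair_pathway_sets")
}

#' Annotate variants with the repair pathways of their genes
#'
#' A variant carries every pathway whose gene set contains its gene.
#' Variants in no pathway are excluded (they do not contribute to
#' repair-pathway summaries).
#'
#' @param variants Data frame with `gene_id` (or `gene`).
#' @param sets A [repair_pathway_sets()].
#' @return The pathway-mapped subset with a `pathways` column
#'   (comma-joined, in MMR/BER/NER/DSBR order).
#' @export
map_pathways <- function(variants, sets) {
  stopifnot(inherits(sets, "repair_pathway_sets"))
  gcol <- if ("gene_id" %in% names(variants)) "gene_id" else "gene"
  pw <- vapply(variants[[gcol]], function(g) {
    hit <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  out <- variants[nzchar(pw), , drop = FALSE]
  out$pathways <- pw[nzchar(pw)]
  rownames(out) <- NULL
  out
}

#' Assign a germline/somatic genotype from detection sources
#'
#' Genotype is a pure function of where the variant was detected:
#' present in the matched-normal exome -> germline; otherwise present in the
#' tumor exome -> somatic; otherwise (RNA only) the genotype cannot be
#' confidently assigned.
#'
#' @param detection_sources Character vector, a non-empty subset of
#'   `c("rna", "wes_tumor", "wes_normal")`.
#' @return `"germline"`, `"somatic"`, or `"unassigned"`.
#' @export
assign_genotype <- function(detection_sources) {
  allowed <- c("rna", "wes_tumor", "wes_normal")
  if (length(detection_sources) == 0) stop("detection source set is empty")
  if (!all(detection_sources %in% allowed)) {
    stop("unknown detection source(s): ",
         paste(setdiff(detection_sources, allowed), collapse = ", "))
  }
  if ("wes_normal" %in% detection_sources) return("germline")
  if ("wes_tumor" %in% detection_sources) return("somatic")
  "unassigned"
}

#' Summarize DNA-repair-pathway variant burden over a cohort
#'
#' Counts distinct variants (keyed by sample, gene, protein change --
#' two different substitutions in one gene of one sample are two variants),
#' distinct genes, and distinct samples carrying at least one
#' pathway-mapped variant; the cohort fraction uses the full sample roster
#' as denominator. Genotype counts are included when a `genotype` column is
#' present.
#'
#' @param annotated Data frame of pathway-mapped variants with `sample_id`
#'   (or `sample`), `gene_id` (or `gene`), `hgvsp`, optionally `genotype`
#'   and `pathways`.
#' @param cohort_sample_ids Full roster of cohort samples.
#' @return List of class `drp_summary`: `n_variants`, `n_genes`,
#'   `n_samples_mutated`, `fraction_of_cohort`, `genotype_counts`,
#'   `pathway_counts`.
#' @export
summarize_drp <- function(annotated, cohort_sample_ids) {
  if (length(cohort_sample_ids) == 0) stop("cohort roster is empty")
  scol <- if ("sample_id" %in% names(annotated)) "sample_id" else "sample"
  gcol <- if ("gene_id" %in% names(annotated)) "gene_id" else "gene"
  key <- paste(annotated[[scol]], annotated[[gcol]], annotated$hgvsp)
  dedup <- annotated[!duplicated(key), , drop = FALSE]
  genotype_counts <- if ("genotype" %in% names(dedup)) {
    table(factor(dedup$genotype, levels = c("germline", "somatic", "unassigned")))
  } else NULL
  pathway_counts <- if ("pathways" %in% names(dedup)) {
    pws <- unlist(strsplit(dedup$pathways, ","))
    table(factor(pws, levels = c("MMR", "BER", "NER", "DSBR")))
  } else NULL
  n_mut <- length(unique(dedup[[scol]]))
  structure(list(
    n_variants = nrow(dedup),
    n_genes = length(unique(dedup[[gcol]])),
    n_samples_mutated = n_mut,
    fraction_of_cohort = n_mut / length(cohort_sample_ids),
    genotype_counts = genotype_counts,
    pathway_counts = pathway_counts
  ), class = "drp_summary")
}

#' Microsatellite instability score comparison by repair genotype
#'
#' Two-sided Wilcoxon rank-sum comparison of externally computed MSI scores
#' between carriers and non-carriers of double-strand-break-repair and/or
#' mismatch-repair gene variants. (The cohort's published group sizes are
#' stated inconsistently between the text, 17 vs 13, and a figure caption,
#' 16 vs 11; the discrepancy is noted here and left unresolved.)
#'
#' @param msi_scores Named numeric vector, sample -> MSI score.
#' @param mutant_samples Sample ids carrying DSBR and/or MMR variants.
#' @return List with `W`, `p`, `n_mutant`, `n_nonmutant`.
#' @export
msi_association <- function(msi_scores, mutant_samples) {
  is_mut <- names(msi_scores) %in% mutant_samples
  if (!any(is_mut) || all(is_mut)) stop("both genotype groups must be non-empty")
  rs <- rank_sum_test(msi_scores[is_mut], msi_scores[!is_mut])
  list(W = rs$W, p = rs$p, n_mutant = sum(is_mut), n_nonmutant = sum(!is_mut))
}

#' Read the packaged DNA-repair variant table
#'
#' Loads the cohort's repair-pathway variant table (one row per variant:
#' gene, sample, protein change, detection sources from manual review,
#' pathway labels, breed) and derives the genotype of each variant from its
#' detection sources with [assign_genotype()].
#'
#' @param path Path to the TSV; defaults to the packaged copy.
#' @return Data frame with columns `gene`, `sample_id`, `hgvsp`,
#'   `pipeline`, `pathways`, `detection_sources`, `breed`, `genotype`.
#' @export
read_drp_table <- function(path = system.file("extdata", "dna_repair_variants.tsv",
                                              package = "caninetc")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$genotype <- vapply(strsplit(tab$detection_sources, ","), assign_genotype,
                         character(1))
  tab
}
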