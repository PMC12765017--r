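#' Write a counts matrix as TSV
#'
#' Genes as rows with a `gene_id` first column, sample ids as the header.
#'
#' @param counts Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a counts TSV written by [write_counts_tsv()]
#'
#' @param path Input path.
#' @return Integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Minimal VCF 4.2 writer: one multi-sample VCF with GT:DP:AD genotypes and a
# CSQ INFO tag carrying consequence|gene|transcript|hgvsp.
write_variants_vcf <- function(variants, path, contig, contig_length) {
  samples <- sort(unique(variants$sample_id))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  sites <- variants[!duplicated(key), c("chrom", "pos", "ref", "alt",
                                        "filter_status", "consequence",
                                        "gene_id", "transcript_id", "hgvsp")]
  sites <- sites[order(sites$pos), , drop = FALSE]
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  gt <- matrix("./.:.:.", nrow(sites), length(samples),
               dimnames = list(skey, samples))
  vkey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    gt[vkey[i], v$sample_id] <- sprintf("0/1:%d:%d,%d", v$depth,
                                        v$depth - v$alt_count, v$alt_count)
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"consequence|gene|transcript|hgvsp\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  info <- sprintf("CSQ=%s|%s|%s|%s", sites$consequence, sites$gene_id,
                  sites$transcript_id, sites$hgvsp)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                sites$filter_status, info, "GT:DP:AD",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read a cohort VCF into a variant data frame
#'
#' Parses a (multi-sample) VCF 4.2 with GT:DP:AD genotypes and the CSQ
#' consequence tag into the long per-(variant, sample) table the filter
#' cascades consume.
#'
#' @param path VCF path.
#' @param source Value for the `source` column (`wes_tumor`, `wes_normal`,
#'   `rna`).
#' @return Variant data frame (see the variant-tables help topic).
#' @export
read_variants_vcf <- function(path, source) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  csq <- sub("^CSQ=", "", fix$INFO)
  parts <- strsplit(csq, "|", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else "",
                            character(1))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP")
  ad <- vcfR::extract.gt(v, element = "AD")
  rows <- list()
  for (s in colnames(gt)) {
    called <- !is.na(gt[, s]) & gt[, s] != "./."
    if (!any(called)) next
    adp <- strsplit(ad[called, s], ",", fixed = TRUE)
    altc <- vapply(adp, function(x) as.integer(x[2]), integer(1))
    depth <- as.integer(dp[called, s])
    rows[[s]] <- data.frame(
      sample_id = s, chrom = fix$CHROM[called],
      pos = as.integer(fix$POS[called]), ref = fix$REF[called],
      alt = fix$ALT[called], filter_status = fix$FILTER[called],
      depth = depth, alt_count = altc,
      allele_fraction = altc / depth,
      consequence = get(1)[called], gene_id = get(2)[called],
      transcript_id = get(3)[called], hgvsp = get(4)[called],
      source = source, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out
}

#' Write a MAF-like variant TSV
#'
#' Fixed, versioned column order: sample, gene, chrom, pos, ref, alt,
#' consequence, HGVSp, t_depth, t_alt_count.
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @export
write_maf_tsv <- function(variants, path) {
  out <- data.frame(sample = variants$sample_id, gene = variants$gene_id,
                    chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    consequence = variants$consequence,
                    HGVSp = variants$hgvsp, t_depth = variants$depth,
                    t_alt_count = variants$alt_count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a caller-style fusion TSV
#'
#' @param path TSV with columns sample, gene_5p, gene_3p, junction_reads,
#'   spanning_frags (column names mappable via `col_map`).
#' @param col_map Named character vector mapping the expected names to the
#'   file's column names.
#' @return Fusion call data frame.
#' @export
read_fusion_tsv <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (want in names(col_map)) names(df)[names(df) == col_map[[want]]] <- want
  }
  if ("sample" %in% names(df) && !"sample_id" %in% names(df)) {
    names(df)[names(df) == "sample"] <- "sample_id"
  }
  df
}

#' Write the full synthetic cohort to a directory
#'
#' Emits the counts TSV, the three VCFs (tumor exome, matched-normal exome,
#' RNA), the MAF-like tumor variant table, the fusion TSV, the ortholog
#' protein FASTA, the clinical CSV, the truth tables, and a manifest listing
#' every file with its MD5 checksum.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  write_counts_tsv(cohort$expression$counts, p("counts.tsv"))
  utils::write.table(
    data.frame(gene_id = cohort$expression$gene_ids,
               length = cohort$expression$gene_lengths),
    p("gene_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  reflen <- 200000L
  write_variants_vcf(cohort$wes_tumor_variants, p("wes_tumor.vcf"), "chrS", reflen)
  write_variants_vcf(cohort$wes_normal_variants, p("wes_normal.vcf"), "chrS", reflen)
  write_variants_vcf(cohort$rna_variants, p("rna.vcf"), "chrS", reflen)
  write_maf_tsv(cohort$wes_tumor_variants, p("variants_maf.tsv"))
  utils::write.table(
    data.frame(sample = cohort$fusion_calls$sample_id,
               gene_5p = cohort$fusion_calls$gene_5p,
               gene_3p = cohort$fusion_calls$gene_3p,
               junction_reads = cohort$fusion_calls$junction_reads,
               spanning_frags = cohort$fusion_calls$spanning_frags),
    p("fusions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- unlist(lapply(cohort$ortholog_pairs, function(o) {
    c(paste0(">", o$gene, "|dog"), o$source_seq,
      paste0(">", o$gene, "|human"), o$target_seq)
  }))
  writeLines(fasta, p("orthologs.fasta"))
  utils::write.csv(cohort$clinical, p("clinical.csv"), row.names = FALSE)
  utils::write.table(
    data.frame(variant_id = names(cohort$truth_genotype),
               genotype = unname(cohort$truth_genotype)),
    p("truth_genotype.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(fusion_id = names(cohort$truth_fusion_class),
               class = unname(cohort$truth_fusion_class)),
    p("truth_fusion_class.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("counts.tsv", "gene_lengths.tsv", "wes_tumor.vcf",
             "wes_normal.vcf", "rna.vcf", "variants_maf.tsv", "fusions.tsv",
             "orthologs.fasta", "clinical.csv", "truth_genotype.tsv",
             "truth_fusion_class.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(directory, files))))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Read the packaged clinical/histopathology table
#'
#' A per-dog table whose per-column margins reproduce the published cohort
#' summaries (60 dogs: 54 follicular and 6 medullary carcinomas by
#' calcitonin status, with histologic pattern, differentiation, nuclear
#' atypia, HER2 immunohistochemistry grades and the binary microscopic
#' features). The joint structure within each subtype beyond those margins
#' is not published and is arbitrary here, which is why the file is
#' labelled synthetic.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @return Data frame, one row per dog.
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "clinical_table_synthetic.csv",
                                                   package = "caninetc")) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Read the packaged sequenced-cohort sample roster
#'
#' The 30 tumors with sequencing data; ids named in the study are used
#' where available and the remainder are synthetic placeholders.
#'
#' @param path Text file, one sample id per line.
#' @return Character vector of sample ids.
#' @export
read_cohort_roster <- function(path = system.file("extdata",
                                                  "cohort_roster_synthetic.txt",
                                                  package = "caninetc")) {
  readLines(path)
}

#' Read or write a cohort configuration as YAML
#'
#' @param config A [cohort_config()] (for writing).
#' @param path YAML file path.
#' @return For reading, a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  x <- unclass(config)
  # named atomic vectors must become maps to survive the YAML round trip
  x$signature_mixture <- as.list(x$signature_mixture)
  x$fusion_artifact_rates <- as.list(x$fusion_artifact_rates)
  yaml::write_yaml(x, path, precision = 15)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  cfg <- yaml::read_yaml(path)
  cfg$signature_mixture <- unlist(cfg$signature_mixture)
  cfg$fusion_artifact_rates <- unlist(cfg$fusion_artifact_rates)
  do.call(cohort_config, cfg)
}
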