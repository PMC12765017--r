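#' Global pairwise alignment of an ortholog protein pair
#'
#' Aligns a source-species protein to its target-species ortholog with a
#' global (Needleman-Wunsch-type) alignment, BLOSUM62 substitution scores
#' and affine gap penalties (open 11, extend 1), via
#' [Biostrings::pairwiseAlignment()]. The result records, residue by
#' residue, which source positions correspond to which target positions --
#' the correspondence later used to project variant amino-acid positions
#' across species.
#'
#' @param source_seq,target_seq Protein sequences (strings over the 20
#'   amino acids plus X).
#' @param type Alignment type; `"global"` (default) or `"local"` for a
#'   Smith-Waterman-style fidelity check.
#' @return List of class `alignment_map`: `source_id`/`target_id` unset
#'   (fill from FASTA ids), `pairs` (data frame `source_pos`, `target_pos`,
#'   NA = gap), `score`, `identity_fraction`.
#' @export
align_pair <- function(source_seq, target_seq, type = c("global", "local")) {
  type <- match.arg(type)
  for (s in c(source_seq, target_seq)) {
    if (!nzchar(s)) stop("empty protein sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(s))) {
      stop("sequence contains characters outside the amino-acid alphabet")
    }
  }
  source_seq <- toupper(source_seq); target_seq <- toupper(target_seq)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(source_seq), Biostrings::AAString(target_seq),
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
    type = type
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # local alignments start mid-sequence; offset by the unaligned prefix
  off_s <- Biostrings::start(Biostrings::pattern(aln)) - 1
  off_t <- Biostrings::start(Biostrings::subject(aln)) - 1
  sp <- off_s + cumsum(pa != "-")
  tp <- off_t + cumsum(sa != "-")
  pairs <- data.frame(
    source_pos = ifelse(pa != "-", sp, NA_integer_),
    target_pos = ifelse(sa != "-", tp, NA_integer_)
  )
  both <- !is.na(pairs$source_pos) & !is.na(pairs$target_pos)
  ident <- if (any(both)) mean(pa[both] == sa[both]) else 0
  structure(list(source_id = NA_character_, target_id = NA_character_,
                 pairs = pairs, score = Biostrings::score(aln),
                 identity_fraction = ident, type = type,
                 source_len = nchar(source_seq), target_len = nchar(target_seq)),
            class = "alignment_map")
}

#' Project one residue position through an alignment
#'
#' Returns the target-protein residue index aligned to `source_pos`, or
#' `NA` when the source residue aligns to a gap (no orthologous residue).
#' For local alignments, positions outside the aligned block are reported
#' as `NA` with attribute `reason = "outside alignment"`.
#'
#' @param map An `alignment_map`.
#' @param source_pos 1-based residue index in the source protein.
#' @return Integer target position or `NA`.
#' @export
project_position <- function(map, source_pos) {
  stopifnot(inherits(map, "alignment_map"))
  if (source_pos < 1 || source_pos > map$source_len) {
    stop("source position ", source_pos, " out of range 1..", map$source_len)
  }
  i <- which(!is.na(map$pairs$source_pos) & map$pairs$source_pos == source_pos)
  if (length(i) == 0) {
    out <- NA_integer_
    attr(out, "reason") <- "outside alignment"
    return(out)
  }
  map$pairs$target_pos[i]
}

#' Parse a single-residue protein substitution from HGVS p. notation
#'
#' Accepts `p.A100P`-style one-letter substitutions. Frameshifts, stops,
#' deletions and other non-substitution changes are reported as
#' unparseable-for-projection with a reason rather than an error, since
#' they pass through the position mapper unprojected.
#'
#' @param hgvsp A protein change string.
#' @return List `ref`, `pos`, `alt`; or an empty list with attribute
#'   `reason` when the change is not a projectable substitution.
#' @export
parse_hgvsp <- function(hgvsp) {
  m <- regmatches(hgvsp, regexec("^p\\.([A-Y])([0-9]+)([A-Y])$", hgvsp))[[1]]
  if (length(m) == 4) {
    return(list(ref = m[2], pos = as.integer(m[3]), alt = m[4]))
  }
  structure(list(),
            reason = if (grepl("^p\\.", hgvsp)) "not a single-residue substitution"
                     else "unparseable HGVSp")
}

#' Project a protein substitution onto the target ortholog
#'
#' Maps the source-species substitution position through the alignment and
#' reports the target position, the target's own residue there, and whether
#' the source reference residue is conserved (`concordant`). Non-concordant
#' positions are still projected but flagged, since downstream driver
#' prediction expects the target's reference residue. Frameshift and other
#' non-substitution changes pass through unprojected with a reason.
#'
#' @param map An `alignment_map`.
#' @param hgvsp Source protein change, e.g. `"p.A100P"`.
#' @param target_seq Target protein sequence.
#' @return List of class `projected_variant`: `source_hgvsp`, `target_pos`,
#'   `target_ref_residue`, `target_hgvsp`, `concordant`, `reason`.
#' @export
project_hgvsp <- function(map, hgvsp, target_seq) {
  parsed <- parse_hgvsp(hgvsp)
  if (length(parsed) == 0) {
    return(structure(list(source_hgvsp = hgvsp, target_pos = NA_integer_,
                          target_ref_residue = "", target_hgvsp = "",
                          concordant = NA, reason = attr(parsed, "reason")),
                     class = "projected_variant"))
  }
  if (parsed$pos > map$source_len) stop("HGVSp position beyond source protein length")
  tp <- project_position(map, parsed$pos)
  if (is.na(tp)) {
    return(structure(list(source_hgvsp = hgvsp, target_pos = NA_integer_,
                          target_ref_residue = "", target_hgvsp = "",
                          concordant = NA,
                          reason = attr(tp, "reason") %||% "aligned to gap"),
                     class = "projected_variant"))
  }
  tres <- substr(toupper(target_seq), tp, tp)
  structure(list(source_hgvsp = hgvsp, target_pos = as.integer(tp),
                 target_ref_residue = tres,
                 target_hgvsp = paste0("p.", tres, tp, parsed$alt),
                 concordant = tres == parsed$ref, reason = NA_character_),
            class = "projected_variant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch-project variants over FASTA ortholog pairs
#'
#' Reads ortholog pairs from a FASTA file whose ids follow the
#' `GENE|species` convention, aligns each pair, and projects each supplied
#' variant through its gene's alignment.
#'
#' @param variants Data frame with `gene_id`, `hgvsp`.
#' @param fasta_path FASTA of ortholog pairs (two records per gene:
#'   `GENE|source_species`, `GENE|target_species`).
#' @param source_species,target_species Species tags in the FASTA ids.
#' @return Data frame: gene, source_hgvsp, target_pos, target_hgvsp,
#'   concordant, identity_fraction, reason.
#' @export
project_variants <- function(variants, fasta_path,
                             source_species = "dog", target_species = "human") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 1)
  species <- vapply(parts, `[`, character(1), 2)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    g <- variants$gene_id[i]
    si <- which(genes == g & species == source_species)
    ti <- which(genes == g & species == target_species)
    if (length(si) != 1 || length(ti) != 1) {
      return(data.frame(gene = g, source_hgvsp = variants$hgvsp[i],
                        target_pos = NA_integer_, target_hgvsp = "",
                        concordant = NA, identity_fraction = NA_real_,
                        reason = "ortholog pair not found"))
    }
    map <- align_pair(as.character(seqs[[si]]), as.character(seqs[[ti]]))
    pv <- project_hgvsp(map, variants$hgvsp[i], as.character(seqs[[ti]]))
    data.frame(gene = g, source_hgvsp = pv$source_hgvsp,
               target_pos = pv$target_pos, target_hgvsp = pv$target_hgvsp,
               concordant = pv$concordant,
               identity_fraction = map$identity_fraction,
               reason = pv$reason %||% NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
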