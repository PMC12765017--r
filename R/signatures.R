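#' The 96 trinucleotide substitution classes
#'
#' Labels of the conventional 96 single-base-substitution mutation types:
#' six pyrimidine-frame substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with the 4 x 4 flanking base combinations, in lexicographic
#' order, formatted as `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
context_96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(unname(revcomp_base(strsplit(x, "")[[1]]))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify one SNV into its 96-type label
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented
#' into the pyrimidine frame, flipping the flanking context, before binning.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide reference context (5' base, ref, 3' base).
#' @return A label as in [context_96_labels()].
#' @export
classify_snv <- function(ref, alt, context) {
  if (nchar(ref) != 1 || nchar(alt) != 1) stop("not a single-base substitution")
  if (nchar(context) != 3) stop("context must be a trinucleotide")
  if (substr(context, 2, 2) != ref) {
    stop("reference allele ", ref, " does not match context ", context)
  }
  if (ref %in% c("A", "G")) {
    context <- revcomp(context)
    ref <- unname(revcomp_base(ref))
    alt <- unname(revcomp_base(alt))
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

#' Build per-sample 96-type mutation spectra
#'
#' Bins each sample's single-nucleotide variants into the 96 trinucleotide
#' substitution classes. Indels and multi-nucleotide variants are excluded.
#' A mismatch between a variant's reference allele and the middle base of
#' its supplied context is a data-integrity error naming the site.
#'
#' @param snvs Variant data frame (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference_context Named character vector, `"chrom:pos"` ->
#'   trinucleotide.
#' @return Integer matrix, 96 classes x samples.
#' @export
build_spectrum <- function(snvs, reference_context) {
  is_snv <- nchar(snvs$ref) == 1 & nchar(snvs$alt) == 1 &
    snvs$ref %in% c("A", "C", "G", "T") & snvs$alt %in% c("A", "C", "G", "T")
  snvs <- snvs[is_snv, , drop = FALSE]
  labels <- context_96_labels()
  samples <- unique(snvs$sample_id)
  spec <- matrix(0L, 96, length(samples), dimnames = list(labels, samples))
  if (nrow(snvs) == 0) return(spec)
  ctx <- reference_context[paste(snvs$chrom, snvs$pos, sep = ":")]
  if (any(is.na(ctx))) {
    stop("no reference context for site(s): ",
         paste(utils::head(paste(snvs$chrom, snvs$pos, sep = ":")[is.na(ctx)], 5),
               collapse = ", "))
  }
  bad <- substr(ctx, 2, 2) != snvs$ref
  if (any(bad)) {
    stop("reference allele does not match context at: ",
         paste(utils::head(paste(snvs$chrom, snvs$pos, sep = ":")[bad], 5),
               collapse = ", "))
  }
  cls <- mapply(classify_snv, snvs$ref, snvs$alt, ctx)
  tab <- table(factor(cls, levels = labels), factor(snvs$sample_id, levels = samples))
  spec[] <- as.integer(tab)
  spec
}

#' De novo mutational signature extraction by KL-divergence NMF
#'
#' Factorizes the 96 x samples spectrum matrix V as W H with W >= 0
#' (signatures) and H >= 0 (exposures), minimizing the generalized
#' Kullback-Leibler divergence by multiplicative updates. The best of
#' `n_restarts` random initializations (by final objective) is kept;
#' signature columns are renormalized to sum to 1 with exposures rescaled to
#' compensate. Deterministic given `seed`.
#'
#' @param spectra 96 x samples matrix of nonnegative counts (>= k samples
#'   with nonzero totals).
#' @param k Factorization rank (number of signatures).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter Maximum multiplicative updates (default 2000).
#' @param tol Relative objective tolerance for early stopping (default 1e-6).
#' @return List of class `signature_set`: `signatures` (96 x k,
#'   column-stochastic), `exposures` (samples x k), `reconstruction_error`
#'   (final KL divergence), `k`.
#' @export
extract_signatures <- function(spectra, k, seed, n_restarts = 10,
                               max_iter = 2000, tol = 1e-6) {
  V <- as.matrix(spectra)
  nz <- colSums(V) > 0
  if (sum(nz) < k) stop("rank k exceeds the number of samples with nonzero spectra")
  if (k > ncol(V)) stop("rank k exceeds the number of samples")
  eps <- .Machine$double.eps
  kl_div <- function(V, WH) {
    sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(96 * k, 0.1, 1), 96, k)
    H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
    obj <- kl_div(V, W %*% H)
    for (it in seq_len(max_iter)) {
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / pmax(rep(1, 96) %o% rowSums(H), eps)
      if (it %% 10 == 0) {
        obj_new <- kl_div(V, W %*% H)
        if (abs(obj - obj_new) <= tol * max(1, abs(obj))) { obj <- obj_new; break }
        obj <- obj_new
      }
    }
    obj <- kl_div(V, W %*% H)
    if (is.null(best) || obj < best$obj) best <- list(W = W, H = H, obj = obj)
  }
  csums <- pmax(colSums(best$W), eps)
  W <- sweep(best$W, 2, csums, "/")
  H <- sweep(best$H, 1, csums, "*")
  colnames(W) <- paste0("S", seq_len(k))
  rownames(W) <- rownames(V)
  exposures <- t(H)
  colnames(exposures) <- colnames(W)
  rownames(exposures) <- colnames(V)
  structure(list(signatures = W, exposures = exposures,
                 reconstruction_error = best$obj, k = k),
            class = "signature_set")
}

#' Read a reference signature catalog from TSV
#'
#' Expects the COSMIC-style layout: a first column of 96 mutation-type
#' labels followed by one named column per signature. The packaged
#' `sbs_catalog_synthetic.tsv` is a synthetic stand-in catalog with
#' flat/clock-like, mismatch-repair-deficiency-like and CpG-deamination-like
#' profiles (it is not the published reference catalog).
#'
#' @param path TSV path; defaults to the packaged synthetic catalog.
#' @return Numeric matrix, 96 x signatures, rows ordered as
#'   [context_96_labels()].
#' @export
read_signature_catalog <- function(path = system.file("extdata",
                                                      "sbs_catalog_synthetic.tsv",
                                                      package = "caninetc")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[context_96_labels(), , drop = FALSE]
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match extracted signatures against a reference catalog
#'
#' Finds, for each de novo signature, the reference catalog entry with the
#' highest cosine similarity. Matches below `novel_threshold` are labelled
#' novel (the convention used to call a de novo signature without a
#' confident catalog counterpart).
#'
#' @param sigset A `signature_set` or a 96 x k signature matrix.
#' @param catalog 96 x m matrix of named reference signatures (COSMIC-style
#'   single-base-substitution catalog layout).
#' @param novel_threshold Cosine below which a signature is called novel
#'   (default 0.80).
#' @return Data frame: `signature`, `best_match`, `cosine`, `novel`.
#' @export
match_reference <- function(sigset, catalog, novel_threshold = 0.80) {
  W <- if (inherits(sigset, "signature_set")) sigset$signatures else as.matrix(sigset)
  catalog <- as.matrix(catalog)
  if (ncol(catalog) == 0) stop("reference catalog is empty")
  if (nrow(catalog) != 96) stop("catalog vectors must have length 96")
  rows <- lapply(seq_len(ncol(W)), function(j) {
    cs <- apply(catalog, 2, cosine_similarity, a = W[, j])
    i <- which.max(cs)
    data.frame(signature = colnames(W)[j], best_match = colnames(catalog)[i],
               cosine = unname(cs[i]), novel = unname(cs[i]) < novel_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
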