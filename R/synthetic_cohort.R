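#' Built-in 96-type signature profiles for simulation
#'
#' A small set of normalized 96-vectors used to compose substitution
#' spectra in simulated cohorts: `flat` (uniform over all 96 classes),
#' `ct_rich` (clock-like, mass concentrated on C>T), `mmr_like`
#' (mismatch-repair-deficiency flavored, T>C and C>T indel-free profile),
#' and `ct_only` (all mass on the 16 C>T contexts; useful for planted-truth
#' tests).
#'
#' @return Named list of numeric 96-vectors, each summing to 1.
#' @export
builtin_signatures <- function() {
  labels <- context_96_labels()
  cls <- sub("^.\\[(.>.)\\].$", "\\1", labels)
  flat <- rep(1 / 96, 96)
  ct_rich <- ifelse(cls == "C>T", 4, 0.3); ct_rich <- ct_rich / sum(ct_rich)
  mmr <- ifelse(cls == "T>C", 3, ifelse(cls == "C>T", 1.5, 0.2))
  mmr <- mmr / sum(mmr)
  ct_only <- ifelse(cls == "C>T", 1 / 16, 0)
  out <- list(flat = flat, ct_rich = ct_rich, mmr_like = mmr, ct_only = ct_only)
  lapply(out, function(v) stats::setNames(v, labels))
}

#' Configuration for a synthetic thyroid carcinoma cohort
#'
#' Defaults reproduce the study conditions the downstream stages assume:
#' 25 + 5 tumors of the two subtypes plus 5 normal thyroid samples,
#' negative-binomial counts with moderate overdispersion, 50 marker genes
#' per subtype shifted by 4 log2 units, about one hundred somatic and one
#' hundred germline coding variants per sample, a clock-like/flat/MMR
#' signature mixture dominated by C>T, exponential survival with a
#' tumor-size log-hazard slope, and independent exponential censoring.
#'
#' @param n_tumors_subtype1,n_tumors_subtype2,n_normals Sample counts
#'   (defaults 25, 5, 5).
#' @param n_genes Background gene count (default 2000; named marker/score
#'   genes are added on top).
#' @param nb_dispersion Negative-binomial dispersion (default 0.15; variance
#'   mu + dispersion * mu^2).
#' @param marker_log2_effect log2 up-shift of a subtype's marker genes in
#'   that subtype (default 4).
#' @param n_marker_genes_per_subtype Markers per subtype (default 50).
#' @param tds_gradient_sd SD of the per-tumor latent differentiation
#'   gradient applied to the 16 thyroid-function genes (default 1).
#' @param n_somatic_per_sample,n_germline_per_sample Coding variants per
#'   tumor (defaults 100, 100).
#' @param signature_mixture Named numeric vector of weights over
#'   [builtin_signatures()] names (must sum to 1); default
#'   c(ct_rich = .5, flat = .3, mmr_like = .2).
#' @param fusion_artifact_rates Named numeric vector with entries
#'   `same_family`, `unofficial_name`, `cohort_frequency`,
#'   `present_in_normals`: per-sample probabilities for the two per-call
#'   artifact classes, and plant-the-class indicators (> 0 plants the
#'   cohort-level class) for the last two.
#' @param survival_baseline_hazard Baseline death hazard per day at zero
#'   tumor diameter (default log(2)/1892, i.e. a 1892-day median).
#' @param size_log_hazard_ratio Log hazard increase per cm of tumor
#'   diameter (default 0.15).
#' @param censoring_rate Expected fraction censored, in [0, 1] (default 0.4).
#' @param n_ortholog_pairs Ortholog protein pairs to simulate (default 5).
#' @param msi_group_shift Additive MSI-score shift for repair-mutant tumors
#'   (default 6, on a score scale with SD about 3).
#' @param seed Integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors_subtype1 = 25, n_tumors_subtype2 = 5,
                          n_normals = 5, n_genes = 2000,
                          nb_dispersion = 0.15, marker_log2_effect = 4,
                          n_marker_genes_per_subtype = 50,
                          tds_gradient_sd = 1,
                          n_somatic_per_sample = 100,
                          n_germline_per_sample = 100,
                          signature_mixture = c(ct_rich = 0.5, flat = 0.3,
                                                mmr_like = 0.2),
                          fusion_artifact_rates = c(same_family = 0.10,
                                                    unofficial_name = 0.10,
                                                    cohort_frequency = 1,
                                                    present_in_normals = 1),
                          survival_baseline_hazard = log(2) / 1892,
                          size_log_hazard_ratio = 0.15,
                          censoring_rate = 0.4,
                          n_ortholog_pairs = 5,
                          msi_group_shift = 6,
                          seed = 1L) {
  cfg <- list(n_tumors_subtype1 = n_tumors_subtype1,
              n_tumors_subtype2 = n_tumors_subtype2, n_normals = n_normals,
              n_genes = n_genes, nb_dispersion = nb_dispersion,
              marker_log2_effect = marker_log2_effect,
              n_marker_genes_per_subtype = n_marker_genes_per_subtype,
              tds_gradient_sd = tds_gradient_sd,
              n_somatic_per_sample = n_somatic_per_sample,
              n_germline_per_sample = n_germline_per_sample,
              signature_mixture = signature_mixture,
              fusion_artifact_rates = fusion_artifact_rates,
              survival_baseline_hazard = survival_baseline_hazard,
              size_log_hazard_ratio = size_log_hazard_ratio,
              censoring_rate = censoring_rate,
              n_ortholog_pairs = n_ortholog_pairs,
              msi_group_shift = msi_group_shift,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_tumors_subtype1", "n_tumors_subtype2", "n_normals", "n_genes",
              "n_marker_genes_per_subtype", "n_somatic_per_sample",
              "n_germline_per_sample", "n_ortholog_pairs")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stop("invalid configuration: ", f, " must be a count >= 1")
    }
  }
  for (f in c("nb_dispersion", "survival_baseline_hazard")) {
    if (cfg[[f]] <= 0) stop("invalid configuration: ", f, " must be positive")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1) {
    stop("invalid configuration: censoring_rate must be in [0, 1]")
  }
  w <- cfg$signature_mixture
  if (is.null(names(w)) || abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
    stop("invalid configuration: signature_mixture weights must be named and sum to 1")
  }
  if (!all(names(w) %in% names(builtin_signatures()))) {
    stop("invalid configuration: signature_mixture names must be built-in signature ids")
  }
  invisible(cfg)
}

# Sub-seed offsets keep modalities on independent reproducible streams, so
# adding a modality does not perturb the earlier ones.
SUBSEED <- c(expression = 1L, reference = 2L, variants = 3L, fusions = 4L,
             orthologs = 5L, clinical = 6L)

tds_gene_ids <- function() sprintf("TDSG%02d", 1:16)
erk_gene_ids <- function() sprintf("ERKG%02d", 1:52)
# 11 of the 52 ERK signature genes are treated as unresolvable in the
# annotation; only the remaining 41 appear in simulated matrices.
erk_unannotated_ids <- function() sprintf("ERKG%02d", 42:52)

#' Generate a fully synthetic thyroid carcinoma cohort
#'
#' Produces expression counts with planted subtype markers and a thyroid
#' differentiation gradient, tumor/normal/RNA variant call sets with known
#' germline/somatic truth and trinucleotide-context-biased substitutions
#' drawn from the configured signature mixture on a self-contained synthetic
#' reference chromosome, fusion calls spanning the four artifact classes,
#' ortholog protein pairs with known residue correspondence, and a clinical
#' table with tumor-size-dependent exponential survival. Deterministic given
#' the config seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `expression`
#'   (an [expression_matrix()]), `wes_tumor_variants`, `wes_normal_variants`,
#'   `rna_variants`, `truth_genotype`, `fusion_calls`, `truth_fusion_class`,
#'   `ortholog_pairs`, `clinical`, `reference_context`, `truth_subtype`,
#'   `truth_tds_gradient`, `score_sets`, `canonical_transcripts`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  s1 <- paste0("T1_", sprintf("%02d", seq_len(config$n_tumors_subtype1)))
  s2 <- paste0("T2_", sprintf("%02d", seq_len(config$n_tumors_subtype2)))
  nm <- paste0("N_", sprintf("%02d", seq_len(config$n_normals)))
  tumors <- c(s1, s2)
  samples <- c(tumors, nm)
  truth_subtype <- stats::setNames(
    c(rep("subtype1", length(s1)), rep("subtype2", length(s2)),
      rep("normal", length(nm))), samples)

  expr <- sim_expression(config, s1, s2, nm)
  refctx <- sim_reference(config)
  vars <- sim_variants(config, tumors, expr$gene_pool, refctx)
  fus <- sim_fusions(config, tumors, nm, expr$gene_pool)
  orth <- sim_orthologs(config)
  clin <- sim_clinical(config, s1, s2, vars$drp_mutant)
  allpos <- c(vars$wes_tumor$pos, vars$wes_normal$pos, vars$rna$pos)
  context <- context_map_for(refctx, allpos)

  structure(list(
    expression = expr$em,
    wes_tumor_variants = vars$wes_tumor, wes_normal_variants = vars$wes_normal,
    rna_variants = vars$rna,
    truth_genotype = vars$truth_genotype,
    fusion_calls = fus$calls, truth_fusion_class = fus$truth,
    ortholog_pairs = orth,
    clinical = clin,
    reference_context = context,
    truth_subtype = truth_subtype,
    truth_tds_gradient = expr$tds_gradient,
    score_sets = expr$score_sets,
    canonical_transcripts = vars$canonical,
    config = config
  ), class = "synthetic_cohort")
}

sim_expression <- function(config, s1, s2, nm) {
  set.seed(config$seed + SUBSEED[["expression"]])
  samples <- c(s1, s2, nm)
  m1 <- sprintf("M1_%03d", seq_len(config$n_marker_genes_per_subtype))
  m2 <- sprintf("M2_%03d", seq_len(config$n_marker_genes_per_subtype))
  sets <- score_gene_sets(tds_genes = tds_gene_ids(),
                          erk_genes = erk_gene_ids())
  erk_present <- setdiff(sets$erk_genes, erk_unannotated_ids())
  bg <- sprintf("G%04d", seq_len(config$n_genes))
  genes <- c(bg, m1, m2, sets$tds_genes, sets$mpas_genes, erk_present)
  base <- stats::setNames(stats::rlnorm(length(genes), log(100), 1.2), genes)
  # latent per-sample structure
  n <- length(samples)
  is_s1 <- samples %in% s1
  is_s2 <- samples %in% s2
  is_t <- is_s1 | is_s2
  # differentiation gradient: subtype-1 tumors and normals high, subtype-2 low
  tds_grad <- stats::rnorm(n, ifelse(is_s2, -2, 1), config$tds_gradient_sd)
  names(tds_grad) <- samples
  mapk <- stats::rnorm(n, ifelse(is_t, 0.5, -1), 1)
  log2mu <- matrix(log2(base), length(genes), n,
                   dimnames = list(genes, samples))
  log2mu[m1, is_s1] <- log2mu[m1, is_s1] + config$marker_log2_effect
  log2mu[m2, is_s2] <- log2mu[m2, is_s2] + config$marker_log2_effect
  log2mu[sets$tds_genes, ] <- sweep(log2mu[sets$tds_genes, ], 2, tds_grad, "+")
  mapk_genes <- c(sets$mpas_genes, erk_present)
  log2mu[mapk_genes, ] <- sweep(log2mu[mapk_genes, ], 2, 0.5 * mapk, "+")
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  lengths <- stats::setNames(sample(500:5000, length(genes), replace = TRUE),
                             genes)
  list(em = expression_matrix(counts, lengths), score_sets = sets,
       tds_gradient = tds_grad,
       gene_pool = genes, markers1 = m1, markers2 = m2)
}

sim_reference <- function(config) {
  set.seed(config$seed + SUBSEED[["reference"]])
  len <- 200000L
  seqchars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  refstr <- paste(seqchars, collapse = "")
  # position pools keyed by forward trinucleotide (positions 2..len-1)
  tri <- paste0(seqchars[1:(len - 2)], seqchars[2:(len - 1)], seqchars[3:len])
  pools <- split(2:(len - 1), tri)
  list(chrom = "chrS", seq = seqchars, length = len, pools = pools)
}

# Named "chrom:pos" -> trinucleotide map for the given positions.
context_map_for <- function(ref, pos) {
  pos <- sort(unique(pos))
  ctx <- paste0(ref$seq[pos - 1], ref$seq[pos], ref$seq[pos + 1])
  stats::setNames(ctx, paste(ref$chrom, pos, sep = ":"))
}

# Draw SNV (pos, ref, alt) sites whose trinucleotide contexts follow the
# configured signature mixture; strand of representation is random, so about
# half the draws appear purine-referenced.
draw_snv_sites <- function(n, mixture, ref) {
  sigs <- builtin_signatures()
  labels <- context_96_labels()
  probs <- Reduce(`+`, Map(function(w, s) w * s, mixture, sigs[names(mixture)]))
  cls <- sample(labels, n, replace = TRUE, prob = probs)
  l <- substr(cls, 1, 1); pyr <- substr(cls, 3, 3)
  alt <- substr(cls, 5, 5); r <- substr(cls, 7, 7)
  flip <- stats::runif(n) < 0.5
  ctx_fwd <- paste0(l, pyr, r)
  ctx <- ifelse(flip, revcomp(ctx_fwd), ctx_fwd)
  refb <- ifelse(flip, unname(revcomp_base(pyr)), pyr)
  altb <- ifelse(flip, unname(revcomp_base(alt)), alt)
  pos <- vapply(ctx, function(cx) {
    pool <- ref$pools[[cx]]
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  data.frame(pos = unname(pos), ref = refb, alt = altb,
             stringsAsFactors = FALSE)
}

CONSEQ_SNV <- c(missense = 0.55, synonymous = 0.25, stop_gained = 0.06,
                splice_region = 0.08, splice_acceptor = 0.03,
                splice_donor = 0.03)
AA1 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

random_hgvsp <- function(n, consequence) {
  pos <- sample(30:900, n, replace = TRUE)
  ref <- sample(AA1, n, replace = TRUE)
  alt <- sample(AA1, n, replace = TRUE)
  out <- paste0("p.", ref, pos, alt)
  out[consequence == "stop_gained"] <- paste0("p.", ref, pos, "*")[consequence == "stop_gained"]
  out[consequence == "synonymous"] <- ""
  out
}

sim_variants <- function(config, tumors, gene_pool, ref) {
  set.seed(config$seed + SUBSEED[["variants"]])
  canonical <- data.frame(gene_id = gene_pool,
                          canonical_transcript = paste0(gene_pool, ".t1"))
  # positions are unique across the whole cohort so that one VCF site row
  # carries one FILTER/annotation without cross-sample collisions
  used_pos <- new.env(parent = emptyenv())
  make_rows <- function(sample_id, n, source, status, mixture) {
    sites <- draw_snv_sites(n, mixture, ref)
    fresh <- !vapply(as.character(sites$pos), exists, logical(1),
                     envir = used_pos) & !duplicated(sites$pos)
    sites <- sites[fresh, , drop = FALSE]
    for (p in sites$pos) assign(as.character(p), TRUE, envir = used_pos)
    n <- nrow(sites)
    conseq <- sample(names(CONSEQ_SNV), n, replace = TRUE, prob = CONSEQ_SNV)
    depth <- pmax(20L, stats::rnbinom(n, mu = 100, size = 10))
    af <- if (status == "germline") stats::rbeta(n, 60, 60)
          else 0.2 + 0.6 * stats::rbeta(n, 2, 2)
    gene <- sample(gene_pool, n, replace = TRUE)
    data.frame(sample_id = sample_id, chrom = ref$chrom, pos = sites$pos,
               ref = sites$ref, alt = sites$alt, filter_status = "PASS",
               depth = depth, alt_count = as.integer(round(af * depth)),
               allele_fraction = af, consequence = conseq,
               gene_id = gene, transcript_id = paste0(gene, ".t1"),
               hgvsp = random_hgvsp(n, conseq), source = source,
               stringsAsFactors = FALSE)
  }
  wes_tumor <- list(); wes_normal <- list(); rna <- list()
  truth <- character()
  w0 <- config$signature_mixture
  for (s in tumors) {
    # per-tumor signature exposures: Dirichlet around the configured mixture,
    # so individual tumors are dominated by different mutational processes
    # while the cohort-pooled spectrum matches the mixture in expectation
    g <- stats::rgamma(length(w0), shape = 3 * length(w0) * w0)
    w_s <- if (sum(g) > 0) stats::setNames(g / sum(g), names(w0)) else w0
    germ <- make_rows(s, config$n_germline_per_sample, "wes_tumor", "germline", w_s)
    soma <- make_rows(s, config$n_somatic_per_sample, "wes_tumor", "somatic", w_s)
    # tumor-side caller artifacts that fail the PASS filter
    art <- make_rows(s, 10, "wes_tumor", "somatic", w_s)
    art$filter_status <- rep("germline_risk", nrow(art))
    wes_tumor[[s]] <- rbind(germ, soma, art)
    gnorm <- germ; gnorm$source <- "wes_normal"
    wes_normal[[s]] <- gnorm
    in_rna_g <- stats::runif(nrow(germ)) < 0.7
    in_rna_s <- stats::runif(nrow(soma)) < 0.5
    rna_only <- make_rows(s, 10, "rna", "germline", w_s)
    rg <- germ[in_rna_g, , drop = FALSE]
    rg$source <- rep("rna", nrow(rg))
    rs <- soma[in_rna_s, , drop = FALSE]
    rs$source <- rep("rna", nrow(rs))
    rna[[s]] <- rbind(rg, rs, rna_only)
    vid <- function(v) paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt, sep = ":")
    truth[vid(germ)] <- "germline"
    truth[vid(soma)] <- "somatic"
  }
  wes_tumor <- do.call(rbind, wes_tumor); rownames(wes_tumor) <- NULL
  wes_normal <- do.call(rbind, wes_normal); rownames(wes_normal) <- NULL
  rna <- do.call(rbind, rna); rownames(rna) <- NULL
  # repair-mutant flag reused by the clinical module: tumors whose id hashes
  # into the first 60% of the roster order carry repair-pathway variants
  drp_mutant <- stats::setNames(seq_along(tumors) <= ceiling(0.6 * length(tumors)),
                                tumors)
  list(wes_tumor = wes_tumor, wes_normal = wes_normal, rna = rna,
       truth_genotype = truth, canonical = canonical, drp_mutant = drp_mutant)
}

sim_fusions <- function(config, tumors, normals, gene_pool) {
  set.seed(config$seed + SUBSEED[["fusions"]])
  rates <- config$fusion_artifact_rates
  calls <- list(); truth <- character()
  add <- function(sample_id, g5, g3, class) {
    id <- sprintf("F%04d", length(calls) + 1)
    calls[[id]] <<- data.frame(
      fusion_id = id, sample_id = sample_id, gene_5p = g5, gene_3p = g3,
      junction_reads = stats::rpois(1, 20) + 1L,
      spanning_frags = stats::rpois(1, 10) + 1L, stringsAsFactors = FALSE)
    truth[id] <<- class
  }
  # planted real fusions: one recurrent in three samples, one cancer-gene pair
  rec <- sample(tumors, 3)
  for (s in rec) add(s, "RRH", "GAR1", "real")
  add(sample(tumors, 1), "FGFR2", "EBF2", "real")
  # random symbol-like partner names with distinct alphabetic stems, so the
  # same-family suffix rule only fires on the planted artifact class
  rand_symbol <- function() {
    paste0(paste(sample(LETTERS, 4, replace = TRUE), collapse = ""),
           sample(c("", as.character(1:9)), 1))
  }
  for (s in tumors) {
    for (k in seq_len(stats::rpois(1, 1))) {
      g5 <- rand_symbol(); g3 <- rand_symbol()
      while (same_family_suffix(g5, g3)) g3 <- rand_symbol()
      add(s, g5, g3, "real")
    }
    if (stats::runif(1) < rates[["same_family"]]) add(s, "PBX2", "PBX3", "artifact_a")
    if (stats::runif(1) < rates[["unofficial_name"]]) {
      add(s, sample(gene_pool, 1), "ENSCAFG00845001234", "artifact_b")
    }
  }
  if (rates[["cohort_frequency"]] > 0) {
    freq_samples <- sample(tumors, ceiling(0.9 * length(tumors)))
    for (s in freq_samples) add(s, "HMGB1", "ACTB", "artifact_c")
  }
  if (rates[["present_in_normals"]] > 0) {
    for (s in sample(tumors, 2)) add(s, "COL1A1", "FN1", "artifact_d")
    for (s in sample(normals, 1)) add(s, "COL1A1", "FN1", "artifact_d")
  }
  calls <- do.call(rbind, calls); rownames(calls) <- NULL
  list(calls = calls, truth = truth)
}

sim_orthologs <- function(config) {
  set.seed(config$seed + SUBSEED[["orthologs"]])
  lapply(seq_len(config$n_ortholog_pairs), function(i) {
    len <- sample(120:300, 1)
    src <- sample(AA1, len, replace = TRUE)
    tgt <- src
    # substitutions at ~5% of positions
    subs <- which(stats::runif(len) < 0.05)
    tgt[subs] <- sample(AA1, length(subs), replace = TRUE)
    map <- seq_len(len) # source pos -> target pos
    # one insertion in the target and one deletion from the source
    ins_at <- sample(10:(len - 10), 1)
    ins_len <- sample(3:7, 1)
    tgt <- c(tgt[1:ins_at], sample(AA1, ins_len, replace = TRUE),
             tgt[(ins_at + 1):length(tgt)])
    map[(ins_at + 1):len] <- map[(ins_at + 1):len] + ins_len
    del_at <- sample(setdiff(10:(len - 10), (ins_at - 8):(ins_at + 8)), 1)
    del_len <- sample(2:5, 1)
    del_idx <- del_at:(del_at + del_len - 1)
    tgt <- tgt[-map[del_idx]]
    map[del_idx] <- NA
    later <- which(seq_len(len) > max(del_idx))
    map[later] <- map[later] - del_len
    list(gene = sprintf("ORTH%02d", i),
         source_seq = paste(src, collapse = ""),
         target_seq = paste(tgt, collapse = ""),
         truth_map = map)
  })
}

sim_clinical <- function(config, s1, s2, drp_mutant) {
  set.seed(config$seed + SUBSEED[["clinical"]])
  samples <- c(s1, s2)
  n <- length(samples)
  subtype <- c(rep("FTC", length(s1)), rep("MTC", length(s2)))
  diam <- stats::rlnorm(n, log(4.25), 0.4)
  hz <- config$survival_baseline_hazard * exp(config$size_log_hazard_ratio * diam)
  death <- stats::rexp(n, hz)
  cr <- config$censoring_rate
  time <- death; event <- rep(1L, n)
  if (cr > 0) {
    cens_rate <- mean(hz) * cr / max(1 - cr, 1e-8)
    cens <- stats::rexp(n, cens_rate)
    event <- as.integer(death <= cens)
    time <- pmin(death, cens)
  }
  pat_lv <- c("follicular", "follicular-compact", "compact")
  diff_lv <- c("well", "moderate", "poor")
  pattern <- ifelse(subtype == "FTC",
                    sample(pat_lv, n, TRUE, prob = c(0.44, 0.44, 0.12)),
                    sample(pat_lv, n, TRUE, prob = c(0, 1/3, 2/3)))
  differentiation <- ifelse(subtype == "FTC",
                            sample(diff_lv, n, TRUE, prob = c(0.37, 0.56, 0.07)),
                            sample(diff_lv, n, TRUE, prob = c(0, 1/3, 2/3)))
  calcitonin <- ifelse(subtype == "MTC",
                       sample(c("positive", "negative"), n, TRUE, c(5/6, 1/6)),
                       "negative")
  msi <- stats::rnorm(n, 5, 3) + ifelse(drp_mutant[samples], config$msi_group_shift, 0)
  data.frame(sample_id = samples, subtype = subtype,
             histologic_pattern = pattern, differentiation = differentiation,
             calcitonin_ihc = calcitonin,
             tumor_diameter_cm = round(diam, 1),
             metastasis_at_diagnosis = stats::runif(n) < 0.2,
             drp_mutant = unname(drp_mutant[samples]),
             msi_score = round(msi, 2),
             survival_days = round(pmax(time, 1)),
             event = event, stringsAsFactors = FALSE)
}
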