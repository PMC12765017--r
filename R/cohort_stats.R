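#' Exact or asymptotic Mann-Whitney U test on an ordinal contingency table
#'
#' Compares two groups of subjects scored on an ordered categorical scale
#' (e.g. histologic pattern follicular < follicular-compact < compact, or an
#' immunohistochemistry grade 0 < 1 < 2 < 3). Categories are scored by their
#' order index and ties are handled by midranks. The exact mode computes the
#' full null distribution of the rank sum over all assignments of subjects to
#' groups by a subset-count dynamic program over the (doubled, hence integer)
#' midranks, which is feasible for any table this package encounters; the
#' asymptotic mode uses the normal approximation with the tie-corrected
#' variance.
#'
#' The two-sided exact p-value is the null probability of an outcome at least
#' as extreme as observed in the sense \eqn{|U - E[U]| \ge |U_{obs} - E[U]|}.
#' A doubling convention (twice the one-sided tail, capped at 1) is available
#' via `two_sided`.
#'
#' @param group1,group2 Nonnegative integer vectors of per-category counts,
#'   same length (>= 2 categories), in increasing category order.
#' @param mode `"exact"`, `"asymptotic"`, or `"auto"` (exact when total
#'   n <= 60).
#' @param two_sided `"minlik"` for the \eqn{|U - E[U]|} convention (default)
#'   or `"double"` for twice the smaller tail.
#' @return A list with elements `U` (for group 1), `p`, `method`.
#' @examples
#' # follicular / follicular-compact / compact pattern, two tumor subtypes
#' mann_whitney(c(0, 2, 4), c(24, 24, 6))
#' @export
mann_whitney <- function(group1, group2, mode = c("auto", "exact", "asymptotic"),
                         two_sided = c("minlik", "double")) {
  mode <- match.arg(mode)
  two_sided <- match.arg(two_sided)
  if (length(group1) != length(group2) || length(group1) < 2) {
    stop("group1 and group2 must be per-category counts over >= 2 shared categories")
  }
  if (any(group1 < 0) || any(group2 < 0)) stop("counts must be nonnegative")
  n1 <- sum(group1)
  n2 <- sum(group2)
  n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  tot <- group1 + group2
  ends <- cumsum(tot)
  starts <- c(1, utils::head(ends, -1) + 1)
  mid <- (starts + ends) / 2 # midranks per category
  W <- sum(mid * group1)
  U <- W - n1 * (n1 + 1) / 2
  EU <- n1 * n2 / 2
  if (mode == "auto") mode <- if (n <= 60) "exact" else "asymptotic"

  if (mode == "exact") {
    p <- mw_exact_p(group1, tot, mid, two_sided)
    return(list(U = U, p = p, method = "exact"))
  }
  # tie-corrected normal approximation
  tiecor <- sum(tot^3 - tot) / (n * (n - 1))
  varU <- n1 * n2 / 12 * ((n + 1) - tiecor)
  if (varU <= 0) return(list(U = U, p = 1, method = "asymptotic"))
  z <- (U - EU) / sqrt(varU)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "asymptotic")
}

# Exact null distribution of the group-1 rank sum given tied midranks.
# Doubled midranks are integers, so subsets of size n1 are counted by sum
# with a (size x sum) dynamic program; O(n * n1 * max_sum) time.
mw_exact_p <- function(group1, tot, mid, two_sided) {
  n1 <- sum(group1)
  n <- sum(tot)
  vals <- rep(2 * mid, tot) # integer item values
  Wobs <- sum(rep(mid, group1))
  maxs <- sum(sort(vals, decreasing = TRUE)[seq_len(n1)])
  cnt <- matrix(0, n1 + 1, maxs + 1)
  cnt[1, 1] <- 1
  for (v in vals) {
    for (k in n1:1) {
      idx <- which(cnt[k, ] > 0)
      if (length(idx)) {
        tgt <- idx + v
        ok <- tgt <= maxs + 1
        cnt[k + 1, tgt[ok]] <- cnt[k + 1, tgt[ok]] + cnt[k, idx[ok]]
      }
    }
  }
  counts <- cnt[n1 + 1, ]
  sums <- (0:maxs) / 2
  total <- choose(n, n1)
  probs <- counts / total
  EW <- n1 * (n + 1) / 2
  dev <- abs(sums - EW)
  dobs <- abs(Wobs - EW)
  if (two_sided == "minlik") {
    p <- sum(probs[dev >= dobs - 1e-9])
  } else {
    lower <- sum(probs[sums <= Wobs + 1e-9])
    upper <- sum(probs[sums >= Wobs - 1e-9])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] returning the tie-corrected H
#' statistic and chi-square p-value, with a guarded path for degenerate
#' all-tied input (H = 0, p = 1) where the base routine would divide by zero.
#'
#' @param values List of numeric vectors, one per group (>= 2 groups, each
#'   non-empty).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values) {
  if (!is.list(values) || length(values) < 2) stop("need a list of >= 2 groups")
  if (any(lengths(values) == 0)) stop("all groups must be non-empty")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(seq_along(values), lengths(values)))
  if (length(unique(x)) == 1) {
    return(list(H = 0, p = 1, df = length(values) - 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Kaplan-Meier comparison with log-rank test and hazard ratio
#'
#' Fits product-limit curves per group, runs the two-sided log-rank test, and
#' (for two groups) estimates the hazard ratio from a single-covariate
#' proportional-hazards fit, all through the survival package. Group medians
#' that are never reached because the curve stays above 0.5 under censoring
#' are reported as `NA` with `median_reached = FALSE`, matching the clinical
#' convention of "not reached".
#'
#' @param time Positive follow-up times (days).
#' @param event Event indicator (1 = progression/death, 0 = censored).
#' @param group Group labels (2 groups for the hazard ratio).
#' @param exclude Optional logical vector; `TRUE` rows are dropped before
#'   analysis (e.g. metastasis at diagnosis excluded from progression-free
#'   interval comparisons) and the number dropped is reported.
#' @param hr_reference Reference level for the hazard ratio; defaults to the
#'   first group lexicographically.
#' @return List with `medians` (per group), `median_reached`, `logrank_p`,
#'   `hr`, `hr_ci` (95%), `n_excluded`.
#' @export
km_logrank <- function(time, event, group, exclude = NULL, hr_reference = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  keep <- if (is.null(exclude)) rep(TRUE, length(time)) else !exclude
  n_excluded <- sum(!keep)
  time <- time[keep]; event <- event[keep]; group <- as.character(group)[keep]
  lv <- sort(unique(group))
  if (!is.null(hr_reference)) lv <- c(hr_reference, setdiff(lv, hr_reference))
  g <- factor(group, levels = lv)
  if (any(table(g) == 0)) stop("every group must have at least one subject")
  if (sum(event) < 1) stop("need at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  med <- summary(fit)$table
  if (is.null(dim(med))) med <- matrix(med, nrow = 1, dimnames = list(lv[1], names(med)))
  medians <- med[, "median"]
  names(medians) <- sub("^g=", "", rownames(med))
  logrank_p <- NA_real_
  hr <- NA_real_; hr_ci <- c(NA_real_, NA_real_)
  if (nlevels(g) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
    logrank_p <- stats::pchisq(sd_$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  if (nlevels(g) == 2) {
    cph <- survival::coxph(survival::Surv(time, event) ~ g)
    beta <- unname(stats::coef(cph))
    se <- sqrt(unname(stats::vcov(cph)[1, 1]))
    hr <- exp(beta)
    hr_ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(medians = medians, median_reached = !is.na(medians),
       logrank_p = logrank_p, hr = hr, hr_ci = hr_ci, n_excluded = n_excluded)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validates the input range and applies the step-up procedure via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values out of [0, 1] at positions: ",
                     paste(which(bad), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Two-group Wilcoxon rank-sum test on continuous scores
#'
#' Exact where feasible (no ties, small n via [stats::wilcox.test()]), else
#' the tie-corrected normal approximation. Used for the microsatellite
#' instability score comparison between DNA-repair-mutant and non-mutant
#' tumors.
#'
#' @param x,y Numeric score vectors for the two groups.
#' @return List with `W` (rank-sum U statistic for `x`), `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    x, y,
    exact = !ties && (length(x) + length(y)) <= 60, correct = FALSE
  ))
  list(W = unname(wt$statistic), p = wt$p.value)
}
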