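# Optimal-codon determination: partition genes by CAI extremes, pool group
# codon counts, test each codon against the rest of its synonymous family,
# and emit the optimal set.

#' Partition genes into high/low groups by CAI extremes
#'
#' Group size is `floor(fraction * N)` (minimum 1); ties in CAI are broken
#' by stable input order; the groups are disjoint.
#'
#' @param ids gene identifiers.
#' @param cai_values per-gene CAI, same length as `ids`.
#' @param fraction extreme fraction per tail, in (0, 0.5) (default 0.05).
#' @return list: `high` (ids of the top fraction), `low` (bottom fraction),
#'   `size`.
#' @export
partition_by_cai <- function(ids, cai_values, fraction = 0.05) {
  stopifnot(length(ids) == length(cai_values))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie in (0, 0.5)")
  }
  n <- length(ids)
  size <- max(1L, as.integer(floor(fraction * n)))
  if (2L * size > n) stop("groups would overlap: too few genes for fraction ", fraction)
  ord_desc <- order(-cai_values, seq_len(n), na.last = TRUE)
  ord_asc <- order(cai_values, seq_len(n), na.last = TRUE)
  list(high = ids[ord_desc[seq_len(size)]],
       low = ids[ord_asc[seq_len(size)]],
       size = size)
}

#' Per-codon 2x2 chi-square between expression groups
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on the
#' table [codon vs other codons of its own synonymous family] x [high vs
#' low group] — family-relative, matching the RSCU-based comparison.
#'
#' @param high,low pooled `codon_counts` (or 64-count vectors) of the two
#'   groups.
#' @param codon a codon (DNA or RNA label) in a multi-codon family.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list `chi2`, `p`; both NA when either group's family total is 0.
#' @export
codon_chi_square <- function(high, low, codon, correct = FALSE) {
  codon <- dna_codon(codon)
  if (!codon %in% INFORMATIVE_CODONS) {
    stop("codon ", codon, " is not in a multi-codon synonymous family")
  }
  fam <- SYN_FAMILIES[[AA_OF_CODON[[codon]]]]
  hv <- .counts_vec(high); lv <- .counts_vec(low)
  a <- hv[codon]; b <- sum(hv[fam]) - a
  c_ <- lv[codon]; d <- sum(lv[fam]) - c_
  if (a + b == 0 || c_ + d == 0) return(list(chi2 = NA_real_, p = NA_real_))
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) return(list(chi2 = NA_real_, p = NA_real_))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Compare codon usage between high- and low-expression gene sets
#'
#' Pools the codon counts of each group, computes group RSCU, tests every
#' informative codon with [codon_chi_square()], and flags optimal codons:
#' significantly more used, family-relative, in the high group
#' (`p < alpha` and `delta_rscu = RSCU_high - RSCU_low >= delta_min`).
#' Multiple-testing adjustment is off by default (raw p-values); set
#' `p_adjust` to a [stats::p.adjust()] method to enable it.
#'
#' @param mat genes-by-64 codon count matrix with ids as rownames.
#' @param high_ids,low_ids gene ids of the two groups.
#' @param alpha significance level (default 0.01).
#' @param delta_min minimum RSCU difference (default 0.08).
#' @param correct Yates correction flag, passed to [codon_chi_square()].
#' @param p_adjust "none" (default) or a p.adjust method.
#' @return `group_comparison` list: `table` (data.frame aa, codon,
#'   high_rscu, high_n, low_rscu, low_n, chi2, p, delta_rscu, optimal),
#'   `high_counts`, `low_counts`, `alpha`, `delta_min`.
#' @export
group_comparison <- function(mat, high_ids, low_ids, alpha = 0.01,
                             delta_min = 0.08, correct = FALSE,
                             p_adjust = "none") {
  stopifnot(all(high_ids %in% rownames(mat)), all(low_ids %in% rownames(mat)))
  if (length(intersect(high_ids, low_ids))) stop("groups must be disjoint")
  high <- pool_codon_counts(mat[high_ids, , drop = FALSE])
  low <- pool_codon_counts(mat[low_ids, , drop = FALSE])
  rh <- rscu(high); rl <- rscu(low)
  tab <- data.frame(aa = rh$aa, codon = rh$codon, codon_dna = rh$codon_dna,
                    family_size = rh$family_size,
                    high_rscu = rh$rscu, high_n = rh$count,
                    low_rscu = rl$rscu, low_n = rl$count,
                    stringsAsFactors = FALSE)
  tests <- lapply(tab$codon_dna, function(cd) {
    if (!cd %in% INFORMATIVE_CODONS) return(list(chi2 = NA_real_, p = NA_real_))
    codon_chi_square(high, low, cd, correct = correct)
  })
  tab$chi2 <- vapply(tests, `[[`, numeric(1), "chi2")
  tab$p <- vapply(tests, `[[`, numeric(1), "p")
  if (p_adjust != "none") tab$p <- stats::p.adjust(tab$p, method = p_adjust)
  tab$delta_rscu <- tab$high_rscu - tab$low_rscu
  tab$optimal <- !is.na(tab$p) & tab$p < alpha &
    !is.na(tab$delta_rscu) & tab$delta_rscu >= delta_min
  structure(list(table = tab, high_counts = high, low_counts = low,
                 alpha = alpha, delta_min = delta_min),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group comparison:", x$high_counts$n_codons, "high vs",
      x$low_counts$n_codons, "low codons;",
      sum(x$table$optimal), "optimal codons at p <", x$alpha,
      "and delta RSCU >=", x$delta_min, "\n")
  invisible(x)
}

#' Extract the optimal-codon set
#'
#' Re-thresholds a [group_comparison()] at the requested `alpha` and
#' `delta_min` (defaults: the values stored in the comparison). The set is
#' non-increasing as `alpha` decreases or `delta_min` increases.
#'
#' @param comparison a `group_comparison`.
#' @param alpha,delta_min thresholds.
#' @return character vector of optimal codons (RNA labels).
#' @export
optimal_codon_set <- function(comparison, alpha = comparison$alpha,
                              delta_min = comparison$delta_min) {
  stopifnot(inherits(comparison, "group_comparison"))
  tab <- comparison$table
  sel <- !is.na(tab$p) & tab$p < alpha &
    !is.na(tab$delta_rscu) & tab$delta_rscu >= delta_min
  tab$codon[sel]
}
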