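# Nucleotide composition, positional GC metrics and PR2-bias coordinates.

.counts_vec <- function(x) {
  if (inherits(x, "codon_counts")) x$counts else x[ALL_CODONS]
}

#' Per-gene (or pooled) composition and positional GC profile
#'
#' Computes base fractions over all counted codon positions, GC at each codon
#' position (stop codons included), GC12 = (GC1 + GC2)/2, overall GC, and
#' GC3s — third-position GC restricted to synonymous codons (Met, Trp and
#' stops excluded), the quantity "s" of the expected-ENC curve.
#'
#' @param counts a `codon_counts` object or named 64-codon count vector.
#' @return one-row data.frame: `frac_a`, `frac_c`, `frac_g`, `frac_t`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`, `gc3s`, `n_codons`. All fields
#'   NA when no codons were counted; `gc3s` NA when no synonymous codon
#'   is present.
#' @export
gc_profile <- function(counts) {
  m <- matrix(.counts_vec(counts), nrow = 1, dimnames = list(NULL, ALL_CODONS))
  composition_table(m)
}

#' @rdname gc_profile
#' @export
base_composition <- function(counts) {
  gc_profile(counts)[, c("frac_a", "frac_c", "frac_g", "frac_t", "n_codons")]
}

#' @rdname gc_profile
#' @export
gc_by_position <- function(counts) {
  gc_profile(counts)[, c("gc1", "gc2", "gc3", "gc12", "gc_all", "gc3s", "n_codons")]
}

#' Composition profiles for a codon count matrix
#'
#' Vectorized form of [gc_profile()] over the rows of a genes-by-64 count
#' matrix (see [codon_count_matrix()]).
#'
#' @param mat numeric matrix with the 64 codons as columns.
#' @return data.frame with one row per input row (plus an `id` column when
#'   the matrix has rownames).
#' @export
composition_table <- function(mat) {
  mat <- mat[, ALL_CODONS, drop = FALSE]
  n <- rowSums(mat)
  npos <- 3 * n
  letters <- mat %*% CODON_LETTER_COUNTS          # n x 4
  frac <- letters / ifelse(npos > 0, npos, NA_real_)
  gcp <- vapply(1:3, function(p) {
    as.vector(mat %*% CODON_POS_GC[, p]) / ifelse(n > 0, n, NA_real_)
  }, numeric(nrow(mat)))
  if (is.null(dim(gcp))) gcp <- matrix(gcp, nrow = nrow(mat))
  syn <- SYNONYMOUS_CODONS
  n_syn <- rowSums(mat[, syn, drop = FALSE])
  gc3s_num <- rowSums(mat[, syn[CODON_POS_GC[syn, 3]], drop = FALSE])
  gc3s <- gc3s_num / ifelse(n_syn > 0, n_syn, NA_real_)
  out <- data.frame(
    frac_a = frac[, "A"], frac_c = frac[, "C"],
    frac_g = frac[, "G"], frac_t = frac[, "T"],
    gc1 = gcp[, 1], gc2 = gcp[, 2], gc3 = gcp[, 3],
    gc12 = (gcp[, 1] + gcp[, 2]) / 2,
    gc_all = (letters[, "G"] + letters[, "C"]) / ifelse(npos > 0, npos, NA_real_),
    gc3s = gc3s,
    n_codons = n)
  if (!is.null(rownames(mat))) {
    out <- cbind(data.frame(id = rownames(mat), stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
  }
  out
}

#' PR2-bias coordinates
#'
#' Third-position base counts accumulated over the eight fourfold-degenerate
#' codon boxes only (Ala GC*, Arg CG*, Gly GG*, Leu CU*, Pro CC*, Ser UC*,
#' Thr AC*, Val GU*; two-fold sub-boxes of the six-fold families excluded),
#' with AU-bias = A3/(A3+T3) and GC-bias = G3/(G3+C3). With
#' `fourfold_only = FALSE` all sense-codon third positions are used instead.
#'
#' @param counts a `codon_counts` or named 64-count vector.
#' @param fourfold_only restrict to fourfold boxes (default, standard PR2).
#' @return one-row data.frame `a3`, `t3`, `g3`, `c3`, `au_bias`, `gc_bias`;
#'   biases NA when their denominator is zero, all-NA when no eligible codon.
#' @export
pr2_coords <- function(counts, fourfold_only = TRUE) {
  m <- matrix(.counts_vec(counts), nrow = 1, dimnames = list(NULL, ALL_CODONS))
  pr2_table(m, fourfold_only = fourfold_only)
}

#' @rdname pr2_coords
#' @param mat genes-by-64 codon count matrix.
#' @export
pr2_table <- function(mat, fourfold_only = TRUE) {
  mat <- mat[, ALL_CODONS, drop = FALSE]
  scope <- if (fourfold_only) FOURFOLD_CODONS else SENSE_CODONS
  third <- CODON_POS_BASE[scope, 3]
  tally <- function(b) rowSums(mat[, scope[third == b], drop = FALSE])
  a3 <- tally("A"); t3 <- tally("T"); g3 <- tally("G"); c3 <- tally("C")
  out <- data.frame(
    a3 = a3, t3 = t3, g3 = g3, c3 = c3,
    au_bias = ifelse(a3 + t3 > 0, a3 / (a3 + t3), NA_real_),
    gc_bias = ifelse(g3 + c3 > 0, g3 / (g3 + c3), NA_real_))
  none <- a3 + t3 + g3 + c3 == 0
  out[none, ] <- NA_real_
  if (!is.null(rownames(mat))) {
    out <- cbind(data.frame(id = rownames(mat), stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
  }
  out
}
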