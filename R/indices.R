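# Codon-bias indices: RSCU, Wright's ENC, the expected-ENC null curve,
# and CAI with explicit reference-set construction.

# 64 x 18 indicator of multi-codon synonymous families, ALL_CODONS rows.
MULTI_FAMILY_IND <- {
  fam <- names(MULTI_FAMILIES)
  m <- matrix(0, length(ALL_CODONS), length(fam),
              dimnames = list(ALL_CODONS, fam))
  for (f in fam) m[MULTI_FAMILIES[[f]], f] <- 1
  m
}

.fam_class <- FAMILY_SIZE[colnames(MULTI_FAMILY_IND)]  # 2/3/4/6 per family
.N_FAMILIES_BY_CLASS <- c(`2` = sum(.fam_class == 2), `3` = sum(.fam_class == 3),
                          `4` = sum(.fam_class == 4), `6` = sum(.fam_class == 6))

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size k with family total N_f is
#' `count[c] / (N_f / k)`: 1 means unbiased, k maximal bias. Six-codon
#' families (Leu, Ser, Arg) are treated as single families (k = 6). Stops are
#' excluded; families never observed get NA (absent amino acid, not avoided
#' codon); single-codon families (Met, Trp) have RSCU 1 whenever observed.
#'
#' @param counts a `codon_counts` or named 64-codon count vector.
#' @return `rscu_table` data.frame: `aa`, `codon` (RNA label), `codon_dna`,
#'   `family_size`, `count`, `rscu`, rows ordered by amino acid then codon.
#' @export
rscu <- function(counts) {
  v <- .counts_vec(counts)
  aa <- AA_OF_CODON[SENSE_CODONS]
  cnt <- v[SENSE_CODONS]
  fam_tot <- ave(cnt, aa, FUN = sum)
  k <- FAMILY_SIZE[aa]
  val <- ifelse(fam_tot > 0, cnt * k / fam_tot, NA_real_)
  out <- data.frame(aa = unname(aa), codon = rna_codon(SENSE_CODONS),
                    codon_dna = SENSE_CODONS,
                    family_size = as.integer(unname(k)),
                    count = unname(cnt), rscu = unname(val),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Gene-by-codon RSCU matrix
#'
#' Per-gene RSCU over the 59 informative codons (Met, Trp and stops
#' excluded), the input of the correspondence analysis.
#'
#' @param mat genes-by-64 codon count matrix.
#' @return genes x 59 matrix of RSCU values (RNA codon labels); NA where a
#'   gene never uses a family.
#' @export
rscu_matrix <- function(mat) {
  mat <- mat[, ALL_CODONS, drop = FALSE]
  fam_tot <- mat %*% MULTI_FAMILY_IND                      # n x 18
  fam_of <- AA_OF_CODON[INFORMATIVE_CODONS]
  tot <- fam_tot[, fam_of, drop = FALSE]
  k <- rep(FAMILY_SIZE[fam_of], each = nrow(mat))
  out <- ifelse(tot > 0, mat[, INFORMATIVE_CODONS, drop = FALSE] * k / tot, NA_real_)
  dim(out) <- c(nrow(mat), length(INFORMATIVE_CODONS))
  dimnames(out) <- list(rownames(mat), rna_codon(INFORMATIVE_CODONS))
  out
}

.enc_core <- function(mat, min_codons = 30) {
  mat <- mat[, ALL_CODONS, drop = FALSE]
  n_f <- mat %*% MULTI_FAMILY_IND
  s2_f <- mat^2 %*% MULTI_FAMILY_IND
  # codon homozygosity F-hat = (n * sum p^2 - 1)/(n - 1); families with
  # n <= 1 or F-hat <= 0 are omitted from their class mean
  f_hat <- (s2_f / n_f - 1) / (n_f - 1)
  f_hat[n_f <= 1] <- NA_real_
  f_hat[!is.na(f_hat) & f_hat <= 0] <- NA_real_
  cls_mean <- function(k) {
    sub <- f_hat[, .fam_class == k, drop = FALSE]
    rowMeans(sub, na.rm = TRUE)  # NaN when no family computable
  }
  f2 <- cls_mean(2); f3 <- cls_mean(3); f4 <- cls_mean(4); f6 <- cls_mean(6)
  f3_eff <- ifelse(is.nan(f3), (f2 + f4) / 2, f3)
  enc <- 2 + 9 / f2 + 1 / f3_eff + 5 / f4 + 3 / f6
  missing_class <- is.nan(f2) | is.nan(f4) | is.nan(f6)
  n_sense <- rowSums(mat[, SENSE_CODONS, drop = FALSE])
  low_n <- n_sense < min_codons
  enc[missing_class | low_n] <- NA_real_
  enc <- pmin(enc, 61)
  flag <- rep("OK", nrow(mat))
  flag[missing_class] <- "MISSING_CLASS"
  flag[low_n] <- "LOW_CODONS"
  list(enc = enc, flag = flag, n_sense = n_sense,
       f_bar = cbind(f2 = f2, f3 = f3_eff, f4 = f4, f6 = f6))
}

#' Wright's effective number of codons (ENC)
#'
#' Wright-style estimator: within each observed synonymous family with n
#' counted codons and usage proportions p, codon homozygosity
#' F = (n * sum(p^2) - 1)/(n - 1); families with n <= 1 or F <= 0 are
#' omitted from their degeneracy-class mean, and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, with F3 falling back to
#' (F2 + F4)/2 when no three-fold family is computable. The result is capped
#' at 61 (uniform usage) and left uncapped below 20; genes with fewer than
#' `min_codons` sense codons, or with an entire 2/4/6-fold class missing,
#' are reported NA with a flag rather than extrapolated.
#'
#' @param counts a `codon_counts` or named 64-count vector.
#' @param min_codons minimum sense-codon count (default 30).
#' @return `enc_result` list: `enc_obs`, `flag`, `n_sense`,
#'   `f_bar_by_class` (mean homozygosity for classes 2, 3, 4, 6).
#' @export
enc <- function(counts, min_codons = 30) {
  m <- matrix(.counts_vec(counts), nrow = 1, dimnames = list(NULL, ALL_CODONS))
  r <- .enc_core(m, min_codons)
  structure(list(enc_obs = unname(r$enc), flag = r$flag,
                 n_sense = unname(r$n_sense),
                 f_bar_by_class = r$f_bar[1, ]),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat("ENC =", format(x$enc_obs, digits = 6), "(", x$flag, ";",
      x$n_sense, "sense codons )\n")
  invisible(x)
}

#' Per-gene ENC table
#'
#' @param mat genes-by-64 codon count matrix.
#' @param min_codons minimum sense-codon count (default 30).
#' @return data.frame `id`, `n_sense`, `enc`, `flag`.
#' @export
enc_table <- function(mat, min_codons = 30) {
  r <- .enc_core(mat, min_codons)
  data.frame(id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             n_sense = r$n_sense, enc = r$enc, flag = r$flag,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected ENC under pure compositional pressure
#'
#' Wright's null curve: for third-position synonymous GC content s,
#' expected ENC = 2 + s + 29 / (s^2 + (1 - s)^2).
#'
#' @param gc3s numeric in `[0, 1]` (NA passes through).
#' @return expected ENC value(s).
#' @export
expected_enc <- function(gc3s) {
  bad <- !is.na(gc3s) & (gc3s < 0 | gc3s > 1)
  if (any(bad)) stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative deviation of observed from expected ENC
#'
#' `(ENCexp - ENCobs) / ENCexp`; positive values mean stronger bias than the
#' compositional null predicts. Downstream reporting bins deviations at
#' width 0.1.
#'
#' @param enc_obs observed ENC (NA propagates).
#' @param gc3s third-position synonymous GC used for the expected curve.
#' @return numeric deviation(s).
#' @export
enc_deviation <- function(enc_obs, gc3s) {
  e <- expected_enc(gc3s)
  (e - enc_obs) / e
}

.cai_weights_from_pooled <- function(pooled, floor = 0.01) {
  w <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  for (f in names(MULTI_FAMILIES)) {
    cods <- MULTI_FAMILIES[[f]]
    cnt <- pooled[cods]
    if (sum(cnt) == 0) next                 # no information: neutral weights
    w[cods] <- pmax(cnt / max(cnt), floor)
  }
  w
}

.eligible_cai_codons <- setdiff(SENSE_CODONS, unlist(SYN_FAMILIES[SINGLE_CODON_AAS]))

#' Build a CAI model from a gene collection
#'
#' Relative adaptiveness weights w are the reference set's within-family
#' RSCU ratios, `w[c] = count[c] / max(family count)`, floored at `floor` so
#' the geometric mean never hits zero; within each family max w = 1. The
#' default reference policy seeds with the `fraction` of genes with lowest
#' ENC (strongest bias), then refines: compute CAI for all genes under the
#' seed weights, re-select the top `fraction` by CAI, recompute weights
#' (`refine` iterations). A user-supplied `reference_ids` overrides the
#' policy entirely.
#'
#' @param mat genes-by-64 codon count matrix with gene ids as rownames.
#' @param fraction reference-set fraction of genes (default 0.05).
#' @param refine number of CAI-reselection iterations (default 1).
#' @param reference_ids optional explicit reference gene ids.
#' @param floor minimum weight for unobserved codons (default 0.01).
#' @param min_codons passed to the ENC seeding step.
#' @return `cai_model` list: `weights` (61 sense codons, DNA labels),
#'   `reference_ids`, `floor`.
#' @export
build_cai_model <- function(mat, fraction = 0.05, refine = 1,
                            reference_ids = NULL, floor = 0.01,
                            min_codons = 30) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  if (is.null(reference_ids)) {
    if (nrow(mat) < 20) stop("need at least 20 genes to build a CAI reference")
    size <- max(1L, as.integer(base::floor(fraction * nrow(mat))))
    if (size < 5) stop("reference set smaller than 5 genes; increase fraction or gene count")
    et <- enc_table(mat, min_codons = min_codons)
    ord <- order(et$enc, seq_len(nrow(mat)), na.last = TRUE)
    reference_ids <- rownames(mat)[ord[seq_len(size)]]
    for (i in seq_len(refine)) {
      w <- .cai_weights_from_pooled(colSums(mat[reference_ids, , drop = FALSE]), floor)
      model_i <- structure(list(weights = w, reference_ids = reference_ids,
                                floor = floor), class = "cai_model")
      cv <- cai_table(mat, model_i)$cai
      ord <- order(-cv, seq_len(nrow(mat)), na.last = TRUE)
      reference_ids <- rownames(mat)[ord[seq_len(size)]]
    }
  } else {
    if (length(reference_ids) < 5) stop("reference set smaller than 5 genes")
    missing_ids <- setdiff(reference_ids, rownames(mat))
    if (length(missing_ids)) stop("unknown reference ids: ",
                                  paste(utils::head(missing_ids), collapse = ", "))
  }
  w <- .cai_weights_from_pooled(colSums(mat[reference_ids, , drop = FALSE]), floor)
  structure(list(weights = w, reference_ids = reference_ids, floor = floor),
            class = "cai_model")
}

#' Codon adaptation index
#'
#' Geometric mean of the model's relative adaptiveness weights over all
#' counted codons, excluding Met, Trp and stops:
#' `exp( sum(count[c] * log w[c]) / sum(count[c]) )`.
#'
#' @param counts a `codon_counts` or named 64-count vector.
#' @param model a `cai_model` from [build_cai_model()].
#' @return CAI in (0, 1]; NA when no eligible codon is counted.
#' @export
cai <- function(counts, model) {
  m <- matrix(.counts_vec(counts), nrow = 1, dimnames = list(NULL, ALL_CODONS))
  cai_table(m, model)$cai
}

#' @rdname cai
#' @param mat genes-by-64 codon count matrix.
#' @return `cai_table()`: data.frame `id`, `n_eligible`, `cai`.
#' @export
cai_table <- function(mat, model) {
  stopifnot(inherits(model, "cai_model"))
  mat <- mat[, ALL_CODONS, drop = FALSE]
  elig <- .eligible_cai_codons
  cnt <- mat[, elig, drop = FALSE]
  n <- rowSums(cnt)
  logw <- log(model$weights[elig])
  val <- exp(as.vector(cnt %*% logw) / ifelse(n > 0, n, NA_real_))
  val[n == 0] <- NA_real_
  data.frame(id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             n_eligible = n, cai = val, stringsAsFactors = FALSE)
}
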