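# Neutrality-plot statistics, correspondence analysis of the gene x codon
# RSCU matrix, and the Spearman correlation table among bias indices.

#' Neutrality-plot statistics (GC12 versus GC3)
#'
#' Ordinary-least-squares fit of GC12 on GC3 plus Spearman rank correlation.
#' A slope near 1 with a strong positive correlation is the
#' mutation-dominated regime; selection compresses the slope toward 0.
#' The OLS slope and the (rank-based) Spearman rho answer different
#' questions and are reported separately. Genes with a missing value in
#' either variable are dropped pairwise; rho is NA when either variable is
#' constant (rank correlation undefined).
#'
#' @param gc12,gc3 numeric vectors, or `gc12` may be a composition
#'   data.frame with `gc12`/`gc3` columns (see [composition_table()]).
#' @return list: `slope`, `intercept`, `rho`, `p_value`, `n`.
#' @export
neutrality_stats <- function(gc12, gc3 = NULL) {
  if (is.data.frame(gc12)) {
    gc3 <- gc12$gc3
    gc12 <- gc12$gc12
  }
  ok <- !is.na(gc12) & !is.na(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc12)
  if (n < 3) stop("need at least 3 genes with defined GC12 and GC3")
  if (stats::sd(gc3) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, rho = NA_real_,
                p_value = NA_real_, n = n))
  }
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::sd(gc12) == 0) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(gc12, gc3, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rho = rho, p_value = p, n = n)
}

#' Correspondence analysis of a gene-by-codon RSCU matrix
#'
#' Standard correspondence analysis applied, as is conventional for codon
#' usage studies, to the non-negative genes x 59 RSCU matrix rather than to
#' raw counts (set `input = "counts"` for the classical variant): row and
#' column masses from matrix totals, chi-square standardized residuals,
#' singular value decomposition, principal coordinates for genes (rows) and
#' codons (columns), and the fraction of total inertia per axis. Missing
#' family RSCU values are imputed as 0 and the gene flagged; genes with an
#' all-zero profile are dropped (flagged). Axis signs are arbitrary: when
#' `gc3` is supplied, Axis 1 is oriented so its Spearman correlation with
#' GC3 is non-negative.
#'
#' @param mat genes x codons non-negative matrix ([rscu_matrix()] output),
#'   or a genes-by-64 count matrix when `input = "counts"`.
#' @param gc3 optional per-gene GC3 used to orient Axis 1.
#' @param axes_kept number of axes of coordinates to keep (default 4).
#' @param input `"rscu"` (default; matrix used as-is) or `"counts"` (the 59
#'   informative columns of a count matrix are used).
#' @return `coa_result` list: `gene_coords`, `codon_coords` (principal
#'   coordinates, axes as columns), `inertia_fraction` over all non-trivial
#'   axes, `axes_kept`, `flagged_genes` (ids with imputed or empty rows).
#' @export
coa_rscu <- function(mat, gc3 = NULL, axes_kept = 4, input = c("rscu", "counts")) {
  input <- match.arg(input)
  if (input == "counts") mat <- mat[, dna_codon(colnames(mat)) %in% INFORMATIVE_CODONS, drop = FALSE]
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 5) stop("need at least 5 genes for correspondence analysis")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  flagged <- rownames(mat)[apply(mat, 1, anyNA)]
  mat[is.na(mat)] <- 0
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    flagged <- union(flagged, rownames(mat)[empty])
    mat <- mat[!empty, , drop = FALSE]
  }
  if (!is.null(gc3) && !is.null(names(gc3))) gc3 <- gc3[rownames(mat)]
  else if (!is.null(gc3) && any(empty)) gc3 <- gc3[!empty]
  P <- mat / sum(mat)
  r <- rowSums(P); cm <- colSums(P)
  keep_c <- cm > 0
  S <- (P[, keep_c, drop = FALSE] - r %o% cm[keep_c]) /
    sqrt(r %o% cm[keep_c])
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps * 10
  nz <- which(sv$d > max(tol, 1e-12))
  d <- sv$d[nz]
  inertia <- d^2 / sum(d^2)
  m <- min(axes_kept, length(nz))
  U <- sv$u[, nz[seq_len(m)], drop = FALSE]
  V <- sv$v[, nz[seq_len(m)], drop = FALSE]
  gene_coords <- sweep(U, 1, sqrt(r), "/") %*% diag(d[seq_len(m)], m)
  codon_coords <- sweep(V, 1, sqrt(cm[keep_c]), "/") %*% diag(d[seq_len(m)], m)
  dimnames(gene_coords) <- list(rownames(mat), paste0("Axis", seq_len(m)))
  dimnames(codon_coords) <- list(colnames(mat)[keep_c], paste0("Axis", seq_len(m)))
  if (!is.null(gc3) && m >= 1) {
    rho1 <- suppressWarnings(stats::cor(gene_coords[, 1], gc3,
                                        method = "spearman",
                                        use = "pairwise.complete.obs"))
    if (!is.na(rho1) && rho1 < 0) {
      gene_coords[, 1] <- -gene_coords[, 1]
      codon_coords[, 1] <- -codon_coords[, 1]
    }
  }
  structure(list(gene_coords = gene_coords, codon_coords = codon_coords,
                 inertia_fraction = inertia, axes_kept = m,
                 flagged_genes = flagged),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat("correspondence analysis:", nrow(x$gene_coords), "genes x",
      nrow(x$codon_coords), "codons;", length(x$inertia_fraction),
      "non-trivial axes\n")
  cat("inertia fractions (first 4):",
      paste(sprintf("%.2f%%", 100 * utils::head(x$inertia_fraction, 4)),
            collapse = " "), "\n")
  invisible(x)
}

#' Spearman correlation table among gene-level indices
#'
#' Pairwise Spearman rank correlations with two-sided p-values over the
#' columns of a per-gene index table (conventionally GC12, GC3, GCall, ENC,
#' CAI, Axis1 and protein length). Missing values are handled
#' pairwise-complete; constant variables get NA correlations.
#'
#' @param indices data.frame of numeric per-gene variables (an `id` column,
#'   if present, is ignored).
#' @return `correlation_table` list: `variables`, `rho` (symmetric, unit
#'   diagonal), `p`, `n` (pairwise complete counts).
#' @export
correlation_table <- function(indices) {
  df <- indices[, setdiff(colnames(indices), "id"), drop = FALSE]
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (nrow(df) < 5) stop("need at least 5 genes")
  vars <- colnames(df)
  k <- length(vars)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      x <- df[[i]]; y <- df[[j]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        rho[i, j] <- if (sum(ok) > 0 && stats::sd(x[ok]) > 0) 1 else NA_real_
        p[i, j] <- 0
        next
      }
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                             exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(variables = vars, rho = rho, p = p, n = n),
            class = "correlation_table")
}

#' Render a correlation table with significance stars
#'
#' @param ct a `correlation_table`.
#' @param digits decimals for rho (default 3).
#' @return character matrix of "rho" plus `*` (p < 0.05) or `**` (p < 0.01).
#' @export
format_correlation_table <- function(ct, digits = 3) {
  stopifnot(inherits(ct, "correlation_table"))
  stars <- ifelse(is.na(ct$p), "",
                  ifelse(ct$p < 0.01, "**", ifelse(ct$p < 0.05, "*", "")))
  out <- matrix(paste0(ifelse(is.na(ct$rho), "NA",
                              formatC(ct$rho, digits = digits, format = "f")),
                       stars),
                nrow(ct$rho), dimnames = dimnames(ct$rho))
  diag(out) <- "1"
  out
}
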