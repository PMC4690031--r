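# Single-command orchestration: FASTA -> QC -> composition -> indices ->
# multivariate -> optimal codons, with a TSV/figure report bundle.

#' Pipeline configuration
#'
#' @param input CDS multi-FASTA path.
#' @param out_dir output directory (created if needed).
#' @param min_len QC length threshold in nt (default 300).
#' @param drop_not_triplet,drop_internal_stop QC drop flags (default off).
#' @param cai_fraction reference-set fraction for the CAI model.
#' @param partition_fraction extreme-CAI fraction per expression group.
#' @param alpha,delta_min optimal-codon thresholds.
#' @param axes_kept correspondence-analysis axes reported.
#' @param min_codons minimum sense codons for ENC.
#' @param gc_low,gc_high GC color thresholds (fractions) for the CA plot.
#' @param seed RNG seed recorded in the manifest and set before the run.
#' @param plots write PDF figures (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, min_len = 300L,
                            drop_not_triplet = FALSE,
                            drop_internal_stop = FALSE,
                            cai_fraction = 0.05, partition_fraction = 0.05,
                            alpha = 0.01, delta_min = 0.08, axes_kept = 4L,
                            min_codons = 30L, gc_low = 0.45, gc_high = 0.60,
                            seed = 1L, plots = TRUE) {
  stopifnot(min_len > 0, cai_fraction > 0, cai_fraction < 0.5,
            partition_fraction > 0, partition_fraction < 0.5,
            alpha > 0, alpha < 1, delta_min >= 0, axes_kept >= 1,
            gc_low < gc_high)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full codon-usage pipeline
#'
#' Reads and QC-filters the CDS, computes per-gene composition and indices
#' (GC fields, ENC and its expected value/deviation, CAI), correspondence
#' analysis of the RSCU matrix, the Spearman correlation table, and the
#' high/low-expression optimal-codon comparison; writes the report bundle
#' (TSVs, figures, run manifest) into `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all intermediate results: `records`,
#'   `qc_report`, `counts` (gene x 64 matrix), `indices` (per-gene table),
#'   `pooled_rscu`, `coa`, `neutrality`, `correlations`, `comparison`,
#'   `optimal_codons`, `pr2_mean`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  p <- function(...) file.path(config$out_dir, ...)
  files <- character(0)

  ## sequence_io
  res <- stage("sequence_io", {
    records <- read_cds_fasta(config$input)
    qc <- qc_filter(records, min_len = config$min_len,
                    drop_not_triplet = config$drop_not_triplet,
                    drop_internal_stop = config$drop_internal_stop)
    if (nrow(qc$kept) < 5) stop("fewer than 5 CDS pass QC")
    qc
  })
  files <- c(files, .write_tsv(res$report, p("qc_report.tsv")))
  write_cds_fasta(res$kept, p("filtered_cds.fasta"))
  files <- c(files, p("filtered_cds.fasta"))
  counts <- stage("sequence_io", codon_count_matrix(res$kept))

  ## composition
  comp <- stage("composition", composition_table(counts))
  pr2 <- stage("composition", pr2_table(counts))
  pr2_mean <- c(au_bias = mean(pr2$au_bias, na.rm = TRUE),
                gc_bias = mean(pr2$gc_bias, na.rm = TRUE))

  ## indices
  encs <- stage("indices", enc_table(counts, min_codons = config$min_codons))
  enc_exp <- expected_enc(comp$gc3s)
  deviation <- enc_deviation(encs$enc, comp$gc3s)
  cai_model <- stage("indices", {
    if (nrow(counts) < 20) {
      warning("fewer than 20 genes: CAI reference set falls back to all genes")
      build_cai_model(counts, reference_ids = rownames(counts))
    } else {
      build_cai_model(counts, fraction = config$cai_fraction,
                      min_codons = config$min_codons)
    }
  })
  cais <- stage("indices", cai_table(counts, cai_model))
  pooled <- pool_codon_counts(counts)
  pooled_rscu <- stage("indices", rscu(pooled))

  ## multivariate
  rmat <- stage("multivariate", rscu_matrix(counts))
  coa <- stage("multivariate",
               coa_rscu(rmat, gc3 = stats::setNames(comp$gc3, comp$id),
                        axes_kept = config$axes_kept))
  axis_cols <- as.data.frame(matrix(NA_real_, nrow(comp), config$axes_kept))
  names(axis_cols) <- paste0("axis", seq_len(config$axes_kept))
  got <- match(rownames(coa$gene_coords), comp$id)
  for (k in seq_len(coa$axes_kept)) axis_cols[got, k] <- coa$gene_coords[, k]

  protein_len <- floor(comp$n_codons -
                         rowSums(counts[, STOP_CODONS, drop = FALSE]))
  indices <- data.frame(
    id = comp$id, n_codons = comp$n_codons, protein_len = protein_len,
    pct_a = 100 * comp$frac_a, pct_t = 100 * comp$frac_t,
    pct_g = 100 * comp$frac_g, pct_c = 100 * comp$frac_c,
    gc1 = comp$gc1, gc2 = comp$gc2, gc3 = comp$gc3, gc12 = comp$gc12,
    gc_all = comp$gc_all, gc3s = comp$gc3s,
    enc = encs$enc, enc_exp = enc_exp, enc_deviation = deviation,
    cai = cais$cai,
    au_bias = pr2$au_bias, gc_bias = pr2$gc_bias,
    stringsAsFactors = FALSE)
  indices <- cbind(indices, axis_cols)
  files <- c(files, .write_tsv(indices, p("gene_indices.tsv")))
  files <- c(files, .write_tsv(
    pooled_rscu[, c("aa", "codon", "rscu", "count")], p("rscu_pooled.tsv"),
    digits = 3))

  neut <- stage("multivariate", neutrality_stats(comp$gc12, comp$gc3))
  corr_in <- data.frame(GC12 = comp$gc12, GC3 = comp$gc3,
                        GCall = comp$gc_all, ENC = encs$enc, CAI = cais$cai,
                        Axis1 = axis_cols[[1]], Length = protein_len)
  corr <- stage("multivariate", correlation_table(corr_in))
  corr_out <- as.data.frame(format_correlation_table(corr))
  corr_out <- cbind(data.frame(parameter = rownames(corr_out)), corr_out)
  files <- c(files, .write_tsv(corr_out, p("correlation_table.tsv")))

  files <- c(files, .write_tsv(
    data.frame(axis = seq_along(coa$inertia_fraction),
               inertia_fraction = coa$inertia_fraction),
    p("coa_inertia.tsv")))
  gdf <- data.frame(id = rownames(coa$gene_coords), coa$gene_coords,
                    row.names = NULL)
  cdf <- data.frame(codon = rownames(coa$codon_coords), coa$codon_coords,
                    row.names = NULL)
  files <- c(files, .write_tsv(gdf, p("coa_gene_coords.tsv")),
             .write_tsv(cdf, p("coa_codon_coords.tsv")))

  ## optimal_codons
  part <- stage("optimal_codons",
                partition_by_cai(cais$id, cais$cai,
                                 fraction = config$partition_fraction))
  comparison <- stage("optimal_codons",
                      group_comparison(counts, part$high, part$low,
                                       alpha = config$alpha,
                                       delta_min = config$delta_min))
  cmp_tab <- comparison$table
  cmp_out <- data.frame(aa = cmp_tab$aa, codon = cmp_tab$codon,
                        high_rscu = round(cmp_tab$high_rscu, 3),
                        high_n = cmp_tab$high_n,
                        low_rscu = round(cmp_tab$low_rscu, 3),
                        low_n = cmp_tab$low_n,
                        chi2 = round(cmp_tab$chi2, 3),
                        p = signif(cmp_tab$p, 3),
                        delta_rscu = round(cmp_tab$delta_rscu, 3),
                        optimal = cmp_tab$optimal)
  files <- c(files, .write_tsv(cmp_out, p("optimal_codons.tsv")))

  if (isTRUE(config$plots)) {
    files <- c(files, .pipeline_figures(config, comp, indices, coa, pr2,
                                        pr2_mean, neut, p))
  }

  manifest <- c(
    paste0("codonbias_version=", as.character(utils::packageVersion("codonbias"))),
    paste0("r_version=", R.version.string),
    paste0("input=", config$input),
    paste0("n_input=", nrow(res$kept) + sum(res$report$count[
      res$report$flag == "TOO_SHORT"])),
    paste0("n_kept=", nrow(res$kept)),
    vapply(setdiff(names(config), c("input", "out_dir")),
           function(k) paste0(k, "=", config[[k]]), character(1)))
  writeLines(manifest, p("run_manifest.txt"))
  files <- c(files, p("run_manifest.txt"))

  invisible(list(records = res$kept, qc_report = res$report, counts = counts,
                 indices = indices, pooled_rscu = pooled_rscu,
                 cai_model = cai_model, coa = coa, neutrality = neut,
                 correlations = corr, comparison = comparison,
                 optimal_codons = optimal_codon_set(comparison),
                 pr2_mean = pr2_mean, files = files))
}

.pipeline_figures <- function(config, comp, indices, coa, pr2, pr2_mean,
                              neut, p) {
  out <- character(0)
  fig <- function(name, expr) {
    path <- p(name)
    grDevices::pdf(path, width = 6, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    out <<- c(out, path)
  }
  fig("fig_gc_hist.pdf", {
    graphics::hist(100 * comp$gc_all, breaks = 30, col = "grey70",
                   main = "GC content of CDS", xlab = "GC (%)")
  })
  fig("fig_neutrality.pdf", {
    graphics::plot(comp$gc3, comp$gc12, pch = 20, cex = 0.4,
                   xlab = "GC3", ylab = "GC12", main = "Neutrality plot")
    if (!is.na(neut$slope)) graphics::abline(neut$intercept, neut$slope,
                                             col = "red")
  })
  fig("fig_enc_plot.pdf", {
    graphics::plot(indices$gc3s, indices$enc, pch = 20, cex = 0.4,
                   xlab = "GC3s", ylab = "ENC", ylim = c(0, 62),
                   main = "ENC plot")
    s <- seq(0.01, 0.99, by = 0.01)
    graphics::lines(s, expected_enc(s), col = "red", lwd = 2)
  })
  fig("fig_enc_deviation_hist.pdf", {
    d <- indices$enc_deviation[is.finite(indices$enc_deviation)]
    if (length(d)) {
      graphics::hist(d,
                     breaks = seq(floor(min(d) * 10) / 10,
                                  ceiling(max(d) * 10) / 10, by = 0.1),
                     col = "grey70", main = "(ENCexp - ENCobs)/ENCexp",
                     xlab = "relative ENC deviation")
    }
  })
  gc_col <- ifelse(comp$gc_all >= config$gc_high, "red",
                   ifelse(comp$gc_all < config$gc_low, "green3", "blue"))
  got <- match(rownames(coa$gene_coords), comp$id)
  fig("fig_coa_genes.pdf", {
    graphics::plot(coa$gene_coords[, 1], coa$gene_coords[, 2],
                   col = gc_col[got], pch = 20, cex = 0.4,
                   xlab = "Axis 1", ylab = "Axis 2",
                   main = "Correspondence analysis: genes")
  })
  fig("fig_coa_codons.pdf", {
    graphics::plot(coa$codon_coords[, 1], coa$codon_coords[, 2], type = "n",
                   xlab = "Axis 1", ylab = "Axis 2",
                   main = "Correspondence analysis: codons")
    graphics::text(coa$codon_coords[, 1], coa$codon_coords[, 2],
                   rownames(coa$codon_coords), cex = 0.6)
  })
  fig("fig_pr2.pdf", {
    graphics::plot(pr2$gc_bias, pr2$au_bias, pch = 20, cex = 0.4,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)",
                   main = "PR2-bias plot (fourfold families)")
    graphics::abline(h = 0.5, v = 0.5, lty = 2)
    graphics::points(pr2_mean["gc_bias"], pr2_mean["au_bias"], col = "red",
                     cex = 1.5, lwd = 2)
  })
  fig("fig_enc_vs_cai.pdf", {
    graphics::plot(indices$cai, indices$enc, pch = 20, cex = 0.4,
                   xlab = "CAI", ylab = "ENC", main = "ENC vs CAI")
  })
  fig("fig_enc_vs_length.pdf", {
    graphics::plot(indices$protein_len, indices$enc, pch = 20, cex = 0.4,
                   log = "x", xlab = "protein length (aa)", ylab = "ENC",
                   main = "ENC vs protein length")
  })
  out
}
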