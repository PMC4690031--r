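# Synthetic CDS generator: controlled mutational GC pressure, translational
# selection toward a planted preferred-codon set, and expression structure,
# so that every pipeline stage can be validated against ground truth.

# Mean GC fraction over codon positions 1-2 for each amino-acid family,
# the lever through which the shared mutational pressure reaches GC12.
GC12_OF_AA <- vapply(SYN_FAMILIES, function(cods) {
  mean((CODON_POS_GC[cods, 1] + CODON_POS_GC[cods, 2]) / 2)
}, numeric(1))

# Amino-acid sampling tilt: weight(aa) = exp(gc12aa * (b0 + c*(2*m - 1)))
# where m is the gene's third-position GC target. The two constants were
# fixed once by simulation so that, at the default GC3 distribution, the
# genome-wide mean GC is ~0.44 and GC12 tracks GC3 with near-unit slope
# (the mutation-dominated neutrality regime the generator emulates).
GC12_COUPLING_DEFAULT <- 4.0
GC12_INTERCEPT_DEFAULT <- 0.435

#' Specification of a synthetic CDS genome
#'
#' Protein lengths are log-normal (codons, truncated below); each gene draws
#' a third-position GC target from a Beta distribution (wide by default,
#' emulating transcriptomes whose per-gene GC3 spans ~5-90%); a fraction of
#' genes is under translational selection of strength `selection_strength`
#' toward one planted preferred codon per multi-codon family. Codons are
#' sampled with probability proportional to the mutational third-base weight
#' (G/C share `m`, A/T share `1 - m`) times `exp(s)` for preferred codons;
#' amino acids are sampled with a tilt coupling first/second-position GC to
#' the same pressure. A stop codon (uniform over TAA/TAG/TGA) is appended.
#'
#' @param n_genes number of genes.
#' @param mean_protein_len,len_sdlog log-normal protein length parameters
#'   (codons).
#' @param min_protein_len lower truncation (default 100 codons = 300 nt, the
#'   conventional QC threshold).
#' @param gc3_shape1,gc3_shape2 Beta parameters of the per-gene GC3 target
#'   (defaults give mean ~0.42 with a wide spread).
#' @param selection_strength selection coefficient s >= 0 for selected genes.
#' @param selected_fraction fraction of genes under selection (default 0.25;
#'   these carry the `expressed` truth label).
#' @param preferred_codons optional named vector (one DNA codon per
#'   multi-codon family); sampled at random under `seed` when NULL.
#' @param gc12_coupling,gc12_intercept amino-acid tilt constants (see above).
#' @param seed RNG seed; the same spec generates byte-identical output.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(n_genes = 2000, mean_protein_len = 160,
                        len_sdlog = 0.5, min_protein_len = 100,
                        gc3_shape1 = 1.9, gc3_shape2 = 2.6,
                        selection_strength = 0, selected_fraction = 0.25,
                        preferred_codons = NULL,
                        gc12_coupling = GC12_COUPLING_DEFAULT,
                        gc12_intercept = GC12_INTERCEPT_DEFAULT,
                        seed = 1L) {
  stopifnot(n_genes >= 1, mean_protein_len > 0, len_sdlog >= 0,
            min_protein_len >= 1, gc3_shape1 > 0, gc3_shape2 > 0,
            selection_strength >= 0,
            selected_fraction >= 0, selected_fraction <= 1)
  if (!is.null(preferred_codons)) {
    preferred_codons <- dna_codon(preferred_codons)
    fams <- names(MULTI_FAMILIES)
    if (!setequal(names(preferred_codons), fams)) {
      stop("preferred_codons must name exactly one codon per multi-codon family")
    }
    ok <- vapply(fams, function(f) preferred_codons[[f]] %in% MULTI_FAMILIES[[f]],
                 logical(1))
    if (!all(ok)) stop("preferred codon outside its family: ",
                       paste(fams[!ok], collapse = ", "))
    preferred_codons <- preferred_codons[fams]
  }
  structure(list(n_genes = as.integer(n_genes),
                 mean_protein_len = mean_protein_len, len_sdlog = len_sdlog,
                 min_protein_len = as.integer(min_protein_len),
                 gc3_shape1 = gc3_shape1, gc3_shape2 = gc3_shape2,
                 selection_strength = selection_strength,
                 selected_fraction = selected_fraction,
                 preferred_codons = preferred_codons,
                 gc12_coupling = gc12_coupling,
                 gc12_intercept = gc12_intercept,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic CDS genome
#'
#' @param spec a [genome_spec()].
#' @return list: `records` (a `cds_set`), `truth` (data.frame id,
#'   protein_len, gc3_target, selection, expressed, realized_gc3 — the
#'   realized value includes the appended stop codon, matching
#'   [gc_by_position()]'s GC3), `preferred` (the planted preferred-codon
#'   set), `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  fams <- names(MULTI_FAMILIES)
  preferred <- spec$preferred_codons
  if (is.null(preferred)) {
    preferred <- vapply(MULTI_FAMILIES, function(cods) sample(cods, 1L),
                        character(1))
  }
  pref_flag <- stats::setNames(rep(FALSE, length(SENSE_CODONS)), SENSE_CODONS)
  pref_flag[unname(preferred)] <- TRUE

  n <- spec$n_genes
  lens <- pmax(spec$min_protein_len,
               as.integer(round(stats::rlnorm(n, log(spec$mean_protein_len),
                                              spec$len_sdlog))))
  m <- pmin(0.99, pmax(0.01, stats::rbeta(n, spec$gc3_shape1, spec$gc3_shape2)))
  s <- ifelse(stats::runif(n) < spec$selected_fraction,
              spec$selection_strength, 0)

  aas <- names(SYN_FAMILIES)
  third <- CODON_POS_BASE[, 3]
  seqs <- character(n)
  realized_gc3 <- numeric(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    aa_w <- exp(GC12_OF_AA * (spec$gc12_intercept +
                                spec$gc12_coupling * (2 * m[i] - 1)))
    aa_seq <- sample(aas, L, replace = TRUE, prob = aa_w)
    w3 <- c(A = (1 - m[i]) / 2, C = m[i] / 2, G = m[i] / 2, T = (1 - m[i]) / 2)
    codons <- character(L)
    for (aa in unique(aa_seq)) {
      idx <- which(aa_seq == aa)
      cods <- SYN_FAMILIES[[aa]]
      if (length(cods) == 1L) {
        codons[idx] <- cods
      } else {
        w <- w3[third[cods]] * exp(s[i] * pref_flag[cods])
        codons[idx] <- sample(cods, length(idx), replace = TRUE, prob = w)
      }
    }
    codons <- c(codons, sample(STOP_CODONS, 1L))
    seqs[i] <- paste0(codons, collapse = "")
    realized_gc3[i] <- mean(substr(codons, 3, 3) %in% c("G", "C"))
  }
  ids <- sprintf("gene%05d", seq_len(n))
  truth <- data.frame(id = ids, protein_len = lens, gc3_target = m,
                      selection = s, expressed = s > 0,
                      realized_gc3 = realized_gc3, stringsAsFactors = FALSE)
  list(records = .new_cds_set(ids, "", seqs), truth = truth,
       preferred = preferred, spec = spec)
}

#' Write a generated genome to disk
#'
#' @param genome output of [generate_genome()].
#' @param fasta_path multi-FASTA output path.
#' @param truth_path truth-table TSV path (optional).
#' @param spec_path optional plain-text key=value serialization of the spec
#'   (preferred codons included) for reproducibility.
#' @return named character vector of written paths, invisibly.
#' @export
write_genome <- function(genome, fasta_path, truth_path = NULL,
                         spec_path = NULL) {
  write_cds_fasta(genome$records, fasta_path)
  out <- c(fasta = fasta_path)
  if (!is.null(truth_path)) {
    utils::write.table(genome$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, truth = truth_path)
  }
  if (!is.null(spec_path)) {
    sp <- genome$spec
    keys <- setdiff(names(sp), "preferred_codons")
    lines <- c(vapply(keys, function(k) paste0(k, "=", sp[[k]]), character(1)),
               paste0("preferred_codons=",
                      paste(names(genome$preferred), genome$preferred,
                            sep = ":", collapse = ",")))
    writeLines(lines, spec_path)
    out <- c(out, spec = spec_path)
  }
  invisible(out)
}

.patterned_gene <- function(body_codons, reps) {
  paste0("ATG", paste(rep(body_codons, length.out = reps), collapse = ""), "TAA")
}

#' Write the standard test-fixture suite
#'
#' Four fixtures: (a) a mutation-only genome (wide GC3, s = 0) for ENC-curve
#' and neutrality checks; (b) a selection genome (planted preferred set,
#' bimodal s) for CAI / optimal-codon recovery; (c) a tiny five-gene
#' hand-checkable FASTA of patterned sequences; (d) a QC-stress file with
#' one planted defect per record. Truth TSVs accompany (a), (b) and (d).
#'
#' @param out_dir writable directory (created if absent).
#' @param seed base RNG seed.
#' @param n_mutation,n_selection genome sizes for fixtures (a) and (b).
#' @return named list of file paths plus the planted QC truth counts.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, n_mutation = 1000L,
                               n_selection = 2000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  mut <- generate_genome(genome_spec(n_genes = n_mutation,
                                     selection_strength = 0, seed = seed))
  write_genome(mut, p("mutation_only.fasta"), p("mutation_only_truth.tsv"),
               p("mutation_only_spec.txt"))

  # The selection fixture narrows the GC3 spread (Beta(12,12): mean 0.5,
  # sd 0.1) so translational selection is identifiable: under a wide GC3
  # distribution, compositional extremes dominate low ENC and the
  # ENC-seeded CAI reference conflates composition with expression.
  sel <- generate_genome(genome_spec(n_genes = n_selection,
                                     selection_strength = 1,
                                     selected_fraction = 0.25,
                                     gc3_shape1 = 12, gc3_shape2 = 12,
                                     seed = seed + 1L))
  write_genome(sel, p("selection.fasta"), p("selection_truth.tsv"),
               p("selection_spec.txt"))

  # hand-checkable patterns that still cover every degeneracy class, so
  # ENC/CAI are defined: one codon per amino-acid family (ENC = 20), the
  # full 61-sense-codon cycle (uniform usage, ENC = 61), and mixtures
  one_per_family_a <- c("GCA", "TGC", "GAC", "GAA", "TTC", "GGA", "CAC",
                        "ATA", "AAA", "CTA", "ATG", "AAC", "CCA", "CAA",
                        "AGA", "TCA", "ACA", "GTA", "TGG", "TAC")
  one_per_family_b <- c("GCT", "TGT", "GAT", "GAG", "TTT", "GGT", "CAT",
                        "ATT", "AAG", "CTT", "ATG", "AAT", "CCT", "CAG",
                        "CGT", "TCT", "ACT", "GTT", "TGG", "TAT")
  all_sense <- SENSE_CODONS
  tiny <- .new_cds_set(
    paste0("tiny", 1:5), "",
    c(.patterned_gene(one_per_family_a, 100),
      .patterned_gene(all_sense, 122),
      .patterned_gene(one_per_family_b, 100),
      .patterned_gene(all_sense, 100),
      .patterned_gene(c(one_per_family_a, all_sense), 162)))
  write_cds_fasta(tiny, p("tiny5.fasta"))

  clean <- function(n) paste(rep("GCT", n), collapse = "")
  qc <- .new_cds_set(
    c("ok", "short", "nontriplet", "ambiguous", "internalstop"), "",
    c(paste0("ATG", clean(99), "TAA"),                    # 303 nt, clean
      paste0("ATG", clean(78), "TAA"),                    # 240 nt: TOO_SHORT
      paste0("ATG", clean(99), "TAAA"),                   # 304 nt: NOT_TRIPLET
      paste0("ATG", "NNN", clean(97), "TAA"),             # 309 nt: HAS_AMBIGUITY
      paste0("ATG", "TAA", clean(97), "TAA")))            # 309 nt: INTERNAL_STOP
  write_cds_fasta(qc, p("qc_stress.fasta"))
  qc_truth <- data.frame(flag = c("TOO_SHORT", "NOT_TRIPLET", "HAS_AMBIGUITY",
                                  "INTERNAL_STOP"),
                         count = c(1L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  utils::write.table(qc_truth, p("qc_stress_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(mutation_fasta = p("mutation_only.fasta"),
       mutation_truth = p("mutation_only_truth.tsv"),
       selection_fasta = p("selection.fasta"),
       selection_truth = p("selection_truth.tsv"),
       tiny_fasta = p("tiny5.fasta"),
       qc_fasta = p("qc_stress.fasta"),
       qc_truth_path = p("qc_stress_truth.tsv"),
       qc_truth = qc_truth,
       mutation = mut, selection = sel)
}
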