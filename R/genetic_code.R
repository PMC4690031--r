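# Shared genetic-code tables. Standard nuclear code (translation table 1),
# taken from Biostrings; all internal bookkeeping uses DNA codon labels in
# alphabetical order (the order trinucleotideFrequency() emits), while
# user-facing tables carry RNA labels (AUG, GCU, ...).

GENETIC_CODE_DNA <- {
  gc <- Biostrings::GENETIC_CODE
  gc[sort(names(gc))]
}

ALL_CODONS  <- names(GENETIC_CODE_DNA)
STOP_CODONS <- ALL_CODONS[GENETIC_CODE_DNA == "*"]
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

AA_OF_CODON <- GENETIC_CODE_DNA[SENSE_CODONS]

# Synonymous families: 20 amino acids; Leu, Ser, Arg kept as single six-codon
# families (59 informative codons = sense codons minus Met and Trp).
SYN_FAMILIES <- split(SENSE_CODONS, AA_OF_CODON)
FAMILY_SIZE  <- vapply(SYN_FAMILIES, length, integer(1))
SINGLE_CODON_AAS <- names(FAMILY_SIZE)[FAMILY_SIZE == 1L]   # M, W
MULTI_FAMILIES   <- SYN_FAMILIES[FAMILY_SIZE > 1L]
INFORMATIVE_CODONS <- unname(unlist(MULTI_FAMILIES))

# Codons whose third position is synonymous-silent for GC3s purposes:
# all sense codons except the single-codon families (ATG, TGG).
SYNONYMOUS_CODONS <- setdiff(SENSE_CODONS, unlist(SYN_FAMILIES[SINGLE_CODON_AAS]))

# The eight fourfold-degenerate boxes used for PR2 analysis (third position
# fully silent): Ala GC*, Arg CG*, Gly GG*, Leu CT*, Pro CC*, Ser TC*,
# Thr AC*, Val GT*. Two-fold sub-boxes of Leu/Arg/Ser are excluded.
FOURFOLD_PREFIXES <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")
FOURFOLD_CODONS <- SENSE_CODONS[substr(SENSE_CODONS, 1, 2) %in% FOURFOLD_PREFIXES]

# Per-codon letter tallies and positional base identities, used by the
# composition module (rows in ALL_CODONS order).
CODON_LETTER_COUNTS <- {
  sp <- strsplit(ALL_CODONS, "")
  m <- vapply(c("A", "C", "G", "T"),
              function(b) vapply(sp, function(x) sum(x == b), integer(1)),
              integer(length(ALL_CODONS)))
  rownames(m) <- ALL_CODONS
  m
}

CODON_POS_BASE <- {
  m <- vapply(1:3, function(i) substr(ALL_CODONS, i, i), character(length(ALL_CODONS)))
  rownames(m) <- ALL_CODONS
  m
}

CODON_POS_GC <- CODON_POS_BASE %in% c("G", "C")
dim(CODON_POS_GC) <- dim(CODON_POS_BASE)
dimnames(CODON_POS_GC) <- dimnames(CODON_POS_BASE)

#' Convert codon labels between DNA and RNA alphabets
#'
#' @param x character vector of codons.
#' @return `rna_codon()` maps T to U; `dna_codon()` maps U to T.
#' @examples
#' rna_codon(c("ATG", "GCT"))
#' @export
rna_codon <- function(x) chartr("T", "U", toupper(x))

#' @rdname rna_codon
#' @export
dna_codon <- function(x) chartr("U", "T", toupper(x))

#' Genetic-code reference table
#'
#' One row per codon of the standard nuclear code with its amino acid and the
#' size of its synonymous family (six-codon families Leu/Ser/Arg undivided).
#'
#' @return data.frame with columns `codon` (DNA), `codon_rna`, `aa`
#'   (one-letter; `*` for stops), `family_size` (NA for stops).
#' @export
codon_table <- function() {
  aa <- unname(GENETIC_CODE_DNA[ALL_CODONS])
  fs <- ifelse(aa == "*", NA_integer_, FAMILY_SIZE[aa])
  data.frame(codon = ALL_CODONS, codon_rna = rna_codon(ALL_CODONS),
             aa = aa, family_size = as.integer(fs),
             stringsAsFactors = FALSE)
}
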