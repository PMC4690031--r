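# CDS input, canonicalization, QC filtering and codon counting.

.canonicalize_seq <- function(x) {
  x <- chartr("U", "T", toupper(x))
  # keep the IUPAC alphabet; anything else becomes N so downstream triplet
  # skipping treats it as an ambiguity
  gsub("[^ACGTRYSWKMBDHVN]", "N", x)
}

.new_cds_set <- function(id, description, seq) {
  df <- data.frame(id = as.character(id),
                   description = as.character(description),
                   seq = as.character(seq),
                   length_nt = nchar(seq),
                   stringsAsFactors = FALSE)
  class(df) <- c("cds_set", "data.frame")
  df
}

#' Read coding sequences from a (multi-)FASTA file
#'
#' Records may be line-wrapped, mixed case, DNA or RNA; sequences are
#' canonicalized to upper-case DNA (U mapped to T, non-IUPAC characters to N).
#' The record id is the header text up to the first whitespace; the remainder
#' is kept as `description`.
#'
#' @param path FASTA file, optionally gzipped.
#' @return A `cds_set` data.frame with columns `id`, `description`, `seq`,
#'   `length_nt`, one row per record in file order. An empty file yields an
#'   empty set with a warning; sequence data before the first header is a
#'   hard error naming the offending line.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 1000L)
  close(con)
  nonempty <- which(nzchar(trimws(head_lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(.new_cds_set(character(0), character(0), character(0)))
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(head_lines[first]), ">")) {
    stop("malformed FASTA: sequence data before first header at line ",
         first, " of ", path)
  }
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  .new_cds_set(id, desc, .canonicalize_seq(as.character(ss)))
}

#' Write a `cds_set` to FASTA
#'
#' @param records a `cds_set`.
#' @param path output file (gzipped if the name ends in .gz).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- ifelse(nzchar(records$description),
                      paste(records$id, records$description),
                      records$id)
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

.internal_stop_flag <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n < 2L) return(FALSE)
  starts <- seq.int(1L, by = 3L, length.out = n - 1L)  # exclude final triplet
  any(substring(seq, starts, starts + 2L) %in% STOP_CODONS)
}

#' Quality-control filtering of CDS records
#'
#' Flags every record for the four QC conditions and removes records failing
#' the enabled filters. The length filter (default 300 nt) is always applied;
#' non-triplet and internal-stop removal are opt-in because assembled or
#' ESTScan-reconstructed CDS frequently carry frame artifacts that are better
#' tallied than discarded. Ambiguity is tallied but never removes a record:
#' affected triplets are skipped at counting time.
#'
#' @param records a `cds_set`.
#' @param min_len minimum CDS length in nt (must be positive).
#' @param drop_not_triplet drop records whose length is not a multiple of 3.
#' @param drop_internal_stop drop records with an in-frame stop before the
#'   final triplet.
#' @return list with `kept` (a `cds_set` with logical flag columns
#'   `too_short`, `not_triplet`, `has_ambiguity`, `internal_stop`) and
#'   `report` (data.frame flag/count tallying each flag over the input,
#'   independently — a record can carry several flags).
#' @export
qc_filter <- function(records, min_len = 300L, drop_not_triplet = FALSE,
                      drop_internal_stop = FALSE) {
  if (!is.numeric(min_len) || min_len <= 0) {
    stop("min_len must be a positive length in nt")
  }
  too_short <- records$length_nt < min_len
  not_triplet <- records$length_nt %% 3L != 0L
  has_ambiguity <- grepl("[^ACGT]", records$seq)
  internal_stop <- vapply(records$seq, .internal_stop_flag, logical(1),
                          USE.NAMES = FALSE)
  report <- data.frame(
    flag = c("TOO_SHORT", "NOT_TRIPLET", "HAS_AMBIGUITY", "INTERNAL_STOP"),
    count = c(sum(too_short), sum(not_triplet), sum(has_ambiguity),
              sum(internal_stop)),
    stringsAsFactors = FALSE)
  drop <- too_short
  if (drop_not_triplet) drop <- drop | not_triplet
  if (drop_internal_stop) drop <- drop | internal_stop
  kept <- records[!drop, , drop = FALSE]
  kept$too_short <- too_short[!drop]
  kept$not_triplet <- not_triplet[!drop]
  kept$has_ambiguity <- has_ambiguity[!drop]
  kept$internal_stop <- internal_stop[!drop]
  class(kept) <- c("cds_set", "data.frame")
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

.new_codon_counts <- function(counts, skipped, source_ids) {
  counts <- counts[ALL_CODONS]
  storage.mode(counts) <- "double"
  structure(list(counts = counts,
                 n_codons = sum(counts),
                 skipped = skipped,
                 source_ids = source_ids),
            class = "codon_counts")
}

#' Count in-frame codons of a sequence
#'
#' Consecutive non-overlapping triplets from position 1; a trailing 1-2 nt
#' remainder is discarded; any triplet containing a non-ACGT character is
#' skipped and tallied in `skipped`.
#'
#' @param x a single sequence string, or a one-row `cds_set`.
#' @param id identifier recorded in `source_ids` (defaults to the record id).
#' @return A `codon_counts` object: `counts` (named vector over the 64
#'   codons), `n_codons`, `skipped`, `source_ids`.
#' @export
count_codons <- function(x, id = NULL) {
  if (inherits(x, "cds_set") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    if (is.null(id)) id <- x$id
    x <- x$seq
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.null(id)) id <- NA_character_
  x <- .canonicalize_seq(x)
  n_triplets <- nchar(x) %/% 3L
  if (n_triplets == 0L) {
    return(.new_codon_counts(stats::setNames(numeric(64), ALL_CODONS), 0L, id))
  }
  counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(x), step = 3)
  .new_codon_counts(counts, n_triplets - sum(counts), id)
}

#' Codon count matrix for a set of CDS records
#'
#' @param records a `cds_set`.
#' @return numeric matrix, one row per record (rownames = ids), one column per
#'   codon in alphabetical DNA order. Ambiguous triplets are skipped.
#' @export
codon_count_matrix <- function(records) {
  if (nrow(records) == 0L) {
    return(matrix(0, 0, 64, dimnames = list(NULL, ALL_CODONS)))
  }
  m <- Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(records$seq), step = 3)
  storage.mode(m) <- "double"
  rownames(m) <- records$id
  m[, ALL_CODONS, drop = FALSE]
}

#' Pool codon counts
#'
#' Cell-wise sum of `codon_counts` objects (or of the rows of a count
#' matrix); `source_ids` are concatenated.
#'
#' @param ... `codon_counts` objects, a list of them, or a single count matrix.
#' @return a pooled `codon_counts`.
#' @export
pool_codon_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.matrix(xs[[1L]])) {
    m <- xs[[1L]]
    return(.new_codon_counts(colSums(m), 0L, rownames(m)))
  }
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "codon_counts")) {
    xs <- xs[[1L]]
  }
  stopifnot(all(vapply(xs, inherits, logical(1), "codon_counts")))
  counts <- Reduce(`+`, lapply(xs, `[[`, "counts"))
  .new_codon_counts(counts,
                    sum(vapply(xs, `[[`, numeric(1), "skipped")),
                    unlist(lapply(xs, `[[`, "source_ids")))
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts:", x$n_codons, "codons from",
      length(x$source_ids), "source(s);", x$skipped, "ambiguous triplet(s) skipped\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(utils::head(sort(nz, decreasing = TRUE), 10))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report the `report` element of [qc_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
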