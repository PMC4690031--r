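test_that("FASTA records are canonicalized to upper-case DNA", {
  path <- write_temp_fasta(c(">g1 some description", "auggcc"))
  recs <- read_cds_fasta(path)
  expect_equal(recs$id, "g1")
  expect_equal(recs$description, "some description")
  expect_equal(recs$seq, "ATGGCC")
  expect_equal(recs$length_nt, 6L)

  path2 <- write_temp_fasta(c(">g1", "ATGAAATAA"))
  recs2 <- read_cds_fasta(path2)
  expect_equal(nrow(recs2), 1L)
  expect_equal(recs2$length_nt, 9L)
})

test_that("line-wrapped records and malformed/empty files are handled", {
  path <- write_temp_fasta(c(">g1", "ATGGCC", "GCTTAA", ">g2", "atguaa"))
  recs <- read_cds_fasta(path)
  expect_equal(recs$seq, c("ATGGCCGCTTAA", "ATGTAA"))

  bad <- write_temp_fasta(c("ATGGCC", ">g1", "ATG"))
  expect_error(read_cds_fasta(bad), "line 1")

  empty <- write_temp_fasta(character(0))
  expect_warning(recs0 <- read_cds_fasta(empty), "empty")
  expect_equal(nrow(recs0), 0L)
})

test_that("generated genomes round-trip through FASTA exactly", {
  g <- generate_genome(genome_spec(n_genes = 100, seed = 5))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(g$records, path)
  back <- read_cds_fasta(path)
  expect_identical(back$id, g$records$id)
  expect_identical(back$seq, g$records$seq)
})

test_that("qc_filter applies the 300 nt rule at its boundary and drop flags", {
  seqs <- c(strrep("GCT", 100),                       # 300 nt: kept
            substr(strrep("GCT", 100), 1, 299),      # 299 nt: dropped
            paste0(strrep("GCT", 100), "AC"),        # not triplet
            paste0("ATGTAA", strrep("GCT", 98)))     # internal stop at codon 2
  recs <- codonbias:::.new_cds_set(paste0("g", 1:4), "", seqs)
  res <- qc_filter(recs)
  expect_setequal(res$kept$id, c("g1", "g3", "g4"))
  expect_equal(res$report$count[res$report$flag == "TOO_SHORT"], 1L)
  expect_equal(res$report$count[res$report$flag == "INTERNAL_STOP"], 1L)

  strict <- qc_filter(recs, drop_not_triplet = TRUE, drop_internal_stop = TRUE)
  expect_equal(strict$kept$id, "g1")

  expect_error(qc_filter(recs, min_len = 0), "positive")
})

test_that("qc_filter counts planted defects and is idempotent", {
  good <- replicate(800, strrep("GCT", 100))
  short <- replicate(200, strrep("GCT", 80))
  recs <- codonbias:::.new_cds_set(sprintf("g%04d", 1:1000), "",
                                   sample(c(good, short)))
  res <- qc_filter(recs)
  expect_equal(nrow(res$kept), 800L)
  expect_equal(res$report$count[res$report$flag == "TOO_SHORT"], 200L)

  again <- qc_filter(res$kept[, 1:4], min_len = 300)
  expect_identical(again$kept$seq, res$kept$seq)
  expect_true(all(again$report$count[again$report$flag == "TOO_SHORT"] == 0))
})

test_that("count_codons counts in-frame triplets, discarding remainders and ambiguity", {
  cc <- count_codons("ATGGCCGCC")
  expect_equal(cc$n_codons, 3)
  expect_equal(unname(cc$counts[c("ATG", "GCC")]), c(1, 2))
  expect_equal(sum(cc$counts), 3)

  cc2 <- count_codons("ATGGC")
  expect_equal(cc2$n_codons, 1)
  expect_equal(unname(cc2$counts["ATG"]), 1)

  cc3 <- count_codons("ATGNNNGCC")
  expect_equal(cc3$n_codons, 2)
  expect_equal(cc3$skipped, 1)
})

test_that("codon counting matches a sliding-index brute-force tally", {
  set.seed(42)
  for (i in 1:5) {
    len <- sample(2990:3010, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    cc <- count_codons(seq)
    # independent tally: walk triplet starts, skip non-ACGT triplets
    starts <- seq.int(1, by = 3, length.out = len %/% 3)
    trips <- substring(seq, starts, starts + 2)
    clean <- trips[!grepl("[^ACGT]", trips)]
    brute <- table(clean)
    expect_equal(cc$n_codons, length(clean))
    expect_equal(cc$skipped, length(trips) - length(clean))
    for (cod in names(brute)) {
      expect_equal(unname(cc$counts[cod]), unname(as.numeric(brute[cod])))
    }
    # conservation: 3*counted + remainder + 3*skipped = length
    expect_equal(3 * cc$n_codons + len %% 3 + 3 * cc$skipped, len)
  }
})

test_that("pooled counts equal the cell-wise sum of per-gene counts", {
  g <- fx_mutation()
  sub <- g$records[1:20, ]
  per_gene <- lapply(seq_len(nrow(sub)), function(i) count_codons(sub[i, ]))
  pooled <- pool_codon_counts(per_gene)
  mat <- codon_count_matrix(sub)
  expect_equal(pooled$counts, colSums(mat))
  expect_equal(pooled$n_codons, sum(mat))
  # matrix route agrees with the object route
  expect_equal(pool_codon_counts(mat)$counts, pooled$counts)
})
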