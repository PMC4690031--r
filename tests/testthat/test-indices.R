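test_that("RSCU reproduces hand-computed and boundary values", {
  # published pooled Ala counts from the high-expression gene set
  r <- rscu(counts_of(GCA = 3868, GCC = 2761, GCG = 1464, GCU = 4338))
  expect_equal(round(r$rscu[r$codon == "GCA"], 3), 1.245)

  u <- rscu(counts_of(GGA = 5, GGC = 5, GGG = 5, GGU = 5))
  expect_equal(u$rscu[u$aa == "G"], rep(1, 4))

  b <- rscu(counts_of(AAA = 7, AAG = 0))
  expect_equal(b$rscu[b$codon == "AAA"], 2)
  expect_equal(b$rscu[b$codon == "AAG"], 0)

  m <- rscu(counts_of(AUG = 3, UGG = 2))
  expect_equal(m$rscu[m$codon %in% c("AUG", "UGG")], c(1, 1))
})

test_that("RSCU family means are 1 for every observed family (fuzzed)", {
  set.seed(11)
  for (i in 1:25) {
    r <- rscu(random_counts(sample(c(5, 50, 500), 1)))
    means <- tapply(r$rscu, r$aa, mean)
    expect_equal(as.numeric(means[!is.na(means)]),
                 rep(1, sum(!is.na(means))), tolerance = 1e-12)
    k <- tapply(r$family_size, r$aa, unique)
    expect_true(all(r$rscu <= r$family_size + 1e-12, na.rm = TRUE))
    # unobserved families are NA, not 0
    expect_true(all(is.na(r$rscu[tapply(r$count, r$aa, sum)[r$aa] == 0])))
  }
})

test_that("RSCU agrees with an independent implementation on a real sequence", {
  g <- fx_mutation()
  seq <- g$records$seq[1]
  mine <- rscu(count_codons(seq))
  other <- seqinr::uco(unlist(strsplit(tolower(seq), "")), index = "rscu")
  names(other) <- toupper(names(other))
  both <- intersect(mine$codon_dna[!is.na(mine$rscu)], names(other))
  expect_gt(length(both), 40)
  expect_equal(mine$rscu[match(both, mine$codon_dna)],
               unname(other[both]), tolerance = 1e-9)
})

test_that("ENC hits its analytic endpoints: 20 and 61", {
  one_per_family <- counts_of(
    GCA = 2, UGC = 2, GAC = 2, GAA = 2, UUC = 2, GGA = 2, CAC = 2, AUA = 2,
    AAA = 2, CUA = 2, AUG = 2, AAC = 2, CCA = 2, CAA = 2, AGA = 2, UCA = 2,
    ACA = 2, GUA = 2, UGG = 2, UAC = 2)
  expect_equal(enc(one_per_family)$enc_obs, 20)

  uniform <- stats::setNames(rep(100, 64), names(counts_of()))
  expect_equal(enc(uniform)$enc_obs, 61)

  # short genes are flagged missing, not extrapolated
  short <- enc(counts_of(AAA = 5, AAG = 5))
  expect_true(is.na(short$enc_obs))
  expect_equal(short$flag, "LOW_CODONS")
})

test_that("ENC matches an independently coded textbook implementation", {
  # independent route: explicit per-amino-acid loop over usage proportions
  textbook_enc <- function(v) {
    gc <- Biostrings::GENETIC_CODE
    aas <- setdiff(unique(gc), c("*", "M", "W"))
    fam_F <- list()
    for (aa in aas) {
      cods <- names(gc)[gc == aa]
      n <- sum(v[cods])
      if (n <= 1) next
      p <- v[cods] / n
      F <- (n * sum(p^2) - 1) / (n - 1)
      if (F <= 0) next
      fam_F[[aa]] <- c(k = length(cods), F = F)
    }
    tab <- do.call(rbind, fam_F)
    fbar <- function(k) mean(tab[tab[, "k"] == k, "F"])
    f2 <- fbar(2); f4 <- fbar(4); f6 <- fbar(6)
    f3 <- if (any(tab[, "k"] == 3)) fbar(3) else (f2 + f4) / 2
    if (any(is.nan(c(f2, f4, f6)))) return(NA_real_)
    min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6)
  }
  mat <- fx_mutation_counts()[1:50, ]
  mine <- enc_table(mat)
  ref <- apply(mat, 1, textbook_enc)
  ok <- mine$flag == "OK"
  expect_gt(sum(ok), 40)
  expect_equal(mine$enc[ok], unname(ref[ok]), tolerance = 1e-9)
})

test_that("expected ENC curve evaluates and is near-symmetric in s", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - expected_enc(1 - s), s - (1 - s),
               tolerance = 1e-12)
  expect_error(expected_enc(1.2), "0, 1")
})

test_that("ENC deviation is the relative gap to the expected curve", {
  expect_equal(enc_deviation(expected_enc(0.3), 0.3), 0)
  expect_equal(enc_deviation(54.45, 0.5), 0.1)
  expect_true(is.na(enc_deviation(NA_real_, 0.5)))
})

test_that("sampled uniform usage approaches ENC 61 from below as genes grow", {
  set.seed(99)
  cods <- setdiff(names(counts_of()), c("TAA", "TAG", "TGA"))
  mean_enc <- vapply(c(100, 400, 3000), function(n) {
    mean(replicate(20, {
      v <- counts_of()
      draw <- table(sample(cods, n, replace = TRUE))
      v[names(draw)] <- as.numeric(draw)
      enc(v)$enc_obs
    }))
  }, numeric(1))
  expect_true(all(diff(mean_enc) > 0))
  expect_true(all(mean_enc < 61))
})

test_that("CAI weight construction follows the floor and normalization rules", {
  # reference using a single codon per family
  mat <- rbind(ref = counts_of(AAA = 50, GGA = 50, TTT = 40))
  model <- build_cai_model(mat, reference_ids = rep("ref", 5))
  w <- model$weights
  expect_equal(unname(w[c("AAA", "GGA", "TTT")]), c(1, 1, 1))
  expect_equal(unname(w[c("AAG", "GGC", "TTC")]), c(0.01, 0.01, 0.01))
  # unobserved family: neutral weights
  expect_equal(unname(w[c("CAA", "CAG")]), c(1, 1))

  uni <- rbind(ref = stats::setNames(rep(10, 64), names(counts_of())))
  muni <- build_cai_model(uni, reference_ids = rep("ref", 5))
  expect_equal(unname(muni$weights), rep(1, 61))
})

test_that("CAI equals its geometric-mean definition", {
  mat <- rbind(ref = counts_of(AAA = 50, GGA = 50, TTT = 40))
  model <- build_cai_model(mat, reference_ids = rep("ref", 5))
  expect_equal(cai(counts_of(AAA = 10, GGA = 7), model), 1)

  w25 <- model$weights
  w25["AAG"] <- 0.25
  model25 <- structure(list(weights = w25, reference_ids = "ref", floor = 0.01),
                       class = "cai_model")
  expect_equal(cai(counts_of(AAA = 5, AAG = 5), model25), 0.5)

  # Met/Trp/stops are excluded from the geometric mean
  expect_equal(cai(counts_of(AAA = 5, AAG = 5, AUG = 50, UGG = 50, UAA = 3),
                   model25), 0.5)

  # length invariance: scaling counts leaves CAI unchanged
  g <- fx_mutation_counts()
  m2 <- build_cai_model(g)
  v <- g[7, ]
  expect_equal(cai(v, m2), cai(v * 13, m2), tolerance = 1e-12)

  # brute-force log-domain recomputation over 100 genes
  tab <- cai_table(g[1:100, ], m2)
  brute <- vapply(1:100, function(i) {
    v <- g[i, ]
    tot <- 0; nn <- 0
    for (cod in names(v)) {
      aa <- Biostrings::GENETIC_CODE[[cod]]
      if (aa %in% c("*", "M", "W")) next
      tot <- tot + v[[cod]] * log(m2$weights[[cod]])
      nn <- nn + v[[cod]]
    }
    exp(tot / nn)
  }, numeric(1))
  expect_equal(tab$cai, brute, tolerance = 1e-12)
})

test_that("ENC falls and CAI rises with selection strength", {
  enc_means <- numeric(0); cai_means <- numeric(0)
  pref <- generate_genome(genome_spec(n_genes = 1, seed = 77))$preferred
  ref_model <- NULL
  for (s in c(0, 0.75, 1.5)) {
    g <- generate_genome(genome_spec(n_genes = 200, selection_strength = s,
                                     selected_fraction = 1,
                                     gc3_shape1 = 12, gc3_shape2 = 12,
                                     preferred_codons = pref, seed = 303))
    cm <- codon_count_matrix(g$records)
    enc_means <- c(enc_means, mean(enc_table(cm)$enc, na.rm = TRUE))
    if (is.null(ref_model)) {
      # weights anchored on the planted preferred set
      v <- counts_of()
      v[unname(pref)] <- 100
      ref_model <- build_cai_model(rbind(ref = v), reference_ids = rep("ref", 5))
    }
    cai_means <- c(cai_means, mean(cai_table(cm, ref_model)$cai, na.rm = TRUE))
  }
  expect_true(all(diff(enc_means) < 0))
  expect_true(all(diff(cai_means) > 0))
})
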