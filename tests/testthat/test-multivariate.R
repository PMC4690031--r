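test_that("neutrality statistics recover identity and flat relationships", {
  gc3 <- seq(0.1, 0.9, length.out = 20)
  ident <- neutrality_stats(gc3, gc3)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$rho, 1, tolerance = 1e-12)

  flat <- neutrality_stats(rep(0.4, 20), gc3)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(flat$rho))  # rank correlation undefined for constant GC12

  const_x <- neutrality_stats(gc3, rep(0.5, 20))
  expect_true(is.na(const_x$slope))

  expect_error(neutrality_stats(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("shared mutational pressure yields a near-unit neutrality slope", {
  g <- generate_genome(genome_spec(n_genes = 500, seed = 404))
  comp <- composition_table(codon_count_matrix(g$records))
  ns <- neutrality_stats(comp$gc12, comp$gc3)
  expect_gt(ns$slope, 0.7)
  expect_lt(ns$slope, 1.1)
  expect_gt(ns$rho, 0)
  expect_lt(ns$p_value, 0.01)
})

test_that("correspondence analysis satisfies decomposition conservation", {
  mat <- rscu_matrix(fx_mutation_counts()[1:60, ])
  res <- coa_rscu(mat)
  expect_equal(sum(res$inertia_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(res$inertia_fraction) <= 1e-12))
  expect_lte(length(res$inertia_fraction), 58)  # <= min(n_genes, 59) - 1
  expect_equal(res$axes_kept, 4)
  expect_equal(dim(res$gene_coords), c(60, 4))
})

test_that("CA coordinates match a definitional eigen-decomposition oracle", {
  set.seed(21)
  mat <- t(replicate(20, random_counts(400)))
  rownames(mat) <- paste0("g", 1:20)
  rmat <- rscu_matrix(mat)
  res <- coa_rscu(rmat, axes_kept = 3)

  # independent small-scale CA from the definitional eigen-decomposition
  X <- rmat; X[is.na(X)] <- 0
  P <- X / sum(X)
  r <- rowSums(P); cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cm) %*% diag(1 / sqrt(cm))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  lam <- ev$values[ev$values > 1e-12]
  expect_equal(res$inertia_fraction[1:3], (lam / sum(lam))[1:3], tolerance = 1e-8)
  for (k in 1:3) {
    oracle_k <- (ev$vectors[, k] / sqrt(r)) * sqrt(ev$values[k])
    agree <- min(max(abs(res$gene_coords[, k] - oracle_k)),
                 max(abs(res$gene_coords[, k] + oracle_k)))
    expect_lt(agree, 1e-8)
  }
})

test_that("planted clusters with disjoint preferred codons separate on Axis 1", {
  mk <- function(pref_seed, seed) {
    pref <- generate_genome(genome_spec(n_genes = 1, seed = pref_seed))$preferred
    generate_genome(genome_spec(n_genes = 30, selection_strength = 2,
                                selected_fraction = 1,
                                gc3_shape1 = 50, gc3_shape2 = 50,
                                preferred_codons = pref, seed = seed))
  }
  a <- mk(1, 10); b <- mk(8, 20)
  stopifnot(any(a$preferred != b$preferred))
  recs <- rbind(a$records, b$records)
  recs$id <- c(paste0("a", 1:30), paste0("b", 1:30))
  rmat <- rscu_matrix(codon_count_matrix(recs))
  res <- coa_rscu(rmat)
  ax1a <- res$gene_coords[1:30, 1]; ax1b <- res$gene_coords[31:60, 1]
  expect_true(max(ax1a) < min(ax1b) || max(ax1b) < min(ax1a))
})

test_that("Axis 1 is oriented to correlate positively with GC3", {
  cm <- fx_mutation_counts()
  comp <- composition_table(cm)
  res <- coa_rscu(rscu_matrix(cm), gc3 = stats::setNames(comp$gc3, comp$id))
  rho <- stats::cor(res$gene_coords[, 1], comp$gc3, method = "spearman")
  expect_gte(rho, 0)
})

test_that("correlation table equals rank-then-Pearson recomputation", {
  set.seed(33)
  n <- 200
  df <- data.frame(x = rnorm(n))
  df$y <- df$x + rnorm(n)
  df$z <- runif(n)
  df$w <- -df$x + rnorm(n, sd = 0.5)
  ct <- correlation_table(df)
  expect_equal(diag(ct$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(ct$rho))
  brute <- stats::cor(apply(df, 2, rank))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(ct$rho[i, j], brute[i, j], tolerance = 1e-12)
  }
})

test_that("Spearman statistics are invariant to monotone transforms and detect perfect anti-monotonicity", {
  x <- sort(runif(30)); y <- -2 * x + 5
  ct <- correlation_table(data.frame(x = x, y = y))
  expect_equal(ct$rho["x", "y"], -1)

  df1 <- data.frame(a = x, b = x^2 + 1)
  df2 <- data.frame(a = exp(x), b = log(x^2 + 1))   # monotone transforms
  expect_equal(correlation_table(df1)$rho, correlation_table(df2)$rho,
               tolerance = 1e-12, ignore_attr = TRUE)

  const <- correlation_table(data.frame(a = x, b = rep(1, 30)))
  expect_true(is.na(const$rho["a", "b"]))
})
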