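# Shared fixtures, generated once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- make()
  .fx[[name]]
}

# small mutation-only genome (wide GC3, no selection)
fx_mutation <- function() fx_cached("mutation", function() {
  generate_genome(genome_spec(n_genes = 300, selection_strength = 0, seed = 101))
})

# composition-controlled selection genome (planted preferred set, bimodal s)
fx_selection <- function() fx_cached("selection", function() {
  generate_genome(genome_spec(n_genes = 600, selection_strength = 1,
                              selected_fraction = 0.25,
                              gc3_shape1 = 12, gc3_shape2 = 12, seed = 202))
})

fx_mutation_counts <- function() fx_cached("mutation_counts", function() {
  codon_count_matrix(fx_mutation()$records)
})

fx_selection_counts <- function() fx_cached("selection_counts", function() {
  codon_count_matrix(fx_selection()$records)
})

# a random multinomial codon-count vector over the 64 codons
random_counts <- function(n_codons = 300, concentration = 1) {
  p <- stats::rgamma(64, concentration)
  cnt <- as.vector(stats::rmultinom(1, n_codons, p / sum(p)))
  stats::setNames(as.numeric(cnt), names(Biostrings::GENETIC_CODE)[
    order(names(Biostrings::GENETIC_CODE))])
}

# counts built from an explicit codon:count specification
counts_of <- function(...) {
  spec <- c(...)
  cods <- sort(names(Biostrings::GENETIC_CODE))
  v <- stats::setNames(numeric(64), cods)
  v[chartr("U", "T", toupper(names(spec)))] <- as.numeric(spec)
  v
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
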