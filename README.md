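# codonbias

Synonymous codon usage bias analysis for transcriptome-scale collections of
coding sequences (CDS), written for molecular-evolution studies of
non-model organisms whose genomes are known only through RNA-Seq. It
implements the standard analysis chain used to dissect mutation versus
translational selection in species such as the herbaceous peony
(*Paeonia lactiflora*), an AT-rich eudicot transcriptome of ~24,000
reconstructed CDS:

* **QC and counting** — FASTA input, canonicalization, the conventional
  300 nt length filter, in-frame codon counting with per-triplet ambiguity
  skipping.
* **Composition** — base fractions, positional GC (GC1, GC2, GC3, GC12,
  GC3s), and PR2-bias coordinates A3/(A3+T3) vs G3/(G3+C3) over the eight
  fourfold-degenerate codon boxes.
* **Indices** — RSCU (for codon *c* in a *k*-codon family with total
  *N\_f*: RSCU = *n\_c* / (*N\_f* / *k*)); Wright's effective number of
  codons ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ from family codon
  homozygosities F̂ = (*n*·Σp̂² − 1)/(*n* − 1); the expected-ENC null curve
  ENC\* = 2 + s + 29/(s² + (1−s)²) and the relative deviation
  (ENC\* − ENC)/ENC\*; CAI as the geometric mean of relative-adaptiveness
  weights with an explicit, reproducible reference-set policy (lowest-ENC
  seed, one CAI-ranked refinement).
* **Multivariate** — neutrality-plot statistics (OLS slope of GC12 on GC3
  plus Spearman rho), correspondence analysis of the gene × 59-codon RSCU
  matrix, and the Spearman correlation table among indices.
* **Optimal codons** — partition genes by the 5% CAI extremes, pool group
  counts, test each codon against the rest of its synonymous family with a
  2×2 Pearson chi-square, and flag codons with *p* < 0.01 and
  ΔRSCU ≥ 0.08 toward the high-expression group.
* **Synthetic genomes** — a CDS generator with controlled mutational GC
  pressure, planted preferred-codon sets and expression structure, so the
  whole pipeline is testable against ground truth without any download.

## Worked example

```r
library(codonbias)

# simulate a transcriptome-like CDS set with translational selection
g <- generate_genome(genome_spec(n_genes = 1000, selection_strength = 1,
                                 selected_fraction = 0.25,
                                 gc3_shape1 = 12, gc3_shape2 = 12, seed = 7))
counts <- codon_count_matrix(g$records)
comp   <- composition_table(counts)

round(c(mean_gc = mean(comp$gc_all), mean_gc3 = mean(comp$gc3)), 3)
#>  mean_gc mean_gc3
#>    0.509    0.558

ns <- neutrality_stats(comp$gc12, comp$gc3)
round(c(slope = ns$slope, rho = ns$rho), 3)
#> slope   rho
#> 0.802 0.805

et <- enc_table(counts)
summary(round(et$enc, 1))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#>   32.50   50.60   56.30   54.78   61.00   61.00       1

model <- build_cai_model(counts)
cv    <- cai_table(counts, model)
part  <- partition_by_cai(cv$id, cv$cai)
cmp   <- group_comparison(counts, part$high, part$low)
sort(optimal_codon_set(cmp))
#>  [1] "AAG" "AAU" "ACU" "AGU" "AUC" "CAC" "CAG" "CCU" "CGA" "CUG" "GAC" "GAG"
#> [13] "GCC" "GGC" "GUG" "UAU" "UGC" "UUC"
```

The slope near 1 with strong positive rho is the mutation-dominated
neutrality regime; the bimodal ENC distribution (unselected genes near 61,
selected genes in the 40s–50s) reflects the planted selection; and the
18-codon optimal set recovered here equals the generator's planted
preferred set exactly (`sort(rna_codon(g$preferred))`).

`run_pipeline(pipeline_config("cds.fasta", "out/"))` performs the whole
analysis in one call and writes the per-gene index table, pooled RSCU,
correlation table with significance stars, correspondence-analysis
coordinates and inertias, the high/low comparison table, and the standard
figures (GC histogram, neutrality plot, ENC plot with expected curve,
deviation histogram, CA scatters, PR2 plot). A command-line wrapper is in
`inst/scripts/codon_pipeline.R`.

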