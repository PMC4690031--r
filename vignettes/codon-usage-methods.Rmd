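---
title: "Methods: codon usage bias analysis with codonbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# The scientific problem

Synonymous codons are not used equally. Two forces dominate the pattern in
most genomes: directional mutation pressure, which drags nucleotide
composition (visible most clearly at the selectively silent third codon
position), and translational selection, which favours codons matching the
abundant tRNA pool in highly expressed genes. `codonbias` implements the
standard battery of statistics used to separate the two in
transcriptome-scale CDS collections — composition profiles, RSCU, ENC with
its compositional null curve, CAI, neutrality and PR2 plots,
correspondence analysis, and high-versus-low-expression optimal-codon
tests — together with a synthetic genome generator that provides ground
truth for every stage.

# Sequence handling

Input CDS are read from multi-FASTA (gzip accepted), upper-cased, U
mapped to T, and non-IUPAC characters mapped to N. Counting walks frame 0
in non-overlapping triplets; a trailing 1–2 nt remainder is discarded and
any triplet containing a non-ACGT character is skipped and tallied, so a
single ambiguous base costs one codon rather than the whole gene. The
conventional length filter removes CDS under 300 nt. Non-triplet lengths
and internal stop codons are flagged and tallied but do **not** remove a
record by default: reconstructed CDS (BLASTx/ESTScan-style) often carry
frame artifacts, and discarding them wholesale would bias the sample. Both
strict behaviours are available as flags. The reading frame is always
frame 0 of the provided sequence; no ORF re-detection is attempted. The
genetic code is the standard nuclear code (translation table 1).

A terminal stop codon is counted in the raw codon counts but excluded
from every index: RSCU, ENC and CAI operate on the 61 sense codons, with
the six-codon families Leu, Ser and Arg kept whole (k = 6), matching the
conventional 59-informative-codon accounting of codon-usage
correspondence analysis.

# Indices

**RSCU.** For codon $c$ in a synonymous family of size $k$ with family
total $N_f$, $\mathrm{RSCU}_c = n_c/(N_f/k)$. Values are missing (not
zero) for families the gene never uses: an absent amino acid is not an
avoided codon.

**ENC.** The estimator is Wright's: per observed family with $n$ codons
and usage proportions $\hat p$, the codon homozygosity is
$\hat F = (n\sum \hat p^2 - 1)/(n-1)$; families with $n \le 1$ or
$\hat F \le 0$ are omitted from their degeneracy-class mean, and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
with $\bar F_3 \leftarrow (\bar F_2 + \bar F_4)/2$ when the single
three-fold family (Ile) is not computable. The result is capped at 61 but
not below 20: values below 20 on short genes are reported as computed,
with genes under 30 sense codons (configurable) flagged missing rather
than extrapolated, as are genes missing an entire 2-, 4- or 6-fold class.

**Expected ENC and deviation.** The compositional null is
$\mathrm{ENC}^\ast(s) = 2 + s + 29/(s^2 + (1-s)^2)$, with $s$ the
third-position GC over synonymous codons only (GC3s: Met, Trp and stops
excluded). The per-gene relative deviation is
$(\mathrm{ENC}^\ast - \mathrm{ENC})/\mathrm{ENC}^\ast$, reported binned at
width 0.1. Note a property that matters when interpreting the histogram:
the closed-form curve is an approximation that sits slightly *below* the
true expectation of uniform usage at mid-range $s$ (it gives 60.5 at
$s = 0.5$ where unbiased usage tends to 61), so a purely
mutation-driven gene population centres at a slightly **negative**
deviation (mode in $[-0.1, 0)$), with selection shifting mass rightward.
Empirical histograms peaking in $[0, 0.1)$ therefore already indicate
mild bias beyond composition.

**CAI.** $\mathrm{CAI} = \exp\!\big(\sum_c n_c \ln w_c / \sum_c n_c\big)$
over all counted codons except Met, Trp and stops, with relative
adaptiveness $w_c$ equal to the reference set's within-family count ratio
$n_c/\max_{c'} n_{c'}$, floored at 0.01 so the geometric mean never hits
zero (a family wholly unobserved in the reference gets neutral weights 1:
no information, no penalty). Because no expression data accompany a
de novo transcriptome, the reference set must come from the sequences
themselves; the default policy seeds with the 5% of genes of lowest ENC
(strongest bias), computes CAI, re-selects the top 5% by CAI and
recomputes the weights once. The policy only has to *rank* genes
sensibly — the downstream optimal-codon procedure consumes nothing else —
and a user-supplied reference set overrides it.

**GC3 vs GC3s.** Both are computed and reported: the ENC plot abscissa
uses GC3s, while the neutrality plot uses GC3 over all codons (stops
included). The two are frequently conflated in the literature, so the
per-gene table carries both columns explicitly.

# Multivariate analyses

**Neutrality plot.** OLS of GC12 on GC3 across genes, plus the Spearman
rank correlation, reported separately (the slope answers "how much of the
third-position pressure reaches the first two positions", the rank
statistic answers "is the association monotone"). A slope near 1 with a
strong positive correlation indicates mutation-dominated evolution. When
either variable is constant the rank correlation is undefined and
reported missing rather than zero.

**Correspondence analysis.** CA is run on the gene × 59 RSCU matrix —
the field's convention for codon usage, although non-classical (the
classical variant on raw counts is available via `input = "counts"`).
Row/column masses come from matrix totals, the chi-square standardized
residual matrix is decomposed by SVD, genes and codons get principal
coordinates, and per-axis inertia fractions are reported for all
non-trivial axes (they sum to 1). Four axes of coordinates are kept by
default. CA axis signs are arbitrary; Axis 1 is oriented so its Spearman
correlation with gene GC3 is non-negative, which makes cross-run
correlation tables reproducible in sign. Genes with missing family RSCU
are imputed at 0 and flagged.

**Correlation table.** Pairwise Spearman rho with two-sided p-values over
GC12, GC3, GCall, ENC, CAI, Axis 1 and protein length,
pairwise-complete, with significance stars at 0.05/0.01 in the rendered
report.

# Optimal codons

Genes are ranked by CAI; the top and bottom `floor(0.05 N)` genes form
the high- and low-expression sets (ties broken by stable input order).
Codon counts are pooled per group and each codon in a multi-codon family
is tested on the 2×2 table [codon vs other codons of its own family] ×
[high vs low] with Pearson's chi-square, df = 1, no continuity correction
(counts are large; Yates is available by flag). The comparison is
family-relative because RSCU is family-relative. A codon is *optimal*
when $p < 0.01$ **and** $\Delta\mathrm{RSCU} =
\mathrm{RSCU}_{high} - \mathrm{RSCU}_{low} \ge 0.08$ — significance plus
direction and effect size. The chi-square alone is symmetric: without the
direction term, codons significantly *avoided* in highly expressed genes
would be flagged too. No multiple-testing correction is applied by
default, mirroring common practice in this literature; Bonferroni/BH are
one flag away.

# The synthetic genome generator

The generator exists so that every pipeline stage can be validated
against planted truth, and its defaults emulate an AT-rich de novo plant
transcriptome:

* **Lengths**: log-normal protein lengths, meanlog $\log 160$, sdlog 0.5,
  truncated at 100 codons — a ~500 bp mean CDS with a 300 bp floor,
  typical of BLASTx/ESTScan-reconstructed transcripts.
* **Mutational pressure**: each gene draws a third-position GC target $m$
  from Beta(1.9, 2.6) (mean ~0.42, wide: realized per-gene GC3 spans
  roughly 0.1–0.97), and third bases are sampled with G and C sharing
  weight $m$, A and T sharing $1-m$.
* **GC12 coupling**: amino acids are sampled with weight
  $\exp\{g_{12}(aa) \cdot (0.435 + 4(2m-1))\}$, where $g_{12}(aa)$ is the
  family's mean first/second-position GC. The two constants were fixed
  once, analytically, so the default genome has mean overall GC ≈ 0.44
  and a GC12~GC3 neutrality slope near 1 — the mutation-dominated regime
  the generator is meant to emulate. With the coupling at 0, amino acids
  are uniform over the 20.
* **Selection**: a fraction of genes (default 25%, carrying the
  `expressed` truth label) multiplies the sampling weight of one planted
  preferred codon per family by $e^{s}$.
* **Stops**: one stop codon, uniform over TAA/TAG/TGA, appended per gene.

Two standard study conditions are wrapped in `make_fixture_suite()`: a
**mutation-only** genome (wide GC3, $s=0$) for ENC-curve and neutrality
properties, and a **selection** genome for CAI and optimal-codon
recovery. The selection genome narrows the GC3 targets to Beta(12, 12)
(mean 0.5, sd 0.1). This is deliberate: under a wide GC3 spread,
compositional extremes (GC3 ≈ 0.1) reach lower ENC than mildly selected
genes, the lowest-ENC CAI seed then locks onto composition, and the
recovered "optimal" set is simply the A/U-ending codon set — the classic
composition/selection confound. The confound is real in real data too,
which is why CAI-based expression proxies must be interpreted cautiously
in strongly compositionally heterogeneous transcriptomes; the narrow-GC3
fixture isolates the selection signal the recovery tests are about. At
$s = 1$, $n = 2000$, the pipeline recovers the planted 18-codon set with
sensitivity and precision 1.0.

## What the generator does not emulate

Real transcriptomes add assembly chimerism, frame errors beyond simple
offsets, within-gene composition heterogeneity, amino-acid usage driven
by proteome function rather than mutation pressure, and expression labels
from actual read counts. Passing the synthetic-recovery tests therefore
demonstrates the *statistics* are computed correctly and the procedure is
internally consistent — not that CAI-ranked extremes of a particular real
transcriptome coincide with true expression extremes.

# Numerical choices and degenerate inputs

* Codon counting, composition and all indices are exact arithmetic on
  counts; no tolerance parameters enter before the multivariate stage.
* CA drops numerically-zero singular values at
  `max(dim) * max(d) * 10 * eps` and reports inertia over the retained
  axes; a rank-deficient matrix (e.g. one distinct row) yields zero
  non-trivial axes.
* Empty count vectors yield all-missing profiles; zero denominators
  (PR2 biases, GC3s with no synonymous codon, CAI with no eligible
  codon) yield missing values, never 0/0 artifacts.
* Partition ties are broken by stable input order, making the pipeline
  deterministic for a fixed input and seed.
* Spearman p-values use the asymptotic approximation (`exact = FALSE`)
  uniformly, so results do not switch methods across sample sizes.

# Problem sizes used in the test suite

Module tests run on 250–600-gene genomes; the end-to-end recovery checks
use 1,000–2,000 genes, the sizes at which the selection/composition
separation and the deviation-histogram shape stabilize. The full suite
completes in well under a minute on a single core.

# Known limitations

* The ENC-seeded CAI reference policy conflates composition with
  expression on compositionally extreme gene sets (see above).
* ENC values below 20 occur on short or highly biased genes; they are
  reported as computed (flagged when under the codon minimum) because
  truncating at the theoretical floor would hide estimator behaviour.
* The PR2 module restricts to the eight fourfold boxes; an all-codons
  variant exists behind a flag but mixes amino-acid composition into the
  third-position signal.
* No dinucleotide/codon-pair statistics, no tAI/Fop/CBI, no detrended or
  within-group CA.
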