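---
title: "Models and methods behind regland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

regland implements the computational chain of an open-chromatin study:
cut-site level processing of ATAC-seq/FAIRE-seq fragments, differential
accessibility of regulatory regions across conditions, classification of
region dynamics over a time course, recovery-curve motif enrichment,
transcription-factor footprinting, and linkage of regions to genes and
expression. This vignette explains the models, the defaults and the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Coordinates and cut sites

All intervals are BED-convention tibbles: 0-based, half-open
`[start, end)`. The cut site of a single-end read is its 5' end — the
`start` coordinate of a `+` read, the `end` coordinate of a `-` read
(whose 5' *base* is `end - 1`, as BED ends are exclusive). For coverage
tracks each cut is extended 5 bp on either side of the cut base, an
11 bp window `[base - 5, base + 6)`; a minus-strand cut recorded at
coordinate `pos` therefore materializes as `[pos - 6, pos + 5)`. No
Tn5 +4/−5 offset correction is applied by default (`tn5_shift` turns it
on); the offset is a convention choice that cancels in every aggregate
statistic the package computes, and leaving the data unshifted keeps
cut coordinates identical to what the aligner reported.

Interval merging is single linkage with ≥ 1 bp overlap, so abutting
half-open intervals remain separate. The same operator builds the
combined peak set across samples and clusters differential peaks into
unique candidate regions.

## Differential accessibility

Counts of cut sites per region follow a negative binomial model. For
region *i* and sample *j*,

`log mu_ij = log(sf_j) + batch_j * beta_b,i + cond_j * beta_c,i + beta_0,i`

with size factors `sf_j` from median-of-ratios (the median over
all-positive regions of the count divided by the region's geometric
mean). The assay (ATAC vs FAIRE) enters as the batch covariate whenever
both are present, so the two techniques act as replicates of each other.

The dispersion `alpha_i` is estimated per region by method of moments on
the Poisson-fitted means, `alpha = sum((y - mu)^2 - mu) / mu^2 / df`,
then shrunk 50/50 toward a mean–dispersion trend
`alpha ~ a0 + a1 / baseMean` fitted across all regions. Because the
trend borrows information from the whole matrix, the Wald statistic on
the condition coefficient is referred to a *t* distribution with
moderated degrees of freedom `df_residual + df_prior`, where
`df_prior = df_residual * (1 - w) / w` for shrinkage weight `w` — with
the default `w = 0.5` the residual degrees of freedom double (at 3 vs 3
samples and three coefficients: df = 6). In null simulations at
dispersion 0.1 this yields a type-I error of 0.03–0.04 at nominal 0.05;
a plain normal reference was markedly anti-conservative (0.08–0.10).
The heavier *t* tails also mean very small p-values saturate around
1e-4 at this sample size — adequate for effect sizes and depths of
desk-scale simulations, while deeply sequenced real data with large z
statistics still reach far smaller values.

Two degenerate cases are handled explicitly: all-zero regions are
reported with `NA` p-values and excluded from multiple testing, and
complete separation (one condition all zeros) triggers a refit on
`y + 0.5`, since the unpenalized Wald statistic otherwise degenerates
(the coefficient diverges faster than its standard error). Multiple
testing uses Benjamini–Hochberg.

One consequence of median-of-ratios worth knowing: with strongly
asymmetric differential signal (many regions opening, few closing) the
size factors absorb part of the shift, biasing null log-ratios by a few
percent. The generator's symmetric default (`frac_open = frac_close`)
avoids conflating this with estimation error in tests.

## Region dynamics

Given differential tables wild-type → early tumor (`we`) and early →
late tumor (`el`), classes follow strict inequalities:
*stable* (`lfc_we > 1` and `-0.2 < lfc_el < 0.2`), *gradual*
(`lfc_we > 0` and `lfc_el > 0.5`); boundary values fall to *none*, and
the two classes are mutually exclusive because their `lfc_el` ranges are
disjoint. The two stage p-values combine by Fisher's omnibus
(`-2 sum ln p`, chi-squared with 2k df); the combination is computed for
every region, not only candidates, since it is cheap and lets the
optional omnibus cutoff on the gradual class (`omnibus_padj`, default
off) be applied uniformly. Signed-p ranking uses the raw p-value by
default (`sign(log2FC) * -log10 p`), switchable to adjusted p; ties
break by `|log2FC|` descending, then region id, making the top-*n*
selection deterministic.

## Motif enrichment by recovery curves

Motifs are position weight matrices with a 0.001 pseudocount per cell
(avoiding minus-infinity log-odds for zero counts); scanning scores
every offset on both strands with the log2 likelihood ratio against the
background and keeps the best hit, `N` bases contributing 0 bits. The
default report threshold of 7 bits corresponds to a site 128 times more
likely under the motif than under background.

For enrichment, every motif ranks the region database by best-hit
score (ties broken by region id). The recovery curve of an input set
counts the fraction of the set seen while descending the ranking; the
AUC is the mean recovery over the top `rank_threshold` ranks (default
10 000, capped at the database size), and
`NES = (AUC - mean) / sd` over the whole collection (population sd).
Motifs with NES > 2.5 are reported. Candidate targets are the input
regions ranked above the leading-edge rank `r*`, chosen to maximize
`recovery(i) - mean_recovery(i)` where the mean is over all motifs at
rank *i* — the point where the motif's curve gains most over the
collection's expectation. Input sets given as coordinates rather than
database ids are mapped first by ≥ 40% reciprocal overlap.

## Footprinting

Regions are re-centered on the midpoint of their best motif hit and
oriented by hit strand; raw (unextended) cut sites are accumulated per
site and relative position. The aggregate profile is corrected by
subtracting a background profile — the same motif's pileup at random
motif-bearing regions, scaled to equal total count, which cancels
sequence-driven cut bias while preserving bound-factor protection.
Background regions are drawn by rejection sampling: anchor-matched in
number and width, excluded from the anchor set, required to contain a
PWM hit at the same threshold, with a 50× oversampling cap. The
protection score `(mean flank - mean motif) / mean flank` uses 50 bp
flanks immediately outside the motif span: 1 for complete protection,
0 for none, negative for enrichment over the motif.

## Gene linkage and GSEA

A peak links to a gene when it overlaps any intron or the strand-aware
5 kb window upstream of the TSS (exclusive of the gene body); a peak
may link to several genes, and per gene the retained peak is the most
significant (smallest adjusted p, then larger `|log2FC|`, then
leftmost). The alternative `nearest_tss` mode assigns every peak to
exactly one gene. Genes ranked by their retained peak feed a preranked
GSEA: hits increment the running sum by `|score|^w` (normalized over
the set, `w` = 0 or 1), misses decrement by `1/(N - Nh)`, and the
enrichment score is the extremum. The null permutes gene labels — the
only valid scheme for a preranked list — with
`NES = ES / mean(|null ES| of the same sign)` and an add-one-corrected
one-tailed p. Permutation extremes are evaluated only at hit
boundaries, where they must occur, making 10^5-permutation runs
practical; null calibration (KS distance of p against uniform < 0.05
over 1000 random sets) is asserted in the acceptance suite.

Genomic-location annotation assigns each peak one category with
precedence promoter > exon > intron > distal, the promoter being a
strand-aware upstream window (default 1 kb).

## The synthetic-data generator

`sim_config()` fixes the study conditions; all generators derive their
randomness from the single seed, and an identical configuration
reproduces byte-identical files. The generator emulates:

- **Counts**: NB regions (default dispersion 0.1) with log-normal
  baselines (log-mean 100, sd 0.8 logs), a planted condition effect
  (default `|log2FC| = 2` in 10% opening + 10% closing regions), a
  multiplicative FAIRE batch offset (default 0.5 log2 units — open
  chromatin assays differ substantially in efficiency), and
  deterministic depth factors spanning > 2-fold.
- **Fragments**: cut sites uniform within regions, thinned over motif
  instances by `1 - footprint_protection`; lengths from a mixture with
  modes at 80/200/400/600 bp (sub-nucleosomal plus one to three
  nucleosomes; weights 0.45/0.30/0.15/0.10), strands 50/50, the 5' end
  of each record sitting exactly on its cut base.
- **Sequences**: i.i.d. background at configurable GC, one
  PWM-sampled motif instance per bearing region at a recorded offset.
- **Motif studies** (`simulate_motif_study`): a fixed-width region
  database, a strong planted PWM (consensus probability 0.985), and
  decoys organized as 5 families × 4 Dirichlet variants around a family
  base (concentration 400). The family structure mirrors the redundancy
  of real motif collections, where most factors appear as several
  near-identical matrices; it also matters statistically — with ~20
  fully independent decoys the maximum NES over the collection under a
  null input is the maximum of ~21 studentized normals, which exceeds
  2.5 about 9% of the time, right at the edge of what a null-behaviour
  check can assert. Correlated families reduce the number of
  independent shots and bring the null exceedance to ~5%. Fixed-width
  database regions avoid a shared length-driven component in every
  motif's ranking that would otherwise inflate cross-motif correlation.

It does **not** emulate: sequencing error or read-level artifacts,
mappability and GC bias, duplicate reads, overdispersion trends beyond
`a0 + a1/mean`, chromatin-state-dependent fragment-length coupling, or
realistic genome sequence composition. Passing tests therefore
demonstrate correctness of the inference chain under the declared
model, not robustness to the full messiness of real libraries.

## Problem sizes and determinism

The test and acceptance suites run at sizes chosen to estimate each
property with adequate precision while staying light: 2000 regions at
3 vs 3 for differential calibration and recovery, a 1000-region
database with 21 motifs and 50 null trials for enrichment, 10^5
fragments for footprint recovery, 5 × 10^4 for fragment-size modes, and
1000 random sets × 499 permutations for GSEA null calibration. All
stochastic steps take explicit seeds; `run_pipeline()` writes an MD5
manifest and reruns of the same configuration are byte-identical.

## Known limitations

- The NB Wald test has no outlier handling (no Cook's distance
  filtering or independent filtering) and no LFC shrinkage; it is not a
  reimplementation of any specific published tool and will not
  reproduce another tool's calls peak for peak.
- The t-reference saturates very small p-values at small n (see above).
- Leading-edge target selection depends on the decoy collection through
  the mean recovery curve; with very few motifs the expectation is
  noisy.
- `classify_regions` reports a single class with precedence
  stable > gradual > global-open; regions qualifying as global openers
  in addition to a time-course class keep the time-course label, with
  the global flag in its own column.
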