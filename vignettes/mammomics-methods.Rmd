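---
title: "Methods: integrating chromatin, methylation, RNA and protein in two cell lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating chromatin, methylation, RNA and protein in two cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammomics)
```

mammomics implements an integrative analysis of two epithelial cell
populations — here called basal and luminal, after the two mammary
lineages — profiled at four successive levels of gene regulation: DNA
methylation (bisulfite count tables), open chromatin (ATAC-seq peak
intervals), RNA abundance, and protein abundance (label-free shotgun
proteomics). This vignette describes each statistical component, its
assumptions and tunable parameters, the design choices made where the
problem is genuinely open, and what the synthetic-data generator does
and does not emulate.

## Coordinates and annotation

All genomic coordinates are held 0-based half-open (the BED convention);
1-based inputs (the CpG count table) are converted at the parser
boundary, so no off-by-one arithmetic appears downstream. Overlap
between two intervals means at least one shared base pair. The gene
model records a strand-aware transcription start site (the 5' end of
the body), and two windows derive from it:

* the *promoter* window, `[TSS - 2500, TSS)` on the appropriate side;
* the *gene window* used to attach peaks and methylation events to a
  gene: the gene body extended 2,500 bp upstream of the TSS only. We
  read "upstream of the gene start and end position" as this one-sided
  extension because the same analysis defines promoters as upstream of
  the TSS; extending both ends would double-count the 3' flank.

Coordinates are assembly-agnostic: the package never lifts over between
assemblies, and the synthetic data uses a single coordinate space.

## Differential methylation

`call_dmcs()` pools replicate counts within each cell type at every CpG
and applies a Fisher exact test to the 2x2 table of methylated and
unmethylated reads by group, followed by Benjamini–Hochberg adjustment
over all tested sites. A site is a differentially methylated cytosine
(DMC) when `|Δβ| >= 0.15` (inclusive) and `q < 0.01` (strict), where
β is the pooled methylated fraction per group. The exact test on pooled
counts is a deliberate, dependency-free stand-in for a bisulfite-specific
model: with two replicates per group there is little information to
estimate per-site dispersion, and pooling plus an exact test is both
conservative and reproducible. Sites with zero pooled coverage in
either group are skipped and counted.

Direction is reported as hypomethylation: the group with the lower β is
"hypo" in that group, which is the quantity the downstream enrichment
and integration steps consume.

## Permutation feature enrichment

`permutation_feature_enrichment()` asks whether DMCs fall into genic
(promoter / exon / intron / intergenic) or CpG-island-context (island /
shore / shelf / open sea) features more or less often than chance.
Genic labels use the precedence promoter > exon > intron > intergenic;
CpG context uses island > shore (≤ 2 kb from an island edge) > shelf
(2–4 kb) > open sea, the standard band definitions. The null draws
`|DMC|` sites uniformly without replacement from the background of all
tested CpGs, 1,000 times by default; the observed overlap count is
compared to the permutation distribution through a normal tail
(`pnorm` at the permutation mean and SD, upper tail when the
observation exceeds the mean), evaluated in natural-log space so
extreme enrichments never underflow to a literal zero. The fold change
is observed over expected mean; ratios below 1 are reported as the
negative reciprocal so that +2 and −2 are symmetric two-fold
enrichment and depletion. Permutations are unconstrained by chromosome
(the background is genome-wide); the seed is recorded in the output
attributes so runs are exactly repeatable.

## Open chromatin

`classify_restriction()` labels a peak *shared* when it overlaps any
peak called in the other cell type by at least 1 bp and
*lineage-restricted* otherwise; half-open adjacency is not overlap. No
merging of same-type peaks is performed — counts are of called peaks as
given. `assign_peaks_to_genes()` attaches each peak to every gene whose
window it overlaps (a peak near two genes counts for both; there is no
nearest-gene tie-break because per-gene counting is window membership,
not assignment of a unique target).

## TFBS scanning and enrichment

Motifs are supplied as position weight matrices (JASPAR-like text).
Count matrices become probabilities with a +0.25 pseudocount per cell,
which keeps log-odds finite. A window scores
`sum(log2(p_base / background_base))` in bits, on both strands; a hit
requires a score at or above the motif threshold, by default 80% of the
maximum achievable score (thresholds for published motif libraries are
motif-specific and not recoverable here, so a single relative default
with a per-motif override is the transparent choice).

Scanning targets are the 300-bp windows centred on hypomethylated DMCs;
the background is an equal-size seeded draw of 300-bp windows around
non-DMC background CpGs, mirroring the permutation background rather
than a GC-matched construction. The enrichment score is
`log2(% target windows with a hit / % background windows with a hit)`,
and significance is the upper hypergeometric tail of the target hit
count when drawing the target set from the combined pool, BH-adjusted
across motifs. `proximal_gene_integration()` then keeps hits within
250 bp of any ATAC peak, maps them to protein-coding genes present in
the expression table through the same gene windows, and reports
per-motif gene sets with mean RNA log2 fold change, plus the per-gene
count of distinct motifs.

## Proteome harmonization

Protein groups with fewer than two peptides are dropped. Abundance per
sample is LFQ when LFQ is present in every sample; otherwise the
record's intensities are replaced by iBAQ scaled per sample by
`median(LFQ)/median(iBAQ)` over the LFQ-complete records — a median-
ratio interpretation of "median-adjusted", chosen for robustness.
Intensities still missing after the fallback are floored to 1, so a
protein detected in only one group shows the characteristic huge log2
fold change (a 65,536-fold ratio is log2fc 16) and is flagged
`detected_only_in` rather than tested. Differential expression between
groups uses the ratio of group means (log2) and a two-sided Welch t-test
on log2 abundance — Welch because two replicates per group give no basis
for assuming equal variances. The differential set is
`|log2fc| >= 1 and p < 0.05` plus all detection-only records. Both raw
and BH-adjusted p-values are emitted, since published volcano plots are
ambiguous about which was thresholded.

`normalize_max()` divides each protein's abundance by its maximum over
samples (row maximum 1), and `zscore_rows()` centres and scales rows by
the sample SD, flagging constant rows. `rna_protein_correlation()`
computes Spearman rank correlation of RNA versus protein log2 fold
changes, globally and within peptide-count quartiles (ties at a
boundary go to the lower quartile) — peptide count is a proxy for
quantification reliability, and the correlation is expected to rise
with it.

## Relationship states and associations

Every gene observed in all four layers receives a ternary state per
layer: chromatin is up in the cell type with strictly more assigned
peaks; methylation is up in the type with strictly more hypomethylated
DMCs (more hypomethylation, i.e. a more permissive DNA state, counts as
"up"); RNA and protein are up when the linear abundance ratio strictly
exceeds 2. Ties and sub-threshold differences are neutral. The
fold rule operates on linear ratios; "greater than twofold" is read
strictly, so a ratio of exactly 2 is neutral.

Associations between layers are estimated per direction with a binary
predictor (predictor layer up in that direction or not) against a
binary outcome (outcome layer up in the same direction versus neutral,
genes with the opposite outcome excluded). This is exactly the
per-category comparison of a multinomial logit with the all-neutral
reference: with one binary predictor the maximum-likelihood log-odds
has the closed form `ln[(n11/n10)/(n01/n00)]`, the Wald SE is
`sqrt(sum(1/n))`, and the package uses the closed form directly
(`nnet::multinom` agrees to numerical precision and serves as an
independent cross-check in the test suite). Zero cells receive the
Haldane–Anscombe +0.5 on all four cells, flagged in the output. Joint
multi-predictor models are deliberately not fitted: the pairwise fits
reproduce the reported layer-to-layer associations without inventing a
joint design. Percentages in the concordance and marker reports round
half away from zero, matching how such ratios are conventionally
printed.

## Limiting-dilution analysis

The single-hit Poisson model says a transplant of `d` cells is positive
with probability `1 − exp(−f·d)`, `f` the repopulating-unit frequency.
`fit_single_hit()` maximizes the binomial log-likelihood over `ln f`
(equivalent to a complementary log-log binomial regression with a
log-dose offset, which the tests use as a cross-check) and reports a
95% profile-likelihood interval (χ²₁ cutoff 3.841). Profile intervals
were preferred over Wald-on-`ln f` because take-rate data at small
numbers of fat pads are routinely boundary-adjacent, where the Wald
interval misbehaves. All-positive or all-negative experiments are
returned as one-sided bounds with a flag rather than point estimates.
`compare_groups()` tests equality of frequencies by likelihood ratio
against χ²₁. Goodness-of-fit extras beyond the single-hit assumption
are out of scope.

## The synthetic study

`simulate_study()` generates, deterministically for a seed, every input
the pipeline consumes: a random genome (two chromosomes of 3.5 Mb by
default), 240 genes of 2–20 kb with 3–8 exons on both strands and CpG
islands at 30% of promoters, 8,000 background CpGs, 500 peaks per cell
type (40% shared), two planted motifs, expression and protein tables,
and a two-group limiting-dilution table — along with a ground-truth
record of every planted quantity. The reference conditions mirror the
study design the pipeline addresses: two bisulfite and ATAC and
proteome replicates per cell type, four expression replicates, a 6%
DMC rate with a three-fold promoter bias, planted motif rates of
60%/20% (target/background) and 45%/15%, chromatin→RNA and RNA→protein
association log-odds of 1.5, per-peptide-quartile RNA–protein
correlations 0.2/0.35/0.45/0.6, 15% LFQ missingness backed by iBAQ, 5%
one-lineage-only proteins, and a true repopulating frequency of 1/2,000
assayed at doses 500/2,000/10,000 with 12 transplants per dose.

Generator design notes, in the order they matter:

* **Methylation noise.** Overdispersion (beta-binomial, dispersion
  0.05) is applied at the *site* level — one methylation level per site
  shared by all samples — rather than independently per sample. Per-
  sample dispersion would make the pooled exact test anticonservative
  under the null (replicate-level biological variance masquerading as a
  group difference); site-level dispersion keeps unplanted sites
  identically distributed between groups, so the null is exactly
  calibrated while site-to-site variation remains overdispersed.
  Planted DMCs are re-centred so the full group shift (0.25–0.5)
  always fits inside [0.02, 0.98].
* **Promoter bias.** `promoter_enrichment_fold` is defined as the
  planted observed/expected overlap ratio: the number of promoter DMCs
  is set to fold × promoter-fraction × |DMC| and the remainder drawn
  uniformly off-promoter, so the permutation statistic's target equals
  the configured fold exactly rather than approximately.
* **CpG spacing.** Background CpGs are placed at least 320 bp apart so
  the 300-bp scan windows around them never overlap; otherwise motif
  plantings leak between neighbouring windows and per-window hit rates
  stop matching the configured planting rates.
* **Peaks follow chromatin states.** Each gene draws an equal base peak
  count for both cell types plus an excess on its planted "up" side,
  so recomputing per-gene counts recovers the planted ternary
  chromatin state; shared peaks are added identically to both types
  and cannot change dominance. Genes are spaced so windows never
  overlap a neighbour.
* **Motif planting.** Each motif embeds its consensus at a distinct
  offset inside the window so two motifs planted at the same CpG do
  not overwrite each other; background planting covers *all* non-DMC
  CpG windows at the configured rate, so any seeded background draw
  sees that rate in expectation.

What the generator does not emulate, and hence what passing tests do
not show about real data: read-level artifacts (bisulfite conversion
failure, mapping bias, PCR duplicates), clustered CpGs and real CpG
island structure, correlated peak widths and signal strengths,
GC-content confounding of motif hits, shared peptides between protein
groups, and batch effects in any layer. The suite demonstrates that the
implementation is correct under its stated model, not that the model
captures every property of the assays.

## Numerical choices and problem sizes

Fisher p-values are clamped to [0, 1] against floating-point overshoot.
Permutation p-values live in log space; a degenerate permutation SD of
zero reports p = 1 at the mean and a flagged log-space extreme
otherwise. Ties in variance ranking (`select_top_variance`) break by
row order. The LDA likelihood is maximized on `ln f` over a wide
bracket with `optimize` at tolerance 1e-10, and profile roots are found
with `uniroot`; the tests compare against a two-stage grid search.
The packaged test suite runs the full synthetic study at 4,000–8,000
CpGs, 20–60 genes, and recovery studies at 200 replicates × 3,000 genes
(associations) and 500 replicates (LDA coverage) — sizes chosen so the
whole suite completes in about a minute while estimator standard errors
stay far below the tolerances being asserted.

## Known limitations

The DMC test ignores within-group replicate dispersion (pooled counts);
a dispersion-aware test would be preferable with more replicates. The
permutation background is genome-wide rather than chromosome-matched.
Motif scanning has no GC-matched background and a heuristic threshold.
The proteome t-test at n = 2 per group has little power, which is why
detection-only records bypass it. The LDA model assumes single-hit
kinetics with no frailty or overdispersion terms.
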