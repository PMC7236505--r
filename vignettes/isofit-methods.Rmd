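---
title: "isofit: models and methods for isoform-resolved functional analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isofit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofit)
```

# Overview

`isofit` analyses two-group bulk or single-cell transcriptome experiments at
isoform resolution. Its premise is that alternative splicing,
polyadenylation and transcription-start-site choice (jointly, alternative
transcript expression mechanisms) redistribute a gene's expression across
isoforms that differ in their functional content — protein domains, signal
peptides, nuclear localization signals, miRNA and RBP binding sites, uORFs,
UTR lengths, polyA sites — so that the functional output of a gene can
change between conditions even when its total expression does not.

Three inputs drive every analysis:

1. an isoform-resolved annotation (a 9-column gff3-like dialect) describing
   each transcript's exons, CDS, polyA position, and the positional
   functional features attached to it;
2. a transcript-by-sample matrix of raw counts;
3. a design table mapping each sample to one of exactly two conditions with
   at least two replicates each.

# The annotation model

Each transcript is stored with 1-based inclusive genomic coordinates; exons
are listed 5'→3' in transcript orientation (descending genomic coordinates
on the minus strand). Functional features live in the coordinate space of
their layer: nucleotides of the mature transcript, or codons of the protein
(codon $c$ covers transcript nucleotides $u_5 + 3c - 2 \ldots u_5 + 3c$,
with $u_5$ the 5' UTR length). Features are projected to genomic intervals
on demand, splitting across exon junctions; presence-only labels (layer
`none`, e.g. an NMD flag) never participate in positional comparisons.

Coding transcripts are classified as likely nonsense-mediated decay (NMD)
targets by the classical 50-nt rule: the stop codon's last base lying
strictly more than 50 nt (configurable; the literature quotes 50–55 nt)
upstream of the last exon–exon junction marks a premature termination
codon. Single-exon transcripts are never flagged.

# Normalization and usage

Counts are normalized by the weighted trimmed mean of M-values (TMM; 30%
trim on log-ratios, 5% on absolute intensities, reference = the sample whose
75th expression percentile is closest to the sample mean) and scaled to CPM
of the effective library size. The implementation reproduces the classical
published TMM recipe; the test suite verifies exact agreement with edgeR's
factors. Raw counts plus effective library sizes (as GLM offsets) feed all
statistical tests; normalized condition means feed all descriptive metrics.

The usage of isoform $i$ in gene $g$ and condition $c$ is
$U_{ig}^{(c)} = \bar E_{ig}^{(c)} / \sum_j \bar E_{jg}^{(c)}$, the share of
the gene's mean normalized expression. Two pre-filters guard differential
usage testing against consistently minor isoforms: a proportion filter
(usage < 10% in all conditions, by default) and a fold-change filter
(per-condition major-to-minor expression ratio ≥ 2 in all conditions). The
per-condition major isoform is never removed.

# Functional diversity analysis (FDA)

FDA is qualitative: a gene varies for an annotation category when at least
one isoform pair differs in it, either in *presence* (one isoform carries an
annotation the other lacks) or in *position* (an annotation on one isoform
has no counterpart of the same feature id on the other with both genomic
endpoints within 9 bp — three codons of slack for prediction noise).
Multi-interval projections are compared interval-wise after sorting, and a
counterpart must share the feature id; presence variation therefore implies
positional variation. Structural diversity uses the same pairwise logic
with its own thresholds: alternative polyadenylation when polyA positions
differ by ≥ 100 bp (absolute genomic distance), 3'/5' UTR length variation
when coding isoforms' UTR lengths differ by > 75 bp, CDS variation when
coding isoforms differ in genomic CDS intervals or CDS length. Because no
genome sequence is supplied, CDS comparison is purely coordinate-based; two
identical-coordinate CDSs are never called different (a documented
divergence from sequence-level comparison). Feature-id-level diversity is
summarized per id and tested for enrichment in varying status against the
other ids of the category with a two-sided Fisher exact test,
Benjamini-Hochberg corrected within the category.

# The shared count model

Every differential analysis in the package reduces to one negative-binomial
log-linear model on raw counts:

$$\log \mu_{us} = \log o_s + \alpha_u + \beta_{c(s)} + \gamma_{u,c(s)}$$

where $u$ indexes the units of one gene (isoforms; unique-ORF groups;
feature-including vs -excluding aggregates; distal vs proximal polyA
aggregates), $s$ the samples, and $o_s$ the effective library sizes. The
interaction block $\gamma$ is tested by likelihood ratio against the
additive model on $(k-1)(c-1)$ degrees of freedom at fixed dispersion.

**Dispersion.** Per gene, a pooled method-of-moments estimate on
offset-normalized counts: $\hat\phi = \sum_{u,g}(v_{ug} - m_{ug}) /
\sum_{u,g}(m_{ug}^2 - v_{ug}/n_g)$ over unit × condition cells, floored at
0.01. The $-v/n$ term removes the upward bias of the squared sample mean
(its variance), without which $\hat\phi$ is systematically low and the test
anticonservative.

**Reference distribution.** With two or three replicates the dispersion
estimate is noisy, and referring the LRT to a chi-square ignores that noise:
on a simulated null (2,000 genes, 2×3 replicates, dispersions 0.05–0.3) the
chi-square reference rejected 9–12% at $\alpha = 0.05$. The package
therefore refers $\mathrm{LRT}/df$ to an $F(df,\; d)$ distribution with $d =
k\sum_g (n_g - 1)$, the residual degrees of freedom behind the dispersion
estimate — the same quasi-likelihood small-sample logic as edgeR's QL
F-test, converging to the chi-square reference as replication grows. This
restores null rejection to 0.058–0.068 across the test seeds while keeping
sensitivity ≥ 0.98 for complete usage switches at depth 200. Gene-level
differential expression (`run_dge`) instead keeps the chi-square reference
with a *common* dispersion pooled across all genes: a single gene offers too
few residual df for either a stable per-gene estimate or a useful F
denominator, and the DE call is additionally guarded by a fold-change
threshold on normalized condition means (pseudo-count 1).

# Differential usage, inclusion and polyadenylation

**DIU / DCU** (`run_diu`): the interaction test on a gene's isoforms (or on
its unique-ORF groups after CDS aggregation), BH across genes. Each record
carries the *total usage change*
$\tfrac{100}{2}\sum_i |U_{ig}^{(1)} - U_{ig}^{(2)}|$ — half the L1 distance
between usage vectors, in percent — the per-condition major isoforms
(argmax of usage; ties break to the lexicographically smallest id and are
flagged) and the switching flag (majors differ).

**DFI** (`run_dfi`): only features that vary across a gene's isoforms are
testable. For presence variation, isoforms carrying ≥ 1 annotation of the
feature id are the "include" side (partial loss counts as exclusion). For
positional-only variation the split is not defined by the literature; the
package splits on positional-equivalence classes, with the class of the
reference isoform (highest overall normalized expression) defining
"include" — a deterministic rule stated here as a design choice. Counts
collapse to two units and enter the interaction engine; p-values are BH
corrected separately within each annotation category. The feature inclusion
rate is $FI = E_{inc}/(E_{inc}+E_{exc})$ per condition from normalized
condition means; $\Delta FI = 100\,|FI_1 - FI_2|$; the favored condition
maximizes $FI$ (exact ties yield `none` and leave the bias and co-DFI
tallies); feature switching means $FI$ crosses 0.5. Category-level
statistics mirror the descriptive figures of isoform-function studies:
Fisher enrichment of DFI features per category against all tested features,
and a two-sided exact binomial test ($p_0 = 0.5$) of the favored-condition
split, each BH corrected across categories. Co-DFI counts, for feature
pairs DFI in ≥ 5 common genes, how often their favored conditions agree
(co-inclusion) or differ (mutual exclusion).

**DPA** (`run_dpa`): polyA sites are the 3'-most genomic bases of coding,
non-NMD isoforms. Per gene, sites within 75 bp are merged by single linkage
(chained merges can exceed 75 bp total span; documented), clusters below 10%
of total gene expression in every condition are dropped with their
transcripts (the 10% denominator is the pre-filter clustered total), the
cluster nearest the gene 5' end in transcript orientation is proximal, the
farthest distal, and intermediate clusters join the nearest labeled cluster.
The cluster representative is the most expressed member's site (ties: the
3'-most). Genes are eligible when both labels exist and the representatives
are ≥ 60 bp apart — deliberately a separate knob from FDA's 100-bp APA
threshold. Distal/proximal aggregates then enter the interaction engine;
$DPAU = E_{dPA}/(E_{dPA}+E_{pPA})$, with $\Delta DPAU$, switching and
favored condition defined as for FI. For a two-isoform gene whose isoforms
use distinct clusters, $\Delta DPAU$, $\Delta FI$ of an isoform-tracking
feature, and the total usage change coincide algebraically; the acceptance
tests assert this identity on 1,000 random fixtures.

**UTR lengthening** (`run_utrl`): per gene and condition, the
usage-weighted UTR length $UTR_w = \sum_i U_{ig}\,UTR_{ig}$ over coding
isoforms (usages renormalized to the coding set) — a convex combination of
isoform UTR lengths. The global shift across genes is tested on the paired
per-gene differences with a Wilcoxon signed-rank test. The source
literature names both the rank-sum and the signed-rank test for this step;
since the values are paired per gene the signed-rank form is the default,
with the unpaired variant behind `paired = FALSE`. All-zero difference sets
return p = 1 rather than an error.

# Enrichment

`fisher_enrichment` is the single enrichment engine: a two-sided Fisher
exact test per term of the 2×2 term-membership × test-membership table
within a user-supplied background, BH across terms. It applies to any
annotation category (a gene carries a term when any isoform does), and any
background — e.g. DIU genes against DE genes. Length-bias-corrected and
gene-set (GSEA-style) methods are out of scope by design.

# The synthetic world

`simulate_dataset` generates the package's entire test bed. Each gene is a
family of 1–4 isoforms sharing a 400-bp first exon and differing in their
second exon, which yields, by construction: distinct polyA sites ≥ 600 bp
apart (always separate clusters at the 75-bp window), 3' UTR lengths
differing by 150 bp steps (UTR-varying at the 75-bp default), distinct ORFs,
and a protein domain tracking isoform 1 of every multi-isoform gene (a
presence-varying feature whose inclusion share equals isoform 1's usage).
Counts are NB with mean `gene_mean × usage × library factor`; defaults are
the stated test world: gene means log-uniform on 50–500, dispersions uniform
on 0.05–0.3, 3 replicates per condition, library factors uniform on
0.8–1.2. Null genes draw one usage vector (normalized Gamma(2) weights) and
reuse it in both conditions; planted genes are forced to two isoforms and
flip the usage of isoform 1 between conditions (0.8 → 0.2 by default,
0.9 → 0.1 for the "complete switch" recovery checks), making them
simultaneously DIU, DFI and DPA positive with expected effect
$100\,|u_1 - u_2|$. Everything is a pure function of the seed.

What the generator does *not* emulate — and hence what a green test does not
establish: overdispersion trends with expression, positional read biases,
correlated isoform structures across genes, NMD/non-coding isoforms in the
count model (they are exercised by handcrafted fixtures instead), and any
resemblance to a real gene catalog. Statistical calibration claims are
claims about the NB world above.

# Numerical choices and degenerate inputs

* All-zero samples abort normalization with the sample named; all-zero
  units are dropped before testing; genes with < 2 usable units are
  `not_testable`, never an error.
* Zero gene expression in one condition makes usage, FI, DPAU and UTRw
  undefined there: records are flagged and excluded from tests, not imputed.
* Non-integer counts are rounded for testing, with a notice.
* Argmax ties (majors) break lexicographically and are flagged; FI/DPAU
  ties yield `favored = "none"` and leave bias/co-DFI tallies.
* BH is implemented as the literal step-up and verified against an
  independent oracle; Fisher and binomial p-values are verified against
  choose()-based enumeration.
* The dispersion floor (0.01) bounds the F statistic for near-Poisson genes;
  the merge window, expression floor and pair distance of the polyA library
  are monotone by construction (tested).

# Known limitations

* Two conditions only; time-course designs are out of scope.
* CDS "sequence-level" comparison is coordinate-based (no genome FASTA).
* The positional include/exclude split for partially disrupted features is
  a package convention (reference-isoform class), not a published rule.
* With two replicates per condition the dispersion estimate rests on two
  residual df per unit and group; the F reference keeps type I error near
  nominal, but power for subtle usage shifts is accordingly limited.
* The annotation dialect is this package's own (the published ecosystem's
  file layout is not formally specified); it is lossless under
  `write_annotation(parse_annotation(x))`.
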