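---
title: "Mapping a transcription-factor regulon from ChIP-seq and RNA-seq"
author: "regulonmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a transcription-factor regulon from ChIP-seq and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonmapr)
```

## The model

A transcription factor's regulon splits into direct targets — genes whose
promoter the factor binds — and indirect targets, reached through
intermediate regulators. `regulonmapr` resolves the split by intersecting
two genome-wide measurements:

1. **Binding** (ChIP-seq): immunoprecipitated (IP) coverage against a
   sheared-input control, reduced to peaks with summits.
2. **Dependence** (RNA-seq): counts from wild-type versus factor-deletion
   cultures, reduced to differentially expressed genes (DEGs) with a
   signed `log2(mutant / wild type)` fold change.

A DEG is *direct* when a consensus peak summit lies within the promoter
window, −1000 to +50 bp of its start codon measured along the gene's
strand (negative = upstream; the +50 bp tail admits sites that sit just
inside the coding sequence, as real regulatory sites occasionally do). A
DEG inside an operon inherits direct status from the operon's first gene
(`direct_via_operon`). Everything else is *indirect*. Because the model
organism class here is a dense, high-GC α-proteobacterium, two features
get first-class treatment: operons (same strand, inter-gene gaps below
50 bp, similar expression) and divergent gene pairs sharing one
intergenic regulatory region, which may both be direct targets of a
single site.

## Peak calling: two background models, intersected

Both callers tile the replicon with 300 bp windows at a 75 bp step and
convert window coverage sums into fragment counts (dividing by the
configured fragment size — fragment-model estimation from the read data is
deliberately not reproduced at this scale).

**Local Poisson caller.** The input track is depth-scaled to the IP, and
each window's background rate is the most conservative of the genome-wide
mean and the 1 kb / 5 kb / 10 kb local means centred on the window:
$\lambda_{\mathrm{local}} = \max(\lambda_{BG}, \lambda_{1k}, \lambda_{5k},
\lambda_{10k})$. A window is significant when the exact Poisson upper tail
$P(X \ge k \mid \lambda_{\mathrm{local}})$ falls at or below the cutoff,
default $10^{-5}$. Overlapping significant windows merge; the summit is the
leftmost per-base IP maximum (ties broken left for determinism).

**GC-stratified negative-binomial caller.** Coverage in GC-rich windows can
be systematically inflated in high-GC genomes. Windows are therefore
stratified into GC-content deciles, and within each stratum an NB
background is fitted to the depth-scaled *input* window counts by the
method of moments (mean $m$, variance $v$, size $m^2/(v-m)$); when
$v \le m$ the fit degenerates to Poisson, which also makes this caller a
strict generalization of a single-bin NB caller on homogeneous genomes.
Strata with fewer than 20 windows are merged into their nearest neighbour
(with a warning) — moments from a handful of windows are too unstable to
define a background. The same $10^{-5}$ cutoff is applied; the published
analysis states no separate threshold for its second caller, so symmetry
is the documented choice.

**Consensus.** Only peaks called by both background models are retained —
a peak from caller A survives when it overlaps any caller-B peak by at
least 1 bp, and it keeps caller A's geometry (interval, summit, p-value),
since those are the coordinates the published tables report. This
intersection is what drives the false-positive behaviour: each caller
alone tests ~2,700 windows per 200 kb at $10^{-5}$, and the null
simulation below confirms the consensus stays empty without planted sites.

## Differential expression

Normalization uses median-of-ratios size factors (the geometric
normalization estimator): for sample $j$,
$f_j = \mathrm{median}_g \, k_{gj} / (\prod_{j'} k_{gj'})^{1/n}$ over genes
with all-positive counts, rescaled to geometric mean 1. Genes whose mean
normalized count is below 10 in both conditions are excluded from testing
(reported with $p = 1$), mirroring a minimum-alignment-count filter; the
threshold unit is interpreted as mean normalized counts per condition since
the original tool option leaves it unspecified.

For tested genes the per-gene NB dispersion is a method-of-moments
estimate $\hat\alpha = (s^2 - \bar k)/\bar k^2$ computed within each
condition; the larger of the two is used, floored at 0.01. The floor keeps
near-Poisson genes from producing overconfident tests when three
replicates happen to agree too well. The Wald statistic is
$\log_2\!\mathrm{FC} / \mathrm{SE}$, with
$\mathrm{Var}(\log \hat\mu) \approx (1/\mu + \alpha)/n$ per condition by
the delta method, referred to a standard normal; a pseudocount of 0.5
normalized units guards the log when a condition mean is zero, preserving
ordering without infinities. Under a 2,000-gene null simulation this test
rejects at 5% between 3% and 8% of the time — mildly miscalibrated, as any
plug-in Wald test with three replicates must be, but adequate because the
DEG call also demands $|\log_2\mathrm{FC}| \ge 1.32$ (fold change
$\ge 2.5$; $2^{1.32} = 2.497$) and a Benjamini–Hochberg $q < 0.05$
computed over the tested genes only. The sign convention follows the
deletion contrast: *activated* genes are lower in the mutant
($\log_2\mathrm{FC} < 0$).

One practical caveat the simulation exposes: when a large, one-sided
fraction of the genome is differentially expressed (roughly a third, as
happens if whole operons are planted with fold changes), median-of-ratios
factors absorb part of the signal and attenuate $|\log_2\mathrm{FC}|$ by
~0.2–0.4 units, costing recall near the 1.32 threshold. This is a known
composition-bias property of ratio-based normalization, not a defect of
the implementation; at the default planted fraction (20%) its effect is
minor.

## Motif analysis

The CRP-family binding site is a 16 bp palindromic spaced dyad,
TGTGA-N<sub>6</sub>-TCACA. Dyad search is exact string matching of
`left · N^s · right` for each allowed spacer on both strands (overlapping
hits all reported); because the strict dyad is its own reverse complement,
every forward hit is mirrored by a minus-strand hit over the same
interval. Relaxed cores GTG-N<sub>8</sub>-CAC and GTG-N<sub>10</sub>-CAC
capture the variant spacings observed for this factor family.

PWM scanning scores log-odds against a background of genome mononucleotide
frequencies (on a 70.5% GC genome a uniform background would overstate
AT-rich matches). Per-position p-values are *exact*: the null distribution
of the score, discretized at 0.001 bits, is built by column-wise
convolution over the background, and $P(S \ge s)$ is read from the
resulting table — the same dynamic-programming construction used by
standard motif scanners, verified in the tests against exhaustive
enumeration of all $4^w$ words for small widths. Hits are reported at
$p < 0.01$. De novo motif discovery (EM or Gibbs alignment) is out of
scope: sites enter pre-aligned as fixed-width windows around dyad hits,
and the consensus-calling step reports the majority base per column (a
two-base IUPAC code when the top two frequencies are within 0.10) with
information content $2 + \sum_b f_b \log_2 f_b$ bits.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: a 200 kb linear
replicon carrying 150 genes packed to 90% intragenic sequence at 70.5%
GC; 60% of genes in operons of 2–4 genes with 5–35 bp internal gaps
(dense bacterial genomes genuinely carry half or more of their genes in
operons, and at 90% intragenic density the packing arithmetic requires
it); inter-unit gaps of at least 200 bp; 20 dyad sites written into
promoter regions at 60–250 bp upstream of a transcription unit's first
gene; IP enrichment 8 over a background of 0.5 fragment starts per bp
with 150 bp fragments (so background coverage ≈ 75×); three replicates
per condition, NB dispersion 0.05, ±30% library-size imbalance, and
planted $|\log_2\mathrm{FC}| = 2$ on the 20 site-adjacent genes plus 10
site-free (indirect) genes. Coverage is Poisson fragment starts
accumulated over the fragment length; the extra IP fragments at a site
start uniformly across the positions covering the summit, giving the
triangular summit profile real ChIP fragments produce.

The simulator does *not* model read-level errors, mappability, PCR
duplicates, strand-specific coverage shifts, chromatin accessibility, or
partial operon read-through. Passing recovery tests therefore demonstrates
that the statistics are implemented correctly and calibrated under their
own assumptions — not that the pipeline is robust to every artefact of
real sequencing data. Benchmarks use problem sizes a laptop handles in
seconds (200–350 kb replicons, 150 genes, ~2,700 windows); genome-scale
counts from the original study (thousands of genes, hundreds of peaks) are
not reproducible from desk-scale simulation, which is why recovery rates,
not absolute counts, are the acceptance surface.

## Numerical and design choices

- **Coordinates.** Genes are 1-based inclusive (GFF3); intervals, peaks
  and summits are 0-based half-open (BED). Conversion happens only in the
  I/O layer, and round-trip tests pin it.
- **Overlapping genes** count as intragenic by union — the conservative
  reading when classifying "intergenic" binding.
- **Topology.** Linear by default; a `circular` flag merges the two
  terminal intergenic gaps into one origin-spanning region (nothing else
  changes).
- **Window geometry.** When a summit is within the window of two
  same-strand starts, the nearer start wins. Divergent classification
  requires *both* flanking starts within the window; a peak upstream of
  only one gene of a divergent pair is plain `intergenic_upstream`.
- **Operon expression similarity** is judged on wild-type mean RPKM with a
  default tolerance of 1 log2 unit — "co-regulated to similar extent" is
  not a quantitative criterion, so 2-fold similarity is the documented,
  configurable choice; wild-type levels are used so that the deletion
  phenotype cannot break up an operon.
- **Ties and determinism.** Summit ties break leftmost; all generators
  draw from one seed (offsets +1/+2 for coverage and counts); pipeline
  outputs omit timestamps, so a fixed seed reproduces every report
  byte-for-byte.
- **Score discretization** for PWM p-values is 0.001 bits (configurable);
  at motif widths up to ~20 the induced p-value error is far below the
  0.01 decision threshold.

## Limitations

Single replicon per run (multi-contig assemblies would be handled as
independent replicons); no isoform or transcript assembly; no dispersion
shrinkage across genes (a deliberate simplicity at 150-gene scale — with
thousands of genes an empirical-Bayes estimator would be preferable); the
NB-GC caller shares the Poisson caller's window geometry rather than
fitting its own; and the packaged regulon table is a transcription of a
published summary, carrying its quirks (one locus listed under two
functional categories, one printed distance that is downstream of the
start codon).
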