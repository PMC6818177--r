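---
title: "Reconstructing a neural lineage from regulatory chromatin signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a neural lineage from regulatory chromatin signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilineage)
```

## The scientific question

During neural development a multipotent neural stem cell (NSC) commits
either to the neuronal fate or, through a *Gcm*-expressing intermediate
progenitor (GNP), to the glial fate. Transcriptomes separate progenitors
from differentiated cells but do not resolve *which* differentiated type
descends from which progenitor: an expression dendrogram groups NSC with
GNP and neurons with glia and stops there. The hypothesis this package
operationalizes is that the repressive mark H3K27me3, measured in
*cis*-regulatory elements (promoters and enhancers), accumulates
gradually along each differentiation path, so that between-cell-type
distances in H3K27me3 space mirror path lengths in the lineage tree — and
hierarchical clustering of that signal therefore reconstructs the tree
itself: first NSC with GNP, then glia attaching to that pair, with
neurons splitting off first.

The pipeline quantifies, per cell type:

* nucleosome occupancy around transcription start sites (MNase-seq),
* H3K9ac / H3K27me3 signal in promoters and called enhancers (ChIP-seq),
* a four-state chromatin-state map from the two marks and the state flows
  between cell types,
* ROC curves for each mark as a predictor of gene activity,
* hierarchical clusterings of all of these matrices against the reference
  lineage.

Because the raw sequencing data are not shipped with the package, a
synthetic-data generator plants all of these structures in a toy genome
with known ground truth; every stage of the analysis is tested against
that truth.

## Coordinate and counting conventions

All intervals are 0-based half-open (the BED convention); GTF input is
converted at the boundary. Reads are counted by **midpoint** for binned
TSS profiles (the midpoint of a short MNase fragment is the best proxy
for the nucleosome dyad, and midpoint counting makes bins a partition: no
read is double-counted) and by **overlap** for broad regions (promoters,
enhancers, 200-bp state bins), where partial coverage should still count.
Signal is normalized as RPM (reads per million mapped) using the declared
library total; expression additionally by transcript kilobase (RPKM).

Windows anchored at a TSS are oriented 5'→3'. On the minus strand the
window is the exact reflection across the TSS base: the nucleosome-depleted
region (NDR), defined as 150 bp upstream to 50 bp downstream, maps to
`[tss-150, tss+50)` on plus-strand genes and `[tss-49, tss+151)` on
minus-strand genes.

## Stage-by-stage model choices

**Expression and differential calls.** Gene filtering for clustering
keeps the union of differentially expressed genes over all cell-type
pairs at FDR < 0.05. The two-sample test is a conditional binomial rate
test: given a gene's summed count, its count in cell A is Binomial with
success probability equal to A's share of the combined library; the
two-sided p-value doubles the smaller tail (clamped at 1), a convention
that is exactly symmetric under swapping the pair and conservative under
the null. Zero-in-both genes get p = 1 and stay in the
Benjamini–Hochberg family, keeping the multiplicity correction
deterministic. The pseudocount (1 read on the per-million scale of the
smaller library) affects only the reported fold change, never the test.

**Nucleosome profiles.** MNase midpoints are binned at 10 bp over TSS ±1
kb (200 bins), minus-strand rows reversed. NDR occupancy is the RPM in
the oriented `[-150, +50)` window; genes are ordered ascendingly by it.
Genes whose window would cross a chromosome end keep zero-filled bins and
are flagged rather than dropped, so every cell type shares one gene
universe.

**Chromatin states.** Each mark is binarized over 200-bp genome bins: a
bin is marked when its count's upper-tail Poisson probability at the
track-wide mean rate is ≤ 1e-4. With exactly two binary marks the four
states are the mark combinations (H3K9ac+, H3K27me3+, both, unmarked), so
no hidden-state training is needed; an optional 3-bin majority filter
supplies the smoothing an HMM would otherwise add (off by default). State
flows between two cell types are the 4×4 per-bin contingency — the
numbers behind an alluvial plot.

**Enhancer calling.** H3K4me1 enrichment is tested in 1-kb windows
stepped every 100 bp against a Poisson null at the global mean
reads-per-window rate, BH-corrected at FDR 0.001. Significant windows are
merged when overlapping or adjacent; because a 1-kb window overhangs a
sub-kilobase element by up to a window on each side, each merged region
is then boundary-refined: 50-bp binned coverage is smoothed with a 3-bin
moving average and trimmed at half-maximum (halfway between background
and the region's peak), and each maximal above-half run of at least two
bins becomes one peak. The smoothing prevents Poisson dips from
fragmenting one element; the run-splitting separates neighbouring
elements that a shared significant window would otherwise fuse. Peaks
overlapping any promoter are discarded. Targets are assigned to the
nearest TSS within 10 kb of the proximal border (distance 0 inside the
peak; ties to the lexicographically smaller gene id).

**Regulatory signal matrices.** Promoters are the strand-symmetric TSS ±1
kb windows, clipped at chromosome ends. Because per-cell enhancer sets
differ, cross-cell matrices use a consensus universe: the merged union of
all cells' peaks, quantified in every cell, so that all columns share
rows.

**ROC evaluation.** Gene activity labels come from expression rank:
top-k genes are positives for the activating mark H3K9ac, bottom-k for
the repressive H3K27me3 (k = 1500 by default). Thresholds are the
distinct signal values descending with a ≥ comparison; the trapezoid AUC
over the (FPR, TPR) polyline equals the pairwise statistic
P(sig_pos > sig_neg) + ½P(tie), and the package carries both
implementations so each run can be cross-checked. When k reaches or
exceeds the scored-gene count (1000 synthetic genes, or the subset of
genes with an assigned enhancer), k is capped at half the scored genes so
both classes stay populated; boundary ties are broken by gene id so that
exactly k genes are labeled. Enhancer signal maps to genes via the target
assignment, taking the maximum over a gene's enhancers; genes without an
enhancer are excluded from that evaluation rather than imputed at zero,
which would manufacture separation.

**Clustering and topology.** Matrices are row Z-scored (population sd,
divisor n; zero-variance rows dropped) and cell types clustered on
Euclidean column distances with complete linkage by default (the linkage
is a logged configuration value; average and Ward are available, and on
default synthetic data the choice does not change the recovered
topology). The dendrogram is compared with the reference caterpillar
(((NSC,GNP),Glia),Neuron) two ways: the unrooted bipartition
{NSC,GNP} | {Glia,Neuron}, and the full nested merge order. A dendrogram
whose merge heights are all equal within 1e-9 is flagged "unresolved" and
counted as recovering nothing, so ties cannot masquerade as signal.

## What the generator plants — and what it leaves out

The generator tiles 1000 genes on a 6-Mb chromosome (one 6-kb slot per
gene, random strand), plants 300 enhancers of 900 bp at 1–2.5 kb from
their target TSS in the inter-promoter gaps (placement guarantees the
intended target is the nearest TSS and total enhancer coverage stays
below 5% of the genome), and emits four assays × four cell types as
49-bp reads with Poisson counts everywhere. Declared library size is 2
million per track with roughly half a million reads in modeled regions;
the rest is accounted to the genome-wide background (0.03 reads/bp).

Latent structure, all on the log2 scale:

* *Expression*: per-gene baseline N(3, 2²) plus block effects of +1.5 for
  progenitor-high (15% of genes, up in NSC and GNP), differentiated-high
  (15%, up in neurons and glia), neuron-specific (10%) and glia-specific
  (10%) blocks, plus N(0, 0.25²) per-cell noise.
* *H3K27me3*: −0.9 × centered expression, **plus a Brownian drift along
  the lineage tree** — NSC at the root state, and independent per-gene
  Gaussian increments with standard deviations 0.3 (NSC→GNP), 0.6
  (GNP→Glia) and 1.0 (NSC→Neuron). The same drift law (fresh draws) acts
  on enhancer H3K27me3. These edge scales make expected Euclidean
  distances respect tree path lengths, which is exactly the signal the
  clustering stage is supposed to exploit.
* *H3K9ac*: +0.8 × centered expression (no tree drift), so it carries the
  same two-block structure as expression — enough to separate progenitors
  from differentiated cells, not enough to order them.
* *MNase*: a phased nucleosome array per gene (Gaussian peaks at −180,
  +120, +295, +470 bp from the oriented TSS, sd 40 bp) whose density
  inside the NDR is multiplied by exp(−0.8 × standardized expression):
  highly expressed genes have open NDRs.
* *H3K4me1*: 10-fold enrichment over background inside active enhancers;
  shared enhancers (180) are active and acetylated in both progenitors,
  neuron-/glia-specific ones (60 each, targeting the matching gene
  blocks) only in their cell type.

The coupling strengths, noise scales and read budgets are the package's
own choices, set once so the generator expresses the qualitative
structure the analysis assumes — strong mark–expression coupling,
tree-structured H3K27me3, block-structured expression/H3K9ac — at
realistic sparsity; the per-gene expression spread (sd 2) is wide enough
that within-cell-type mark-vs-expression ranking stays informative even
for the most drifted cell type (neurons). The tree edge scales are free
parameters in the same sense: recovery is supposed to succeed at the
default depth and fail when the scales are equalized.

What the generator does **not** emulate: sequence content and
mappability, fragment-length variation and paired ends, replicate
structure (a single pseudo-replicate per cell type, as in the study
design), input-control tracks, copy-number or GC biases, overlapping or
nested genes, and any enhancer–promoter looping. Passing tests therefore
show the pipeline's inferential machinery is correct under its own
assumptions; they do not show robustness to alignment artifacts or
batch structure in real libraries.

## Numerical and degenerate-input choices

* Poisson tail thresholds are computed exactly (smallest k with
  P(X ≥ k) ≤ p), verified against term-wise summation.
* The binomial two-sided convention is the doubled smaller tail, clamped
  at 1; BH q-values never fall below their p-values.
* Empty inputs are contracts, not crashes: an empty region set counts to
  an empty vector; a zero-read track binarizes to all-unmarked with a
  warning; an empty DEG union or an empty consensus enhancer set raises
  an actionable error.
* Zero-variance rows are dropped before clustering with a logged count;
  an all-tie distance matrix yields an "unresolved" topology flag.
* Determinism: the generator derives one sub-seed per stage (latents,
  then each cell × assay track), so any assay subset reproduces exactly
  the tracks of the full run, and a fixed seed yields byte-identical
  files; the pipeline report carries md5 checksums of every output so
  reruns can be compared wholesale.

## Problem sizes used by the checks

The test-suite and the acceptance script rerun the full path at the
default study conditions: 100 generator seeds for the lineage-recovery
and contrast sweeps, 20 seeds for each null calibration (ROC label
shuffles, pure-background enhancer calling and binarization, DEG nulls),
3 seeds for ROC and state-transition spot checks. Smaller configurations
(120–150 genes on a 0.8–1 Mb chromosome) are used where only plumbing is
exercised, e.g. byte-identity of outputs and pipeline reports.

## Known limitations

* The two-mark state model cannot represent marks beyond H3K9ac/H3K27me3
  and performs no control-track normalization.
* The DEG test is a calibrated stand-in for a dispersion-aware model; it
  is used only as a gene filter, and with real replicated data a
  negative-binomial test would be preferable.
* Nearest-TSS target assignment ignores looping; the per-gene enhancer
  aggregation (max) is one documented choice among several defensible
  ones.
* With four leaves the topology comparison is exhaustive; the machinery
  (bipartitions + merge order) generalizes, but consensus/bootstrap
  support for larger trees is out of scope.
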