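---
title: "How screads simulates single-cell reads: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How screads simulates single-cell reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screads)
```

## Overview

`screads` generates synthetic scRNA-seq and scATAC-seq reads by learning
from a real aligned, barcoded read set, in three stages: genome
segmentation, synthetic count generation, and synthetic read generation.
This vignette explains the models behind each stage, the parameters that
matter, the numerical choices, and what the test suite does and does not
establish about real data.

## Coordinates and containers

All intervals are 0-based half-open `[start, end)`, the native BED/SAM
convention; GTF input (1-based closed) is converted at the I/O boundary
and the conversion round-trips exactly. Reads are plain data frames keyed
by the 5'-most base (`pos5`), which is the right-hand end of the
alignment for minus-strand reads. Count matrices are features x cells
with barcodes in a fixed, shared column order across matched matrices
(gene/inter-gene, peak/non-peak) so cells always line up.

## Stage 1: genome segmentation

**scRNA-seq.** Overlapping annotated genes are unioned into "supergenes"
(connected components of the overlap graph) so that no read can be
attributed to two features; member gene ids are kept in the output for
reporting. Inter-genes are the complement. Since the gene/inter-gene
features tile the genome and a read is assigned to the unique feature
containing its 5' base, total counts are conserved exactly — a property
the test suite asserts. The assignment rule is our convention: raw
overlap counting would double-count boundary-spanning reads between
adjacent features, which breaks conservation; 5'-base assignment is the
minimal rule that restores it. A UMI is assigned to the feature of its
leftmost-5' read.

**scATAC-seq.** The genome becomes trustworthy peaks, trustworthy
non-peaks, and gray areas (the remainder; regions that cannot be
confidently called either way). Trustworthy regions come from, in order
of preference: user BED files; an external candidate list filtered by the
half-length rule (`select_trustworthy_by_overlap()` keeps a candidate
when at least half its length is covered by the reference region union);
or the internal fallback caller. The fallback tiles the genome into
fixed windows (default 500 bp — comparable to a nucleosome-scale
accessible region and wide enough for stable counts at toy depths),
computes per-window Poisson upper-tail p-values against the genome-wide
mean window count, BH-adjusts them to q-values, and applies two rules:
q <= 0.01 (stringent) defines peaks, and the complement of q <= 0.1
(relaxed) defines non-peaks. Peaks are always a subset of the relaxed
peaks, so peaks and non-peaks can never overlap. The BH adjustment is
what makes the null calibration honest: under flat coverage essentially
no windows are called, while planted enrichment of the magnitude in the
fixtures (tens of times background) is detected with recall ~1. The
caller is deliberately simple — it is a fallback, not a replacement for a
dedicated peak caller, and it ignores local background variation.

**Designed ground-truth peaks.** `design_tss_peaks()` builds truth peaks
`[TSS, TSS + LEN − 1]` with LEN drawn uniformly from 250..550 bp (the
range of typical accessible-region sizes used when benchmarking peak
callers) and merges overlaps so the truth set is non-overlapping.

## Stage 2: the count engine

The engine is a classed S3 model (`fit_count_model()` returns a
`count_model` with `print`, `summary`, `coef` and `simulate` methods).

**Clustering.** If the user supplies no cell labels, cells are
log-normalized (counts per 10k, log1p), embedded by their 500 most
variable features, connected in a k = 10 shared-nearest-neighbour graph
with Jaccard weights, and partitioned by Louvain communities (igraph).
With fewer than 4 cells the model falls back to a single cluster with a
warning.

**Marginals.** Every (cluster k, feature g) gets a negative binomial
NB(mu_kg, theta_kg) with variance mu + mu^2/theta. The mean MLE is the
sample mean; dispersion is fitted by `MASS::theta.ml` from a
method-of-moments start and clamped to [1e-8, 1e6] — the lower bound is a
numerical stability floor and the upper bound is operationally Poisson
(when the sample variance does not exceed the mean there is no evidence
of overdispersion and theta is set to the cap). Zero-inflation is not
modelled: we fix the NB family for tractability rather than selecting
among count families per feature, a documented simplification of the
usual practice.

**Copula.** Dependence is estimated on the top-J features by mean
(default J = 500) per cluster; the rest are sampled independently. The
choice of J trades correlation fidelity against estimation stability:
correlation matrices over thousands of mostly-zero features are noisy and
frequently indefinite, while the top-expressed features carry nearly all
of the estimable dependence. Normal scores come from the
mid-distributional transform u = F(x−1) + 0.5 f(x) of the fitted
marginals — the deterministic variant of the randomized distributional
transform, chosen so that fitting is reproducible without consuming RNG
state. The score correlation matrix is projected to the nearest
positive-semi-definite correlation matrix by eigenvalue clipping (floor
1e-8, then rescaling to unit diagonal), and a 1e-10 ridge is added before
the Cholesky factorization used in sampling.

**Sampling.** Synthetic cells are allocated to clusters by a multinomial
draw on the fitted proportions (or an explicit assignment — the pipeline
drivers draw the assignment once and reuse it for the gene and inter-gene
models so a synthetic cell is the same cell in both matrices). Counts are
qnbinom-transformed Gaussian draws for copula features and independent
`rnbinom` draws otherwise.

**Depth scaling.** The baseline depth is the total UMI count (UMI-based
RNA) or deduplicated read count (ATAC) of the training data. A factor
r <= 1 is applied by binomial thinning of the sampled counts with
probability r — exact downsampling, the same operation subsampling a
library performs; r > 1 scales the NB means by r before sampling with
theta unchanged, the standard model-level up-scaling. The two conventions
meet at r = 1 and both scale expected totals linearly, which the tests
verify at ±5% with 2000 cells.

**Gray areas.** Each gray area copies the synthetic count row of its
nearest upstream (5') non-peak and masks entries to zero independently
with probability max(1 − L_gray/L_nonpeak, 0), scaling coverage by
length; a gray area longer than its donor copies the row unchanged (and
is thus at most non-peak-like). A gray area at the extreme 5' end of a
chromosome has no upstream donor; we use the nearest downstream non-peak
instead, preserving the nearest-donor intent at chromosome edges.

**User-designed regions.** A designed feature takes counts from the
trustworthy feature most similar in length: among the 50 same-chromosome
candidates closest in length, the donor is the one with the largest
(peaks) or smallest (non-peaks) count-to-length ratio — high-signal
donors for truth peaks, low-signal donors for truth non-peaks. Ties break
by smaller length difference, then leftmost start, making the mapping
deterministic. The signed relocation distance is
d = start(designed) − start(donor); the reference point (start vs
midpoint) is not externally fixed, and start-anchoring pins the donor's
read landscape to the designed feature's left edge.

## Stage 3: read synthesis

**scRNA-seq read 2.** For a feature with synthetic UMI count u, each of
the u synthetic UMIs resamples a real UMI of the feature uniformly with
replacement; its read count c is thereby drawn from the empirical
reads-per-UMI distribution (uniform UMI resampling and "draw c from the
law, then a uniform UMI with that c" induce the same joint law — we
implement the single draw). The UMI's c reads resample the real UMI's
reads with replacement; each synthetic read takes the source read's 5'
position plus an independent integer shift uniform on −4..4 (9 values, 0
included), breaking the exact-duplicate positions that resampling with
replacement would otherwise produce. Strand is copied; the 3' end follows
from the configured read length (default 90 nt): plus-strand reads occupy
[pos5, pos5 + l), minus-strand reads (pos5 − l, pos5] with the emitted
sequence reverse-complemented. Shifted reads are clipped to chromosome
bounds rather than discarded. A feature with synthetic counts but no real
reads falls back to uniform placement inside the feature with a warning.

**Transcriptome mode.** Exons of each gene are unioned and concatenated
into a collapsed transcript (reverse-complemented for minus-strand
genes); read starts are uniform on the collapsed length l and read length
is min(90, l − start), so reads never cross the transcript boundary. A
supergene whose member genes disagree on strand is collapsed on the
forward strand.

**scRNA-seq read 1.** One random 16-nt barcode per synthetic cell
(collisions resampled away so the emitted whitelist is unique — synthetic
UMI collisions within a cell-feature are left as drawn, mirroring real
UMI spaces), one fresh 10-nt UMI per synthetic molecule, concatenated to
the 26-nt read 1 with quality 37 throughout.

**scATAC-seq.** A synthetic count c yields ⌈c/2⌉ pairs resampled from the
real pairs overlapping the feature; a pair is eligible when either mate's
5' base is assigned to the feature, and the mate is taken as found even
if it lies outside. Both mates receive the same shift, so the fragment
size (outer distance) is preserved exactly — asserted per pair in the
tests. With odd c the realized mate count exceeds c by one; the
ground-truth matrix reported to users is the synthetic count matrix, with
this rounding documented. In designed-truth mode the donor pair is first
translated by d; pairs relocated entirely off the chromosome are dropped
(counted, with a warning) and the rest are clamped jointly so the
fragment size survives clamping.

**Substitution errors.** Position i (5'→3' in read orientation, per mate
role) has total error rate p_i estimated as mismatches/observations
against the reference; the substituting base is drawn conditionally on
the reference base, with cells under 50 observations falling back to the
positional aggregate (variance control on small inputs). Injection is a
per-base Bernoulli(p_i); substituted bases get Phred quality 24 ('9'),
untouched bases 37 ('F'), so quality 24 holds iff the base changed — an
exactly checkable invariant. `N` bases are never substituted. Indels are
out of scope.

## What the fixtures emulate — and what they do not

The fixture generators produce uniform-composition genomes, genes with
random transcript/exon structure (including planted overlapping pairs
whose supergene components are known), UMI-tagged reads whose per-feature
tabulation equals a planted matrix with a planted reads-per-UMI law and
planted per-position error rates, and paired ATAC fragments with planted
peak enrichment and a clamped-normal fragment-size law whose background
is placed on the peak complement (so enrichment ratio 1 is genuinely
flat). They do not emulate sequence content (motifs, GC waves, Tn5
insertion bias), mappability structure, doublets, or per-cell depth
gradients. Green tests therefore establish that the algorithms implement
their stated laws exactly and recover planted structure; they do not
establish that synthetic reads are indistinguishable from any particular
real data set — that comparison requires real input and the evaluation
module's statistics (summary statistics, k-mer spectra, fragment-size
distributions, RPKM, truth-peak matching).

## Problem sizes and acceptance checks

The shipped checks run at sizes chosen to make the statistical assertions
sharp while keeping a full run in seconds on one core: 200 genes x 100
cells for the count round trip; 1e5 reads for the shift, masking,
transcriptome-uniformity and error-rate laws (binomial standard errors
~1.5e-3 at p = 0.05); 2000 cells for parameter recovery (mu within ±5%,
theta within ±20%, copula correlation within ±0.1) and depth scaling
(±5%). `scripts/acceptance.R` recomputes all of these from scratch under
a user-supplied seed and writes them as JSON.

## Known limitations

* One NB family for all features; no zero-inflation, no per-feature
  family selection, no continuous trajectories, batches or multi-omics
  joint modelling.
* Ground truths are gene-level (no isoforms) and the ATAC model copies
  mate orientation and fragment size without modelling Tn5 bias.
* The fallback region caller uses a single global background rate.
* Doublet removal is a hook (`remove_flagged_cells()`); no detector is
  bundled.
* Alignment of the emitted FASTQ is left to the user; since true
  positions are known, the package writes SAM directly instead.
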