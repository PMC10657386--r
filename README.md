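# screads

Simulation of single-cell RNA-seq and ATAC-seq sequencing reads with
ground truths.

## The problem

Benchmarking read-level single-cell tools — UMI deduplication tools
(UMI-tools, STARsolo, cellranger) and scATAC-seq peak callers (MACS-style
callers and friends) — requires sequencing reads whose ground truth is
known: the true molecule (UMI) count of every gene in every cell, or the
true open-chromatin regions. Real data never comes with that truth, and
purely parametric simulators do not look like real reads. `screads` takes
the middle road: it **learns from a real set of aligned, barcoded reads**
and emits synthetic reads that mimic them — at the count level, at the
read-position level and at the base/quality level — while recording the
exact ground truth it generated from.

The package is aimed at method developers who need FASTQ/SAM input with
known truth, and at anyone studying the behaviour of single-cell
quantification pipelines under controlled cell numbers, sequencing depths
and error rates.

## The method

The simulator runs in three steps.

**1. Genome segmentation.** For scRNA-seq, overlapping annotated genes are
aggregated into non-overlapping features ("supergenes") and the complement
is kept as inter-genes, so every read has exactly one home. For scATAC-seq
the genome is split into trustworthy peaks, trustworthy non-peaks, and
*gray areas* (everything else — regions that cannot be confidently
classified). Trustworthy regions can be supplied as BED files, selected
from a candidate list by the half-length overlap rule, or called by a
built-in coverage-window fallback (per-window Poisson upper-tail p-values,
BH-adjusted, with a stringent q for peaks and a relaxed q whose complement
defines non-peaks).

**2. Synthetic counts.** Real feature-by-cell count matrices (distinct
UMIs for RNA; mates for ATAC) are fitted per cell cluster with a negative
binomial marginal for every feature g in cluster k,

    X_g | cluster k  ~  NB(mu_kg, theta_kg),   Var = mu + mu^2/theta,

coupled across the top-J features by a Gaussian copula with correlation
matrix R_k estimated from normal scores of the distributional transform.
Synthetic cells are drawn cluster-wise (multinomial on the fitted cluster
proportions); the sequencing-depth factor r is applied by binomial
thinning (r <= 1) or mean scaling (r > 1). Gray areas inherit the
synthetic counts of their nearest upstream non-peak, masked entrywise with
probability max(1 − L_gray/L_nonpeak, 0), and become ground-truth
non-peaks.

**3. Synthetic reads.** Each synthetic UMI inherits the read multiplicity
of a resampled real UMI (the empirical reads-per-UMI law of its feature);
each synthetic read takes a real read's 5' position plus a uniform shift
on −4..4 nt. ATAC counts c become ⌈c/2⌉ read pairs resampled from the real
pairs of the feature, with one shared shift per pair so the fragment size
is preserved exactly; user-designed ground-truth peaks relocate their
donor's reads by the signed distance between the two regions. Per-position
substitution error rates estimated from the real reads are injected
Bernoulli-wise (quality 37 for reference bases, 24 for substituted ones),
and read 1 carries a 16-nt cell barcode plus a 10-nt UMI (26 nt total).

Everything is seeded: the same configuration and seed give byte-identical
FASTQ output.

## Worked example

The fixture generator stands in for real data, so the whole pipeline runs
in seconds with no download:

```r
library(screads)

# toy training data: 2 x 60 kb genome, 12 genes (some overlapping),
# UMI-tagged reads for 15 cells with a planted UMI count matrix
genome <- make_toy_genome(n_chrom = 2, chrom_len = 6e4, seed = 3)
ann    <- make_toy_annotation(chrom_sizes(genome), n_genes = 12,
                              overlap_fraction = 0.3, seed = 3)
train  <- make_toy_scrna_reads(genome, merge_overlapping_genes(ann$genes),
                               n_cells = 15, seed = 4)

sim <- simulate_rna(train$reads, ann$genes, genome,
                    outdir = "rna_sim", n_cells = 10, seed = 7)

sim$model_gene
#> NB Gaussian-copula count model
#>   features: 11
#>   clusters: 2 (proportions 0.467, 0.533)
#>   copula features per cluster: 11, 10

nrow(sim$ledger)                      # synthetic reads 2
#> [1] 347
table(sim$ledger$shift)               # 5' shifts, uniform on -4..4
#> -4 -3 -2 -1  0  1  2  3  4
#> 46 33 42 40 34 38 45 29 40
dim(sim$synth_gene)                   # ground-truth UMI matrix
#> [1] 11 10
substr(sim$read1$seq[1], 1, 16)       # cell barcode of the first read
#> [1] "TGACAACATTGCGGAG"
list.files("rna_sim")
#> [1] "barcode_whitelist.txt" "gene_umi_matrix"       "intergene_umi_matrix"
#> [4] "manifest.json"         "reads_R1.fastq"        "reads_R2.fastq"
#> [7] "synthetic_reads.sam"
```

The 12 annotated genes collapse to 11 features because one planted
overlapping pair merges into a supergene. `gene_umi_matrix/` holds the
ground-truth UMI counts of the 10 synthetic cells; the shift table shows
the resampled read positions staying within ±4 nt of their sources.
`simulate_atac()` is the scATAC-seq counterpart (mimic mode or
user-designed ground-truth peaks via `designed_peaks=`); `inst/cli/screads`
wraps both as shell subcommands.

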