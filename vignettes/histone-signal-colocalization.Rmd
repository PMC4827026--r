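---
title: "Mapping a histone modification against expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a histone modification against expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histcoloc)
```

# The problem

Histone acetylation is usually a mark of active chromatin, but some
acetylation sites behave differently: H4K20ac in human cells accumulates
around the transcription start sites (TSSs) of *minimally expressed* genes
and, mildly, in the bodies of expressed genes. Establishing a claim like
that from ChIP-seq requires a chain of small, well-defined computations:
depth- and length-normalized coverage, input subtraction, stratification of
genes by expression, anchor-relative aggregation, similarity statistics
between tracks, motif co-localization, and — upstream of all of it —
mass-spectrometric confirmation that the modification itself exists and is
distinguishable from its near-isobaric neighbors. This package implements
that chain as reusable, tested components, with a seeded synthetic-data
generator so that every stage can be validated without any external
sequencing data.

# Signal model

## Binned RPKM and signal intensity

The genome is tiled into bins of `L` bp (`bin_grid()`); the terminal bin of
a chromosome may be shorter. Each aligned read is reduced to its 5'-end
coordinate and contributes to exactly one bin, so bin counts always sum to
the library size. Counts are normalized as

$$\mathrm{RPKM}_i = \frac{c_i}{(w_i/10^3)\,(N/10^6)},$$

where $c_i$ is the bin count, $w_i$ the bin width and $N$ the number of
mapped reads. We use the *actual* bin width $w_i$ rather than the nominal
`L`, which matters only for the partial terminal bin; all full bins behave
identically. The normalized **signal intensity** is the per-bin difference

$$SI_i = \mathrm{RPKM}^{\mathrm{ChIP}}_i - \mathrm{RPKM}^{\mathrm{Input}}_i,$$

which may legitimately be negative: regions depleted in ChIP relative to
input sit below zero, and because planted (or real) enrichment inflates the
ChIP library total, background bins of an enriched library sit slightly
below zero too. No smoothing is applied, and reads are not extended to
fragment length; 5'-end counting makes the result independent of read
length and is applied identically to both libraries, so the subtraction is
unaffected.

The default `L` is 1000 bp where an analysis does not dictate one; the
raw-signal TSS aggregation uses 200 bp (about one nucleosome plus linker)
and the track-similarity analysis uses 10 kb windows, both passed
explicitly.

## Region fold change

`fold_change()` compares ChIP and input over two strand-aware per-gene
regions: TSS ± 1 kb, and the gene body from 1 kb downstream of the TSS to
the transcription end site (genes of ≤ 1 kb are skipped for the body
region). The statistic is the ratio of region RPKMs, each computed against
its library's own depth. Division by zero is handled by a symmetric
pseudocount: when the input region count is zero, one read is added to
*both* counts. The correction is rare at realistic depths and keeps the
ratio finite without biasing nonzero-input genes.

## A deliberately naive peak caller

`naive_peak_call()` merges maximal runs of at least `min_run` consecutive
bins with $SI \ge$ `min_si`. It exists so the pipeline runs end to end
without external software; it performs no background modelling, fragment
estimation or FDR control, and for real data a statistical caller should
be used and its output read with `read_intervals()`. Sensible thresholds
scale with depth; in our own analyses we set `min_si` to an upper quantile
of the SI distribution (e.g. the 97th percentile when roughly 3% of the
genome is expected to be enriched) with `min_run = 2`.

# Expression stratification

Genes with FPKM = 0 form the `"zero"` group; the remaining genes are ranked
ascending by FPKM and cut at rank deciles into ten groups, `q0-10` (lowest
nonzero) to `q90-100`. Rank deciles, not equal-width FPKM intervals, are
used so every group is populated regardless of the (heavily skewed)
expression distribution; ties are broken by gene id, making the split
deterministic. Group sizes therefore differ by at most one. An alternative
stratification by promoter signal (`assign_signal_decile_groups()`) ranks
genes by their mean SI over TSS ± 2 kb — the mean, not the sum, so the
value does not depend on how many bins the window spans.

# Aggregation profiles

All profiles are strand-flipped so positive offsets are downstream in
transcription order, and a gene contributes only to its own group.

* `peaks_per_gene_profile()` samples a 0/1 peak-coverage indicator at each
  offset from the anchor (TSS or TES) and averages within groups; values
  are fractions of genes in the group covered at that distance.
* `metagene_profile()` uses a composite axis: absolute bp in the ±5 kb
  flanks, and the gene body rescaled to [0, 1] and discretized into
  `n_body_bins` slices (default 100) sampled at slice centers. Point
  sampling means genes shorter than the number of slices simply resample
  nearby positions rather than erroring. It accepts either peak calls
  (indicator) or a signal track (mean SI).
* `raw_signal_tss_profile()` averages binned SI by TSS offset, one value
  per 200-bp window sampled at the window's central bp.

The absolute-axis sampling step defaults to 50 bp; this is a plotting
resolution, not a statistical parameter. Positions that fall beyond a
chromosome edge are dropped from the group averages rather than imputed.
A gene is "enriched at the TSS" (`select_enriched_genes()`) when at least
one peak overlaps TSS ± 1 kb by at least 1 bp under the half-open
convention: a peak ending exactly where the window starts does not count.

# Track similarity: Jaccard curves

Two tracks are compared on 10-kb windows. The *matching control* labels a
window true when its SI reaches the track's own percentile threshold —
95th for spiky promoter marks (H3K4me3, H3K27ac), 90th for broad marks
(H3K9me3, H3K27me3, H4K20ac); percentiles use linear interpolation between
order statistics (R's default type 7). The query track is then swept over
cutoffs in $SI \in [-1, 2]$ (step 0.05 by default), labelling windows
positive at each cutoff, and the Jaccard index

$$J = \frac{|A \cap B|}{|A \cup B|} = \frac{\#TP}{\#\mathrm{true} + \#FP}$$

is recorded per cutoff. $J = 1$ iff the labelings coincide on a non-empty
set; when both sets are empty the point is undefined and reported as `NA`
rather than 0. All windows enter the percentile computation; windows with
no coverage in either library are not excluded.

# Motif co-localization

`profile_over_sites()` averages SI by distance from site midpoints
(strand-flipped when sites are stranded). `motif_enrichment_table()` ranks
factors by the fold between the observed number of sites in peaks and the
mean over seeded random re-placements of the peak set within each
chromosome (per-chromosome counts and lengths preserved). This
fold-vs-shuffle ranking is this package's own background model — public
motif-enrichment servers use different statistics — and is labelled as
such. `positive_rate()` is the fraction of predicted sites overlapping a
TF ChIP peak by ≥ 1 bp, the quantity used to argue that co-localization
differences are not artifacts of differing false-positive rates among
motif catalogs.

# Peptide masses

`monoisotopic_mh()` sums residue monoisotopic masses (standard IUPAC
values at 6 decimals), one water (18.010565 Da), the modification deltas
(acetyl +42.010565, methyl +14.015650, dimethyl +28.031300, trimethyl
+42.046950 Da) and one proton (1.007276 Da). Six-decimal residue masses
are used so that 4-decimal MH+ values round correctly; acetyl and
trimethyl lysine differ by only 0.036385 Da, which is why accurate-mass
assignment needs tolerances of ~0.01 Da. `assign_modification()` accepts a
call only when exactly one candidate lies within tolerance and the
second-best error is at least `margin` (default 0.005 Da) worse; a
measurement midway between two species, or a tolerance wide enough to
admit both (e.g. 0.05 Da for the acetyl/trimethyl pair), yields an
`"ambiguous"` status instead of a guess.

# The synthetic experiment

`generate_synthetic_experiment()` draws, from a single seed:

* a genome of 2 × 5 Mb with 1000 non-overlapping stranded genes of
  1.5–10 kb (uniform lengths; random gaps via sorted uniform cuts);
* zero-inflated expression: 20% of genes at FPKM 0, the rest log-normal
  (meanlog 1, sdlog 1.5) — a heavy-tailed shape typical of FPKM tables;
* ChIP reads (10^6) from a mixture of uniform background and planted
  enrichment: density fold 5 over a 1-kb window centered on the TSS for
  genes in q0-10–q20-30, and fold 2 over the gene body (1 kb downstream of
  TSS to TES) for q90-100 — the qualitative structure under study: strong
  TSS signal confined to minimally expressed genes, subtle body signal in
  highly expressed ones;
* a matched uniform input library (10^6 reads), and read totals that equal
  the configured sizes exactly;
* motif catalogs: 300 sites, half planted inside the enrichment windows,
  and synthetic TF peaks covering 30% of sites, so the positive rate is
  recoverable up to binomial noise.

Reads are emitted as 36-bp BED intervals whose 5' ends are the sampled
positions, so the files round-trip exactly through `read_alignments()`.

What the generator does *not* emulate: mappability and GC biases, duplicate
reads, fragment-length effects, overdispersed (non-Poisson) background,
overlapping genes and isoforms, and realistic inter-gene spacing (the
synthetic genome is gene-dense). Passing the recovery tests therefore shows
the pipeline's arithmetic and bookkeeping are correct under the assumed
signal model, not that the biological conclusions would survive those
real-data complications; for real data the upstream caller, aligner and
quantifier carry that burden.

# Problem sizes and determinism

The test suite and the acceptance script run the full standard simulation
(2 × 5 Mb, 1000 genes, 2 × 10^6 reads) in well under a minute on one CPU;
unit tests use smaller genomes. All stochastic steps take explicit seeds;
the generator derives per-catalog sub-seeds deterministically from the
configured seed so that adding a catalog does not perturb the reads.
Statistical assertions in the tests use 3–4σ binomial or rate bounds, so
they hold for any seed with overwhelming probability rather than for one
blessed value.

# Known limitations

* The naive peak caller is plumbing, not a contribution; its thresholds are
  user-supplied.
* The metagene body axis uses point sampling at slice centers; a
  coverage-weighted average within each slice would differ slightly for
  features narrower than a slice.
* The motif enrichment background re-places peaks independently, so
  shuffled peaks may overlap each other; with realistic peak densities the
  effect on the mean background count is negligible.
* `read_alignments()` accepts BED and SAM; coordinate-sorted BAM works via
  `Rsamtools` but duplicate marking and mapping-quality filters are out of
  scope.
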