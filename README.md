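# histcoloc

Tools for asking where a histone modification sits on the genome and what
that position means: is it enriched at transcription start sites (TSSs),
and of which genes — silent, minimally expressed, or highly expressed? Does
its genomic distribution resemble any other chromatin mark? Which
transcription-factor motifs co-occur with it? And, upstream of all the
genomics, is the modification itself real — can an accurate peptide mass
distinguish, say, lysine acetylation from the nearly isobaric
trimethylation?

The package grew out of the analysis style used to characterize H4K20ac, an
unusual acetylation mark enriched at TSSs of minimally expressed genes, but
every component is generic. It is aimed at computational biologists who
have aligned ChIP-seq reads, peak calls and an expression table and want
the downstream analysis to be reproducible and testable.

## What it computes

* **Signal intensity (SI)** — the genome is tiled into *L*-bp bins, each
  library's reads are counted by their 5′ ends and normalized to RPKM, and

  *SI = RPKM(ChIP) − RPKM(input)*

  per bin. Negative values are meaningful (input exceeds ChIP).
* **Expression groups** — genes with FPKM = 0 form a `zero` group; the rest
  split into rank deciles `q0-10` … `q90-100`.
* **Aggregation profiles** — group-averaged peak coverage ("peaks per
  gene") or SI around the TSS/TES, and metagene profiles in which gene
  bodies are rescaled to a common 0–1 axis between ±5 kb absolute flanks.
* **Region fold change** — RPKM(ChIP)/RPKM(input) over TSS ± 1 kb or the
  gene body (1 kb downstream of TSS to TES), strand-aware.
* **Jaccard curves** — tracks thresholded at their own 90th/95th SI
  percentile on 10-kb windows become true/false label sets; a query track
  is swept over SI cutoffs in [−1, 2] and scored by intersection-over-union
  against the control at each cutoff.
* **Motif co-localization** — SI profiles across binding-site catalogs,
  fold enrichment of site counts in peaks versus a shuffled background, and
  the positive rate of predicted motifs against TF ChIP peaks.
* **Peptide masses** — monoisotopic MH⁺ of modified histone peptides and
  assignment of a modification state from an accurate measured mass, with
  explicit ambiguity handling (acetyl vs trimethyl differ by 0.0364 Da).
* **Synthetic data** — a seeded generator producing annotation, expression,
  reads and motif catalogs with planted enrichment, so the whole pipeline
  is testable offline.

Standard formats (GTF, BED, narrowPeak, SAM, bedGraph, Cufflinks-style
expression tables) are read through `rtracklayer`/`Rsamtools`; internal
coordinates are uniformly 0-based half-open (BED convention).

## Worked example

```r
library(histcoloc)

sim <- generate_synthetic_experiment(simulation_config(seed = 1))
si  <- si_track_from_reads(sim$chip_reads, sim$input_reads, sim$layout,
                           bin_size = 200)
si
#> signal_track(si): 50000 bins of 200 bp, range [-145, 850]

peaks <- naive_peak_call(si, min_si = quantile(si$values, 0.97), min_run = 2)
nrow(peaks)
#> [1] 271

prof <- peaks_per_gene_profile(peaks, sim$genes, sim$groups,
                               flank = 5000, step = 50, layout = sim$layout)
at0 <- prof[prof$offset == 0, ]
head(at0[order(-at0$value), ], 5)
#>   group offset      value
#>   q0-10      0 1.00000000
#>  q10-20      0 1.00000000
#>  q20-30      0 1.00000000
#>  q70-80      0 0.03846154
#>  q40-50      0 0.03797468

length(select_enriched_genes(peaks, sim$genes))
#> [1] 273
```

The three lowest nonzero expression deciles — where the generator planted
5-fold TSS enrichment — have peak coverage 1.0 at the TSS while every other
group, including the silent `zero` group, stays below 0.04: the profile
recovers the planted biology. The 273 selected genes are essentially the
~300 genes of those three deciles, minus those whose peak missed the ±1 kb
window.

On the proteomics side:

```r
cand <- peptide_candidates("RHRKVLR", 4, c("acetyl", "trimethyl"))
cand[, c("name", "mh_plus")]
#>       name  mh_plus
#>     acetyl 1006.638
#>  trimethyl 1006.674

assign_modification(1006.6434, cand, tolerance = 0.01)
#> $status: "match"   $best: "acetyl"   $delta: 0.00531
```

A measured MH⁺ of 1006.6434 is 5.3 mDa from the acetylated species and
31 mDa from the trimethylated one, so at a 0.01 Da tolerance the call is an
unambiguous acetyl; at a 0.05 Da tolerance both species would qualify and
the same call returns `"ambiguous"` instead.

## Design notes

The methods vignette (`vignettes/histone-signal-colocalization.Rmd`)
documents the model, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices (percentile definition, tie-breaking,
pseudocounts, edge truncation).
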