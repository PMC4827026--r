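## Seeded synthetic-data generator.
##
## Emulates the statistical structure the downstream analysis assumes: a
## small genome of stranded, non-overlapping genes; a zero-inflated
## log-normal expression distribution; ChIP read coverage that is uniform
## Poisson background plus planted enrichment — TSS-proximal in the
## low-but-nonzero expression deciles and gene-body in the top decile —
## with a matched uniform input library; plus motif-site and TF-peak
## catalogs correlated with the planted enrichment. All randomness flows
## from a single seed so identical configurations reproduce identical
## data.

#' Configuration for the synthetic experiment
#'
#' Defaults describe the standard simulated study: 2 chromosomes of 5 Mb,
#' 1000 genes, one million ChIP and one million input reads, 5-fold TSS
#' enrichment planted in the three lowest nonzero expression deciles
#' (q0-10, q10-20, q20-30) over windows of 1 kb centered on the TSS, and
#' 2-fold gene-body enrichment in the top decile.
#'
#' @param seed Integer seed driving every draw.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of genes, placed without overlap across both
#'   strands.
#' @param gene_length_range Min/max gene length in bp.
#' @param zero_fraction Fraction of silent (FPKM = 0) genes.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of nonzero FPKM.
#' @param tss_enrichment Named fold (>= 1) of ChIP read density over
#'   background in the TSS window, per expression group; unnamed groups
#'   get fold 1.
#' @param body_enrichment Named fold (>= 1) over the gene body, per group.
#' @param enrichment_width Width in bp of the planted TSS window (centered
#'   on the TSS).
#' @param n_reads_chip,n_reads_input Library sizes (emitted exactly).
#' @param n_sites Motif sites in the synthetic catalog.
#' @param site_fraction_enriched Fraction of sites planted inside planted
#'   TSS-enrichment windows; the rest are uniform.
#' @param tf_positive_rate Fraction of sites covered by a synthetic TF
#'   ChIP peak.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 2,
                              chrom_length = 5e6,
                              n_genes = 1000,
                              gene_length_range = c(1500, 10000),
                              zero_fraction = 0.2,
                              fpkm_meanlog = 1,
                              fpkm_sdlog = 1.5,
                              tss_enrichment = c("q0-10" = 5,
                                                 "q10-20" = 5,
                                                 "q20-30" = 5),
                              body_enrichment = c("q90-100" = 2),
                              enrichment_width = 1000,
                              n_reads_chip = 1e6,
                              n_reads_input = 1e6,
                              n_sites = 300,
                              site_fraction_enriched = 0.5,
                              tf_positive_rate = 0.3) {
  cfg <- list(seed = seed, n_chroms = n_chroms,
              chrom_length = chrom_length, n_genes = n_genes,
              gene_length_range = gene_length_range,
              zero_fraction = zero_fraction,
              fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
              tss_enrichment = tss_enrichment,
              body_enrichment = body_enrichment,
              enrichment_width = enrichment_width,
              n_reads_chip = n_reads_chip, n_reads_input = n_reads_input,
              n_sites = n_sites,
              site_fraction_enriched = site_fraction_enriched,
              tf_positive_rate = tf_positive_rate)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes > 0,
            cfg$zero_fraction >= 0, cfg$zero_fraction < 1,
            all(cfg$tss_enrichment >= 1), all(cfg$body_enrichment >= 1),
            cfg$n_reads_chip > 0, cfg$n_reads_input > 0)
  class(cfg) <- "simulation_config"
  cfg
}

## Internal: place n non-overlapping intervals of the given lengths on
## [0, chrom_len): random gaps distributed by sorted uniform draws
place_nonoverlapping <- function(lengths, chrom_len) {
  slack <- chrom_len - sum(lengths)
  if (slack < 0)
    stop("genes cannot be placed without overlap; ",
         "use a larger genome or fewer/shorter genes")
  cuts <- sort(stats::runif(length(lengths), 0, slack))
  gaps <- diff(c(0, cuts))
  starts <- cumsum(gaps) + cumsum(c(0, lengths[-length(lengths)]))
  floor(starts)
}

## Internal: sample read 5' positions from uniform background plus
## enriched regions with densities fold x background
sample_read_positions <- function(n_reads, layout, regions) {
  g_size <- genome_size(layout)
  extra <- if (nrow(regions) > 0)
    (regions$end - regions$start) * (regions$fold - 1) else numeric()
  w <- c(g_size, extra)
  comp <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
  pos <- numeric(n_reads)
  chrom <- character(n_reads)
  bg <- comp == 1
  if (any(bg)) {
    u <- stats::runif(sum(bg), 0, g_size)
    ci <- findInterval(u, cumsum(layout$length), left.open = TRUE) + 1
    chrom[bg] <- layout$chrom[ci]
    pos[bg] <- floor(u - layout$offset[ci])
  }
  if (any(!bg)) {
    ri <- comp[!bg] - 1
    chrom[!bg] <- regions$chrom[ri]
    pos[!bg] <- floor(stats::runif(sum(!bg), regions$start[ri],
                                   regions$end[ri]))
  }
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  read_set(chrom, pos, strand)
}

#' Generate a synthetic ChIP-seq experiment
#'
#' Draws genes, expression values, planted enrichment regions, ChIP and
#' input reads from `config` (see [simulation_config()]). Optionally
#' writes the standard file set: `annotation.gtf`, `expression.tsv`,
#' `chip.bed`, `input.bed` (reads as 36-bp intervals whose 5' ends are the
#' sampled positions) and `truth.json`.
#'
#' @param config A [simulation_config()].
#' @param outdir Directory to write files to, or `NULL` for in-memory
#'   output only.
#' @return List with `layout`, `genes`, `expression`, `groups`,
#'   `chip_reads`, `input_reads`, `truth` (planted region tables and
#'   per-gene groups) and, when `outdir` is given, `files`.
#' @export
generate_synthetic_experiment <- function(config = simulation_config(),
                                          outdir = NULL) {
  set.seed(config$seed)
  layout <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                          rep(config$chrom_length, config$n_chroms))
  # genes: lengths uniform in range, split evenly across chromosomes
  chrom_of <- sort(rep_len(seq_len(config$n_chroms), config$n_genes))
  lens <- floor(stats::runif(config$n_genes, config$gene_length_range[1],
                             config$gene_length_range[2] + 1))
  starts <- numeric(config$n_genes)
  for (ci in seq_len(config$n_chroms)) {
    sel <- chrom_of == ci
    starts[sel] <- place_nonoverlapping(lens[sel], config$chrom_length)
  }
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- gene_models(sprintf("g%04d", seq_len(config$n_genes)),
                       layout$chrom[chrom_of], starts, starts + lens,
                       strand, layout)
  # zero-inflated log-normal expression
  is_zero <- stats::runif(config$n_genes) < config$zero_fraction
  fpkm <- ifelse(is_zero, 0,
                 stats::rlnorm(config$n_genes, config$fpkm_meanlog,
                               config$fpkm_sdlog))
  expression <- data.frame(gene_id = genes$gene_id, fpkm = fpkm,
                           stringsAsFactors = FALSE)
  groups <- assign_expression_groups(expression)
  lab <- as.character(groups$label)
  # planted enrichment regions
  half <- config$enrichment_width / 2
  tss_fold <- config$tss_enrichment[lab]
  tss_sel <- !is.na(tss_fold) & tss_fold > 1
  tss_regions <- data.frame(
    chrom = genes$chrom[tss_sel],
    start = pmax(genes$tss[tss_sel] - half, 0),
    end = pmin(genes$tss[tss_sel] + half,
               chrom_length(layout, genes$chrom[tss_sel])),
    gene_id = genes$gene_id[tss_sel],
    fold = unname(tss_fold[tss_sel]),
    stringsAsFactors = FALSE
  )
  # gene-body enrichment starts 1 kb downstream of the TSS so it stays
  # distinct from TSS-proximal enrichment
  body_fold <- config$body_enrichment[lab]
  body_sel <- !is.na(body_fold) & body_fold > 1 &
    (genes$end - genes$start) > 1000
  body_regions <- data.frame(
    chrom = genes$chrom[body_sel],
    start = ifelse(genes$strand[body_sel] == "+",
                   genes$start[body_sel] + 1000, genes$start[body_sel]),
    end = ifelse(genes$strand[body_sel] == "+",
                 genes$end[body_sel], genes$end[body_sel] - 1000),
    gene_id = genes$gene_id[body_sel],
    fold = unname(body_fold[body_sel]),
    stringsAsFactors = FALSE
  )
  regions <- rbind(tss_regions, body_regions)
  chip_reads <- sample_read_positions(config$n_reads_chip, layout, regions)
  input_reads <- sample_read_positions(config$n_reads_input, layout,
                                       regions[0, , drop = FALSE])
  truth <- list(groups = groups, tss_regions = tss_regions,
                body_regions = body_regions, config = config)
  out <- list(layout = layout, genes = genes, expression = expression,
              groups = groups, chip_reads = chip_reads,
              input_reads = input_reads, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- write_synthetic_experiment(out, outdir)
    out$files <- files
  }
  out
}

## Internal: emit the synthetic experiment as standard files
write_synthetic_experiment <- function(sim, outdir) {
  g <- sim$genes
  gtf <- file.path(outdir, "annotation.gtf")
  writeLines(sprintf(
    "%s\thistcoloc_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    g$chrom, g$start + 1, g$end, g$strand, g$gene_id, g$gene_id), gtf)
  expr <- file.path(outdir, "expression.tsv")
  utils::write.table(sim$expression, expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_reads_bed <- function(rs, path) {
    r <- rs$reads
    plus <- r$strand == "+"
    lens <- chrom_length(sim$layout, r$chrom)
    start <- ifelse(plus, r$pos, pmax(r$pos - 35, 0))
    end <- ifelse(plus, pmin(r$pos + 36, lens), r$pos + 1)
    write_intervals_bed(
      data.frame(chrom = r$chrom, start = start, end = end,
                 name = ".", score = 0, strand = r$strand,
                 stringsAsFactors = FALSE), path)
  }
  chip <- file.path(outdir, "chip.bed")
  inp <- file.path(outdir, "input.bed")
  write_reads_bed(sim$chip_reads, chip)
  write_reads_bed(sim$input_reads, inp)
  truth <- file.path(outdir, "truth.json")
  tr <- sim$truth
  tr$groups$label <- as.character(tr$groups$label)
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA)
  c(annotation = gtf, expression = expr, chip = chip, input = inp,
    truth = truth)
}

#' Generate synthetic motif-site and TF-peak catalogs
#'
#' A configured fraction of motif sites is planted inside the simulated
#' TSS-enrichment windows, the remainder placed uniformly; a configured
#' fraction of all sites is then covered by a synthetic TF ChIP peak, so
#' [positive_rate()] on the emitted catalogs recovers
#' `config$tf_positive_rate` up to binomial noise.
#'
#' @param sim Output of [generate_synthetic_experiment()].
#' @param site_width,tf_peak_width Interval widths in bp.
#' @return List with `sites` (role `motif_site`) and `tf_peaks` (role
#'   `tf_peak`) interval data frames, and `planted` (logical: site inside
#'   an enrichment window).
#' @export
generate_site_catalog <- function(sim, site_width = 20,
                                  tf_peak_width = 300) {
  config <- sim$truth$config
  set.seed(config$seed + 101)
  n <- config$n_sites
  n_in <- round(config$site_fraction_enriched * n)
  regions <- sim$truth$tss_regions
  if (n_in > 0 && nrow(regions) == 0)
    stop("no enrichment windows exist to plant sites into")
  layout <- sim$layout
  mids <- numeric(n)
  chrom <- character(n)
  if (n_in > 0) {
    ri <- sample.int(nrow(regions), n_in, replace = TRUE)
    chrom[seq_len(n_in)] <- regions$chrom[ri]
    mids[seq_len(n_in)] <- floor(stats::runif(
      n_in, regions$start[ri] + site_width / 2,
      regions$end[ri] - site_width / 2))
  }
  if (n_in < n) {
    rest <- (n_in + 1):n
    u <- stats::runif(length(rest), 0, genome_size(layout))
    ci <- findInterval(u, cumsum(layout$length), left.open = TRUE) + 1
    chrom[rest] <- layout$chrom[ci]
    mids[rest] <- floor(u - layout$offset[ci])
    mids[rest] <- pmin(pmax(mids[rest], site_width / 2),
                       layout$length[ci] - site_width / 2)
  }
  sites <- data.frame(
    chrom = chrom,
    start = mids - site_width %/% 2,
    end = mids - site_width %/% 2 + site_width,
    name = "TFsyn",
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(sites, "role") <- "motif_site"
  covered <- stats::runif(n) < config$tf_positive_rate
  pk_mid <- mids[covered]
  pk_chrom <- chrom[covered]
  pk_start <- pmax(pk_mid - tf_peak_width %/% 2, 0)
  tf_peaks <- data.frame(
    chrom = pk_chrom,
    start = pk_start,
    end = pmin(pk_start + tf_peak_width, chrom_length(layout, pk_chrom)),
    stringsAsFactors = FALSE
  )
  attr(tf_peaks, "role") <- "tf_peak"
  list(sites = sites, tf_peaks = tf_peaks, planted = seq_len(n) <= n_in)
}
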