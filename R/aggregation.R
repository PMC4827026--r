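## Aggregation profiles: group-averaged peak coverage or signal intensity
## at positions laid out relative to gene anchors (TSS/TES) or rescaled
## gene bodies. All profiles are strand-flipped so that positive axis
## positions are downstream in transcription order.

## Internal: align a group labeling to a gene table
match_groups <- function(genes, groups) {
  lab <- groups$label[match(genes$gene_id, groups$gene_id)]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " gene(s) without a group label dropped")
  }
  lab
}

## Internal: 0/1 peak coverage at single-bp points; NA outside the genome
sample_indicator <- function(intervals, chrom, pos, layout = NULL) {
  out <- rep(NA_real_, length(pos))
  inside <- pos >= 0
  if (!is.null(layout)) inside <- inside & pos < chrom_length(layout, chrom)
  if (!any(inside)) return(out)
  if (nrow(intervals) == 0) {
    out[inside] <- 0
    return(out)
  }
  pts <- GenomicRanges::GRanges(chrom[inside],
                                IRanges::IRanges(pos[inside] + 1,
                                                 width = 1))
  hits <- GenomicRanges::countOverlaps(pts, as_granges0(intervals),
                                       ignore.strand = TRUE)
  out[inside] <- as.numeric(hits > 0)
  out
}

## Internal: signal value of the bin containing each point; NA outside
sample_signal <- function(si, chrom, pos) {
  idx <- bin_index(si$grid, chrom, pos)
  val <- rep(NA_real_, length(pos))
  ok <- !is.na(idx)
  val[ok] <- si$values[idx[ok]]
  val
}

## Internal: per-group column means of a genes x positions matrix
group_means <- function(mat, lab, levels) {
  res <- lapply(levels, function(lv) {
    rows <- which(!is.na(lab) & lab == lv)
    if (length(rows) == 0) {
      warning("group ", lv, " is empty; profile set to zero")
      return(rep(0, ncol(mat)))
    }
    colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
  })
  names(res) <- levels
  res
}

#' Peaks-per-gene profile around an anchor
#'
#' For each gene, peak coverage is sampled at positions `offset` bp from
#' the anchor (TSS or TES) in transcription order, giving a 0/1 indicator
#' per position; the profile of a group is the average of its genes'
#' indicators, so values lie in [0, 1] and read as the fraction of genes
#' in the group carrying a peak at that distance from the anchor.
#'
#' @param peaks Interval data frame of peak calls.
#' @param genes Gene model data frame.
#' @param groups Group labels (`gene_id`, `label`), e.g. from
#'   [assign_expression_groups()].
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank Profile half-width in bp.
#' @param step Sampling step in bp.
#' @param layout Optional [genome_layout()] for edge handling; positions
#'   beyond chromosome ends are dropped from the averages.
#' @return Long data frame `group`, `offset`, `value`.
#' @export
peaks_per_gene_profile <- function(peaks, genes, groups,
                                   anchor = c("TSS", "TES"),
                                   flank = 5000, step = 50,
                                   layout = NULL) {
  anchor <- match.arg(anchor)
  lab <- match_groups(genes, groups)
  offs <- seq(-flank, flank, by = step)
  a <- if (anchor == "TSS") genes$tss else genes$tes
  s <- ifelse(genes$strand == "+", 1, -1)
  n_g <- nrow(genes)
  pos <- rep(a, each = length(offs)) + rep(s, each = length(offs)) * offs
  chrom <- rep(genes$chrom, each = length(offs))
  ind <- sample_indicator(peaks, chrom, pos, layout)
  mat <- matrix(ind, nrow = n_g, ncol = length(offs), byrow = TRUE)
  lv <- if (is.factor(lab)) levels(lab) else sort(unique(lab))
  gm <- group_means(mat, lab, lv)
  out <- data.frame(
    group = rep(lv, each = length(offs)),
    offset = rep(offs, times = length(lv)),
    value = unlist(gm, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out
}

#' Gene-body-rescaled metagene profile
#'
#' Positions within gene bodies are expressed as the relative distance
#' between TSS (0) and TES (1) and discretized into `n_body_bins` equal
#' slices sampled at their centers, so genes of different lengths are
#' averaged on a common axis; the flanks outside the gene use absolute bp
#' distances up to `flank`. Works on either peak calls (0/1 coverage
#' indicator) or a signal track (mean SI).
#'
#' @param x Interval data frame of peaks, or a `signal_track`.
#' @param genes,groups,flank,step,layout As in [peaks_per_gene_profile()].
#' @param n_body_bins Number of body slices.
#' @return Long data frame `group`, `segment` (`upstream`/`body`/
#'   `downstream`), `axis` (bp offset in the flanks, fraction in the body),
#'   `axis_index` (strictly increasing across the composite axis), `value`.
#' @export
metagene_profile <- function(x, genes, groups, flank = 5000,
                             n_body_bins = 100, step = 50, layout = NULL) {
  lab <- match_groups(genes, groups)
  lv <- if (is.factor(lab)) levels(lab) else sort(unique(lab))
  up <- seq(-flank, -step, by = step)
  body_f <- (seq_len(n_body_bins) - 0.5) / n_body_bins
  down <- seq(step, flank, by = step)
  s <- ifelse(genes$strand == "+", 1, -1)
  len <- genes$end - genes$start
  n_g <- nrow(genes)
  pos_for <- function(gene_i) {
    c(genes$tss[gene_i] + s[gene_i] * up,
      genes$tss[gene_i] + s[gene_i] * floor(body_f * len[gene_i]),
      genes$tes[gene_i] + s[gene_i] * down)
  }
  npos <- length(up) + n_body_bins + length(down)
  pos <- unlist(lapply(seq_len(n_g), pos_for), use.names = FALSE)
  chrom <- rep(genes$chrom, each = npos)
  val <- if (inherits(x, "signal_track")) sample_signal(x, chrom, pos)
         else sample_indicator(x, chrom, pos, layout)
  mat <- matrix(val, nrow = n_g, ncol = npos, byrow = TRUE)
  gm <- group_means(mat, lab, lv)
  axis <- c(up, body_f, down)
  segment <- rep(c("upstream", "body", "downstream"),
                 c(length(up), n_body_bins, length(down)))
  data.frame(
    group = rep(lv, each = npos),
    segment = rep(segment, times = length(lv)),
    axis = rep(axis, times = length(lv)),
    axis_index = rep(seq_len(npos), times = length(lv)),
    value = unlist(gm, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Raw-signal aggregation around TSSs
#'
#' Averages binned signal intensity (typically on a 200-bp grid, about one
#' nucleosome plus linker) by distance from the TSS for each gene group.
#' Each offset names the window `[offset, offset + L)` in transcription
#' order; the SI sampled for a gene at that offset is the value of the
#' track bin containing the window's central bp.
#'
#' @param si A `signal_track` of kind `"si"`.
#' @param genes,groups,flank As in [peaks_per_gene_profile()].
#' @return Long data frame `group`, `offset`, `value`.
#' @export
raw_signal_tss_profile <- function(si, genes, groups, flank = 5000) {
  lab <- match_groups(genes, groups)
  lv <- if (is.factor(lab)) levels(lab) else sort(unique(lab))
  L <- attr(si$grid, "bin_size")
  offs <- seq(-flank, flank - L, by = L)
  s <- ifelse(genes$strand == "+", 1, -1)
  n_g <- nrow(genes)
  pos <- rep(genes$tss, each = length(offs)) +
    rep(s, each = length(offs)) * (offs + L %/% 2)
  chrom <- rep(genes$chrom, each = length(offs))
  val <- sample_signal(si, chrom, pos)
  mat <- matrix(val, nrow = n_g, ncol = length(offs), byrow = TRUE)
  gm <- group_means(mat, lab, lv)
  data.frame(
    group = rep(lv, each = length(offs)),
    offset = rep(offs, times = length(lv)),
    value = unlist(gm, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Select genes with a peak near the TSS
#'
#' A gene is selected when its window TSS +/- `window` overlaps at least
#' one peak by at least 1 bp (half-open convention: a peak ending exactly
#' where the window starts shares no base and does not select).
#'
#' @param peaks Interval data frame of peak calls.
#' @param genes Gene model data frame.
#' @param window Half-width around the TSS in bp.
#' @return Character vector of selected `gene_id`s.
#' @export
select_enriched_genes <- function(peaks, genes, window = 1000) {
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(character())
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(genes$tss - window, 0),
                    end = genes$tss + window,
                    stringsAsFactors = FALSE)
  hits <- GenomicRanges::countOverlaps(as_granges0(win), as_granges0(peaks),
                                       ignore.strand = TRUE)
  genes$gene_id[hits > 0]
}

#' Write an aggregation profile as TSV
#'
#' @param profile Long profile data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
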