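#' Tile a genome into fixed-size bins
#'
#' Bins of `bin_size` bp tile each chromosome without gaps or overlap; the
#' last bin of a chromosome may be shorter when the length is not a
#' multiple of `bin_size`.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width L in bp.
#' @return A `bin_grid`: data frame of bins (`chrom`, `start`, `end`) with
#'   attributes `layout` and `bin_size`.
#' @export
bin_grid <- function(layout, bin_size) {
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size < 1) stop("bin_size must be >= 1")
  per_chrom <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, per_chrom)
  rownames(grid) <- NULL
  n_bins <- vapply(per_chrom, nrow, integer(1))
  attr(grid, "layout") <- layout
  attr(grid, "bin_size") <- bin_size
  attr(grid, "bin_offset") <- stats::setNames(
    cumsum(c(0L, n_bins[-length(n_bins)])), layout$chrom)
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

## Internal: global 1-based bin index of 0-based positions; NA outside genome
bin_index <- function(grid, chrom, pos) {
  layout <- attr(grid, "layout")
  L <- attr(grid, "bin_size")
  off <- attr(grid, "bin_offset")
  i <- match(chrom, layout$chrom)
  ok <- !is.na(i) & pos >= 0 & pos < layout$length[i]
  idx <- rep(NA_real_, length(pos))
  idx[ok] <- off[i[ok]] + pos[ok] %/% L + 1
  idx
}

same_grid <- function(a, b) {
  identical(attr(a, "bin_size"), attr(b, "bin_size")) &&
    identical(attr(a, "layout")$chrom, attr(b, "layout")$chrom) &&
    identical(attr(a, "layout")$length, attr(b, "layout")$length)
}

#' Count read 5' ends per bin
#'
#' Each read falls in the unique bin containing its 5'-end coordinate, so
#' the counts always sum to `total_mapped`.
#'
#' @param reads A [read_set()].
#' @param grid A [bin_grid()].
#' @return Integer vector of counts, one per bin of `grid`.
#' @export
count_reads_in_bins <- function(reads, grid) {
  idx <- bin_index(grid, reads$reads$chrom, reads$reads$pos)
  if (anyNA(idx))
    stop("reads fall outside the genome layout of the grid")
  tabulate(idx, nbins = nrow(grid))
}

#' Per-bin RPKM track
#'
#' RPKM = count / ((bin length / 1e3) * (total mapped reads / 1e6)). The
#' actual bin width is used for the (possibly shorter) terminal bin of each
#' chromosome.
#'
#' @param counts Per-bin counts from [count_reads_in_bins()].
#' @param grid The [bin_grid()] the counts were made on.
#' @param total_mapped Library size (must be > 0).
#' @return A `signal_track` of kind `"rpkm"`.
#' @export
rpkm_track <- function(counts, grid, total_mapped) {
  if (length(counts) != nrow(grid))
    stop("counts length does not match the grid")
  if (!is.finite(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be positive")
  widths <- grid$end - grid$start
  values <- counts / ((widths / 1e3) * (total_mapped / 1e6))
  signal_track(grid, values, kind = "rpkm")
}

#' Construct a signal track
#'
#' @param grid A [bin_grid()].
#' @param values Numeric vector, one finite value per bin.
#' @param kind `"rpkm"` or `"si"`.
#' @return A `signal_track` list (`grid`, `values`, `kind`).
#' @export
signal_track <- function(grid, values, kind = c("rpkm", "si")) {
  kind <- match.arg(kind)
  if (length(values) != nrow(grid))
    stop("values length does not match the grid")
  if (any(!is.finite(values))) stop("signal values must be finite")
  out <- list(grid = grid, values = as.numeric(values), kind = kind)
  class(out) <- "signal_track"
  out
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track(%s): %d bins of %g bp, range [%.4g, %.4g]\n",
              x$kind, nrow(x$grid), attr(x$grid, "bin_size"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Input-normalized ChIP-seq signal intensity
#'
#' The signal intensity (SI) of a bin is the RPKM of the ChIP library minus
#' the RPKM of the matched input library; it may be negative where the
#' input exceeds the ChIP coverage.
#'
#' @param chip,input RPKM `signal_track`s on the same grid.
#' @return A `signal_track` of kind `"si"`.
#' @export
signal_intensity <- function(chip, input) {
  if (!same_grid(chip$grid, input$grid))
    stop("chip and input tracks are on different grids")
  signal_track(chip$grid, chip$values - input$values, kind = "si")
}

#' Compute an SI track directly from two read sets
#'
#' Convenience wrapper: bins both libraries on one grid, converts to RPKM
#' and subtracts input from ChIP.
#'
#' @param chip_reads,input_reads [read_set()]s.
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (default 1000).
#' @return A `signal_track` of kind `"si"`.
#' @export
si_track_from_reads <- function(chip_reads, input_reads, layout,
                                bin_size = 1000) {
  grid <- bin_grid(layout, bin_size)
  chip <- rpkm_track(count_reads_in_bins(chip_reads, grid), grid,
                     chip_reads$total_mapped)
  inp <- rpkm_track(count_reads_in_bins(input_reads, grid), grid,
                    input_reads$total_mapped)
  signal_intensity(chip, inp)
}

#' RPKM of a single genomic region
#'
#' @param reads A [read_set()].
#' @param chrom,start,end Region in 0-based half-open coordinates; its own
#'   length is the kilobase denominator.
#' @param total_mapped Library size; defaults to the read set's own total.
#' @return RPKM value.
#' @export
region_rpkm <- function(reads, chrom, start, end,
                        total_mapped = reads$total_mapped) {
  if (end <= start) stop("region must have positive length")
  n <- region_read_count(reads, chrom, start, end)
  n / (((end - start) / 1e3) * (total_mapped / 1e6))
}

region_read_count <- function(reads, chrom, start, end) {
  sum(reads$reads$chrom == chrom &
        reads$reads$pos >= start & reads$reads$pos < end)
}

## Internal: vectorized 5'-end counts over many regions at once
count_in_regions <- function(reads, chrom, start, end) {
  regs <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1, end))
  pts <- GenomicRanges::GRanges(reads$reads$chrom,
                                IRanges::IRanges(reads$reads$pos + 1,
                                                 width = 1))
  GenomicRanges::countOverlaps(regs, pts, ignore.strand = TRUE)
}

#' Region fold change of ChIP over input
#'
#' For each gene, reads are counted in one of two strand-aware regions —
#' `"tss1kb"` (TSS +/- 1 kb) or `"genebody"` (1 kb downstream of the TSS to
#' the TES) — converted to RPKM against each library's own depth, and the
#' ratio RPKM_ChIP / RPKM_Input is returned. When the input count is zero,
#' one read is added to both counts so the ratio stays finite; the
#' correction is applied to both libraries symmetrically. Genes shorter
#' than 1 kb are skipped with a warning for `"genebody"`.
#'
#' @param chip_reads,input_reads [read_set()]s.
#' @param genes Gene model data frame (see [read_gene_annotation()]).
#' @param region_kind `"tss1kb"` or `"genebody"`.
#' @param layout Optional [genome_layout()]; regions extending past
#'   chromosome edges are truncated when it is supplied.
#' @return Data frame `gene_id`, `region`, `fc`.
#' @export
fold_change <- function(chip_reads, input_reads, genes,
                        region_kind = c("tss1kb", "genebody"),
                        layout = NULL) {
  region_kind <- match.arg(region_kind)
  if (region_kind == "genebody") {
    short <- (genes$end - genes$start) <= 1000
    if (any(short)) {
      warning(sum(short), " gene(s) of length <= 1 kb skipped for ",
              "gene-body fold change")
      genes <- genes[!short, , drop = FALSE]
    }
    start <- ifelse(genes$strand == "+", genes$start + 1000, genes$start)
    end <- ifelse(genes$strand == "+", genes$end, genes$end - 1000)
  } else {
    start <- genes$tss - 1000
    end <- genes$tss + 1000
  }
  if (!is.null(layout)) {
    lens <- chrom_length(layout, genes$chrom)
    start <- pmax(start, 0)
    end <- pmin(end, lens)
  } else {
    start <- pmax(start, 0)
  }
  n_chip <- count_in_regions(chip_reads, genes$chrom, start, end)
  n_inp <- count_in_regions(input_reads, genes$chrom, start, end)
  # pseudocount: one read added to both libraries when the input is empty
  zero_inp <- n_inp == 0
  n_chip[zero_inp] <- n_chip[zero_inp] + 1
  n_inp[zero_inp] <- 1
  fc <- (n_chip / chip_reads$total_mapped) /
    (n_inp / input_reads$total_mapped)
  data.frame(gene_id = genes$gene_id,
             region = rep(region_kind, nrow(genes)), fc = fc,
             stringsAsFactors = FALSE)
}

#' Naive threshold-run peak caller
#'
#' Convenience caller for pipelines without an external peak caller:
#' maximal runs of at least `min_run` consecutive bins with SI >= `min_si`
#' are merged into intervals. It performs no background modelling and is
#' not a substitute for a statistical peak caller on real data.
#'
#' @param chip_si A `signal_track` of kind `"si"`.
#' @param min_si SI threshold.
#' @param min_run Minimum run length in bins.
#' @return Interval data frame (`chrom`, `start`, `end`, `score` = mean SI
#'   of the run), role `"peak"`; disjoint and sorted.
#' @export
naive_peak_call <- function(chip_si, min_si, min_run = 1) {
  grid <- chip_si$grid
  above <- chip_si$values >= min_si
  # runs must not span chromosome boundaries
  chrom_f <- factor(grid$chrom, levels = unique(grid$chrom))
  out <- lapply(levels(chrom_f), function(cn) {
    sel <- which(chrom_f == cn)
    r <- rle(above[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    data.frame(
      chrom = cn,
      start = grid$start[sel[starts[keep]]],
      end = grid$end[sel[ends[keep]]],
      score = vapply(which(keep), function(k)
        mean(chip_si$values[sel[starts[k]:ends[k]]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "role") <- "peak"
  out
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%s\t%s\t%g", track$grid$chrom,
                   format(track$grid$start, scientific = FALSE, trim = TRUE),
                   format(track$grid$end, scientific = FALSE, trim = TRUE),
                   track$values)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph written on a known grid
#'
#' @param path bedGraph path.
#' @param grid The [bin_grid()] the file was written on.
#' @param kind Track kind of the values (`"si"` or `"rpkm"`).
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, grid, kind = "si") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) != nrow(grid) || !all(tab$chrom == grid$chrom) ||
      !all(tab$start == grid$start))
    stop("bedGraph does not match the supplied grid")
  signal_track(grid, tab$value, kind = kind)
}
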