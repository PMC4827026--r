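#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths over
#' which every other object in the package (bin grids, signal tracks, gene
#' models, interval sets, read sets) is defined. All coordinates in the
#' package are 0-based, half-open (BED convention).
#'
#' @param chrom_names Character vector of unique chromosome names, in the
#'   order bins and tracks will be laid out.
#' @param chrom_lengths Integer vector of chromosome lengths in bp, one per
#'   name, all positive.
#' @return An object of class `genome_layout`: a data frame with columns
#'   `chrom` and `length`, plus a precomputed `offset` column giving the
#'   cumulative bp preceding each chromosome.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(
    chrom = chrom_names,
    length = chrom_lengths,
    offset = cumsum(c(0, chrom_lengths[-length(chrom_lengths)])),
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print(as.data.frame(x)[, c("chrom", "length")], ...)
  invisible(x)
}

#' Chromosome lengths by name
#' @param layout A [genome_layout()].
#' @param chrom Chromosome name(s); unknown names are an error.
#' @return Length(s) in bp.
#' @export
chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Total genome length of a layout
#' @param layout A [genome_layout()].
#' @return Total bp across chromosomes.
#' @export
genome_size <- function(layout) sum(layout$length)

## Internal: data.frame of 0-based half-open intervals -> GRanges (1-based)
as_granges0 <- function(df, layout = NULL) {
  strand <- if ("strand" %in% names(df) && !all(is.na(df$strand))) {
    s <- as.character(df$strand)
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  seqlengths <- NULL
  if (!is.null(layout)) {
    seqlengths <- stats::setNames(layout$length, layout$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

## Internal: validate an interval data.frame against a layout
check_intervals <- function(df, layout = NULL, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start >= df$end))
    stop(what, " records with start >= end are not allowed")
  if (any(df$start < 0)) stop(what, " start coordinates must be >= 0")
  if (!is.null(layout)) {
    if (any(df$end > chrom_length(layout, df$chrom)))
      stop(what, " records extend past the chromosome end")
  }
  invisible(df)
}
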