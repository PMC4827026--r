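#' Read a gene annotation into gene models
#'
#' Reduces a GTF or BED12 annotation to one record per gene: chromosome,
#' 0-based half-open extent, strand, transcription start site (TSS) and
#' transcription end site (TES). When a gene has several transcripts the
#' longest one defines the model. GTF coordinates (1-based, closed) are
#' converted on read; BED12 is taken verbatim with the `name` column as the
#' gene id.
#'
#' The TSS is the 5'-most base of the gene in transcription order: `start`
#' for `+`-strand genes, `end - 1` for `-`-strand genes. The TES is the
#' opposite end.
#'
#' @param path Path to a `.gtf`/`.gff` or BED12 file.
#' @param layout A [genome_layout()]. Records on chromosomes absent from the
#'   layout are skipped with a warning.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`; one row per gene.
#' @export
read_gene_annotation <- function(path, layout) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- rtracklayer::import(path, format = "gtf")
    if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
      stop("GTF lacks gene_id attributes: ", path)
    # prefer transcript-level features; fall back to exon spans, then genes
    type <- as.character(gr$type)
    tx <- gr[type %in% c("transcript", "mRNA")]
    if (length(tx) == 0 && any(type == "exon")) {
      ex <- gr[type == "exon"]
      key <- if ("transcript_id" %in% names(S4Vectors::mcols(ex)))
        ex$transcript_id else ex$gene_id
      sp <- unlist(range(GenomicRanges::split(ex, key)))
      gid <- ex$gene_id[match(names(sp), key)]
      tx <- sp
      tx$gene_id <- gid
    }
    if (length(tx) == 0) {
      tx <- gr[type == "gene"]
    }
    if (length(tx) == 0) stop("no usable features in ", path)
    df <- data.frame(
      gene_id = tx$gene_id,
      chrom = as.character(GenomicRanges::seqnames(tx)),
      start = GenomicRanges::start(tx) - 1L,
      end = GenomicRanges::end(tx),
      strand = as.character(GenomicRanges::strand(tx)),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    df <- data.frame(
      gene_id = if (!is.null(gr$name)) gr$name
                else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  }
  known <- df$chrom %in% layout$chrom
  if (!all(known)) {
    warning(sum(!known), " record(s) on chromosomes absent from the layout ",
            "were skipped (", paste(unique(df$chrom[!known]), collapse = ", "),
            ")")
    df <- df[known, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no gene records left after chromosome filtering")
  # longest transcript per gene; stable tie-break on coordinates
  len <- df$end - df$start
  o <- order(df$gene_id, -len, df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand, layout)
}

#' Build gene models from vectors
#'
#' Low-level constructor used by [read_gene_annotation()] and the synthetic
#' generator. Coordinates are 0-based, half-open.
#'
#' @param gene_id,chrom,start,end,strand Per-gene vectors; strand is
#'   `"+"` or `"-"`.
#' @param layout Optional [genome_layout()] used for bounds checking.
#' @return Gene model data frame (see [read_gene_annotation()]).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, layout = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  check_intervals(df, layout, what = "gene")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tes <- ifelse(df$strand == "+", df$end - 1, df$start)
  rownames(df) <- NULL
  df
}

#' Read genomic intervals from BED or narrowPeak
#'
#' Intervals are kept verbatim in 0-based half-open coordinates. For
#' narrowPeak input the `signalValue` column is retained as `score`.
#'
#' @param path Path to a BED3/BED6 or narrowPeak file.
#' @param role Tag describing what the intervals are
#'   (`"peak"`, `"motif_site"`, `"window"`, `"tf_peak"`); stored as an
#'   attribute.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present in the input, `name`, `score` and `strand`; attribute `role`.
#' @export
read_intervals <- function(path, role = "peak") {
  n_data <- length(utils::count.fields(path, comment.char = "#"))
  if (n_data == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    attr(out, "role") <- role
    return(out)
  }
  is_np <- grepl("\\.narrowPeak$", path, ignore.case = TRUE)
  gr <- if (is_np) rtracklayer::import(path, format = "narrowPeak")
        else rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (is_np) out$score <- gr$signalValue
  else if (!is.null(gr$score) && !all(is.na(gr$score))) out$score <- gr$score
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s %in% c("+", "-"))) out$strand <- s
  check_intervals(out, what = "interval")
  attr(out, "role") <- role
  out
}

#' Write intervals to a BED file
#'
#' @param intervals Interval data frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  n <- nrow(intervals)
  cols <- list(intervals$chrom,
               format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  has_name <- "name" %in% names(intervals)
  has_score <- "score" %in% names(intervals)
  has_strand <- "strand" %in% names(intervals)
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(if (has_name) intervals$name else rep(".", n)))
  }
  if (has_score || has_strand) {
    cols <- c(cols, list(if (has_score) intervals$score else rep(0, n)))
  }
  if (has_strand) cols <- c(cols, list(intervals$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads and reduce them to 5' positions
#'
#' Each mapped read is represented by the genomic coordinate of its 5' end:
#' the interval start for `+`-strand reads, `end - 1` for `-`-strand reads.
#' With 5'-end counting the read length never enters any downstream
#' computation, so ChIP and input libraries of different read lengths are
#' treated identically.
#'
#' @param path A BED file of read intervals or a SAM file of alignments.
#'   SAM records flagged unmapped are skipped and counted in a message.
#' @return A `read_set`: list with `reads` (data frame `chrom`, `pos`,
#'   `strand`) and `total_mapped`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth", "flag"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    unmapped <- bitwAnd(x$flag, 4L) != 0L | is.na(x$pos)
    if (any(unmapped))
      message(sum(unmapped), " unmapped record(s) skipped")
    keep <- !unmapped
    chrom <- as.character(x$rname[keep])
    start0 <- x$pos[keep] - 1L
    end0 <- start0 + x$qwidth[keep]
    strand <- as.character(x$strand[keep])
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
  }
  strand[!(strand %in% c("+", "-"))] <- "+"
  pos <- ifelse(strand == "+", start0, end0 - 1)
  read_set(chrom, pos, strand)
}

#' Build a read set from 5' positions
#'
#' @param chrom,pos,strand Per-read vectors; `pos` is the 0-based 5'-end
#'   coordinate.
#' @return A `read_set` list with elements `reads` and `total_mapped`.
#' @export
read_set <- function(chrom, pos, strand = NULL) {
  if (is.null(strand)) strand <- rep("+", length(chrom))
  out <- list(
    reads = data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
    total_mapped = length(chrom)
  )
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", format(x$total_mapped, big.mark = ","),
      "mapped reads on", length(unique(x$reads$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Pool replicate read sets
#'
#' Replicates are combined by simple concatenation before any counting.
#'
#' @param ... `read_set` objects.
#' @return A single pooled `read_set`.
#' @export
pool_read_sets <- function(...) {
  sets <- list(...)
  df <- do.call(rbind, lapply(sets, function(s) s$reads))
  read_set(df$chrom, df$pos, df$strand)
}

#' Read a gene expression table
#'
#' Accepts either a plain two-column TSV (`gene_id`, `fpkm`, with or without
#' a header) or a Cufflinks `gene_exp.diff`-style table from which the gene
#' id and FPKM columns are picked by name.
#'
#' @param path Path to a TSV file.
#' @param gene_col,fpkm_col Column names to use when the file has a header
#'   with more than two columns.
#' @return A data frame with columns `gene_id` and `fpkm`.
#' @export
read_expression_table <- function(path, gene_col = "gene_id",
                                  fpkm_col = "FPKM") {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields[-1]))))
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) == 2) {
    names(tab) <- c("gene_id", "fpkm")
  } else {
    idx_g <- match(gene_col, names(tab))
    idx_f <- match(fpkm_col, names(tab))
    # Cufflinks gene_exp.diff carries two FPKM columns value_1/value_2;
    # fall back to value_1 when no plain FPKM column exists
    if (is.na(idx_f)) idx_f <- match("value_1", names(tab))
    if (is.na(idx_g) || is.na(idx_f))
      stop("cannot locate gene id / FPKM columns in ", path)
    tab <- data.frame(gene_id = tab[[idx_g]], fpkm = tab[[idx_f]],
                      stringsAsFactors = FALSE)
  }
  tab$fpkm <- as.numeric(tab$fpkm)
  if (any(is.na(tab$fpkm)) || any(tab$fpkm < 0))
    stop("FPKM values must be non-negative numbers")
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in ", path)
  tab
}
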