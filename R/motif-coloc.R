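## Transcription-factor motif co-localization: signal profiles across site
## catalogs, fold enrichment of site counts in peaks against a shuffled
## background, and positive rate of predicted motifs against TF ChIP peaks.

#' Signal profile across a catalog of binding sites
#'
#' Mean SI by distance from the site midpoint, averaged over all sites of
#' a catalog; when sites carry a strand, minus-strand sites are flipped so
#' positive offsets point in the site's own orientation.
#'
#' @param si A `signal_track`.
#' @param sites Interval data frame of motif sites (optionally with a
#'   `strand` column).
#' @param flank Profile half-width in bp.
#' @return Data frame `offset`, `value`, `n_sites`.
#' @export
profile_over_sites <- function(si, sites, flank = 5000) {
  if (nrow(sites) == 0) stop("site catalog is empty")
  L <- attr(si$grid, "bin_size")
  offs <- seq(-flank, flank, by = L)
  mid <- (sites$start + sites$end) %/% 2
  s <- if ("strand" %in% names(sites))
    ifelse(sites$strand == "-", -1, 1) else rep(1, nrow(sites))
  pos <- rep(mid, each = length(offs)) + rep(s, each = length(offs)) * offs
  chrom <- rep(sites$chrom, each = length(offs))
  val <- sample_signal(si, chrom, pos)
  mat <- matrix(val, nrow = nrow(sites), ncol = length(offs), byrow = TRUE)
  data.frame(offset = offs, value = colMeans(mat, na.rm = TRUE),
             n_sites = nrow(sites))
}

## Internal: number of sites overlapping >=1 interval of `peaks` by >=1 bp
count_sites_in_peaks <- function(sites, peaks) {
  if (nrow(sites) == 0 || nrow(peaks) == 0) return(0L)
  sum(GenomicRanges::countOverlaps(as_granges0(sites), as_granges0(peaks),
                                   ignore.strand = TRUE) > 0)
}

## Internal: random re-placement of each peak within its own chromosome,
## preserving per-chromosome peak counts and lengths
shuffle_peaks <- function(peaks, layout) {
  w <- peaks$end - peaks$start
  maxs <- chrom_length(layout, peaks$chrom) - w
  if (any(maxs < 0)) stop("a peak is longer than its chromosome")
  start <- floor(stats::runif(nrow(peaks), 0, maxs + 1))
  data.frame(chrom = peaks$chrom, start = start, end = start + w,
             stringsAsFactors = FALSE)
}

#' Fold enrichment of motif-site catalogs in peak regions
#'
#' For each transcription factor, counts the sites falling in peaks and
#' compares with the mean count over `n_shuffles` random placements of the
#' peak set within each chromosome (lengths and per-chromosome counts
#' preserved). Rows are ranked by fold (observed / shuffled mean). A zero
#' shuffled mean yields an infinite fold, ranked first and flagged.
#'
#' @param peaks Interval data frame of peak calls.
#' @param catalogs Named list of site interval data frames, or a single
#'   data frame with a `name` column naming the factor of each site (as in
#'   a tfbsConsSites export).
#' @param layout A [genome_layout()].
#' @param n_shuffles Number of background shuffles (>= 1).
#' @param seed Seed for the shuffles.
#' @return Data frame `tf`, `n_sites_in_peaks`, `n_sites_total`,
#'   `background_mean`, `fold`, `flagged`, `rank`, sorted by decreasing
#'   fold.
#' @export
motif_enrichment_table <- function(peaks, catalogs, layout,
                                   n_shuffles = 20, seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (is.data.frame(catalogs)) {
    if (!"name" %in% names(catalogs))
      stop("a single catalog data frame needs a 'name' column")
    catalogs <- split(catalogs, catalogs$name)
  }
  if (length(catalogs) == 0) stop("no catalogs supplied")
  set.seed(seed)
  shuffles <- replicate(n_shuffles, shuffle_peaks(peaks, layout),
                        simplify = FALSE)
  rows <- lapply(names(catalogs), function(tf) {
    sites <- catalogs[[tf]]
    obs <- count_sites_in_peaks(sites, peaks)
    bg <- mean(vapply(shuffles, function(sh)
      count_sites_in_peaks(sites, sh), numeric(1)))
    data.frame(tf = tf, n_sites_in_peaks = obs,
               n_sites_total = nrow(sites), background_mean = bg,
               fold = if (bg == 0) Inf else obs / bg,
               flagged = bg == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Positive rate of predicted motif sites against TF ChIP peaks
#'
#' Fraction of predicted sites overlapping at least one TF ChIP peak by at
#' least 1 bp — the coverage rate used to judge whether a motif catalog's
#' co-localization signal could be an artifact of false-positive
#' predictions.
#'
#' @param predicted_sites Interval data frame of predicted motif sites.
#' @param tf_peaks Interval data frame of TF ChIP peaks.
#' @return Fraction in [0, 1].
#' @export
positive_rate <- function(predicted_sites, tf_peaks) {
  if (nrow(predicted_sites) == 0) stop("no predicted sites supplied")
  if (nrow(tf_peaks) == 0) stop("no TF peaks supplied")
  count_sites_in_peaks(predicted_sites, tf_peaks) / nrow(predicted_sites)
}
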