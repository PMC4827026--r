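#' Expression group labels
#'
#' The eleven labels used throughout the package: `"zero"` for silent genes
#' and ten rank-decile labels `"q0-10"` (lowest-expressed nonzero decile)
#' through `"q90-100"` (highest).
#'
#' @param include_zero Include the `"zero"` level.
#' @return Character vector of labels in increasing-expression order.
#' @export
expression_group_levels <- function(include_zero = TRUE) {
  q <- paste0("q", seq(0, 90, 10), "-", seq(10, 100, 10))
  if (include_zero) c("zero", q) else q
}

## Internal: rank-decile labels for a numeric vector, stable on (value, id).
## Group sizes differ by at most one; the lowest values land in q0-10.
decile_labels <- function(values, ids) {
  n <- length(values)
  o <- order(values, ids, method = "radix")
  rank <- integer(n)
  rank[o] <- seq_len(n)
  g <- pmin(floor((rank - 1L) * 10 / n), 9L)   # sizes differ by at most 1
  expression_group_levels(include_zero = FALSE)[g + 1L]
}

#' Assign genes to the eleven expression groups
#'
#' Genes with FPKM exactly 0 are labeled `"zero"`; the remaining genes are
#' ranked ascending by FPKM (ties broken by gene id for a stable,
#' reproducible split) and cut at rank deciles into ten groups whose sizes
#' differ by at most one.
#'
#' @param table Expression data frame with columns `gene_id` and `fpkm`
#'   (see [read_expression_table()]).
#' @return Data frame `gene_id`, `label` (factor over
#'   [expression_group_levels()]).
#' @export
assign_expression_groups <- function(table) {
  if (nrow(table) == 0) stop("expression table is empty")
  if (any(table$fpkm < 0)) stop("FPKM must be non-negative")
  label <- rep("zero", nrow(table))
  nz <- table$fpkm > 0
  if (!any(nz)) {
    warning("all genes have FPKM = 0; only the \"zero\" group is populated")
  } else {
    label[nz] <- decile_labels(table$fpkm[nz], table$gene_id[nz])
  }
  data.frame(
    gene_id = table$gene_id,
    label = factor(label, levels = expression_group_levels()),
    stringsAsFactors = FALSE
  )
}

#' Mean promoter signal intensity per gene
#'
#' Mean SI over the window TSS +/- `flank`, strand-agnostic, weighted by
#' the bp each bin contributes to the window. Windows are truncated at
#' chromosome edges.
#'
#' @param si A `signal_track`.
#' @param genes Gene model data frame.
#' @param flank Half-width of the promoter window in bp.
#' @return Numeric vector of per-gene means, in `genes` order.
#' @export
promoter_mean_si <- function(si, genes, flank = 2000) {
  grid <- si$grid
  layout <- attr(grid, "layout")
  L <- attr(grid, "bin_size")
  lens <- chrom_length(layout, genes$chrom)
  ws <- pmax(genes$tss - flank, 0)
  we <- pmin(genes$tss + flank, lens)
  vapply(seq_len(nrow(genes)), function(i) {
    i0 <- bin_index(grid, genes$chrom[i], ws[i])
    i1 <- bin_index(grid, genes$chrom[i], we[i] - 1)
    idx <- i0:i1
    ov <- pmin(grid$end[idx], we[i]) - pmax(grid$start[idx], ws[i])
    sum(si$values[idx] * ov) / sum(ov)
  }, numeric(1))
}

#' Group genes by promoter-signal deciles
#'
#' Alternative stratification used when grouping by a promoter mark (e.g.
#' H3K4me3 signal at TSS +/- 2 kb) instead of mRNA level: the per-gene mean
#' SI over the promoter window is computed and genes are cut at rank
#' deciles into ten groups (no `"zero"` group).
#'
#' @inheritParams promoter_mean_si
#' @return Data frame `gene_id`, `label` (factor over the ten decile
#'   levels), `promoter_si`.
#' @export
assign_signal_decile_groups <- function(si, genes, flank = 2000) {
  m <- promoter_mean_si(si, genes, flank)
  data.frame(
    gene_id = genes$gene_id,
    label = factor(decile_labels(m, genes$gene_id),
                   levels = expression_group_levels(include_zero = FALSE)),
    promoter_si = m,
    stringsAsFactors = FALSE
  )
}
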