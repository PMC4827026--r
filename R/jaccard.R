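## Track-similarity statistic: percentile-thresholded labels on 10-kb
## windows and Jaccard curves over a sweep of SI cutoffs.

#' Percentile to use as the matching-control threshold for a mark
#'
#' Spiky promoter marks (H3K4me3, H3K27ac) are thresholded at the 95th
#' percentile of window SIs; broadly and dispersedly distributed marks
#' (H3K9me3, H3K27me3, H4K20ac) at the 90th. Unknown marks default to the
#' broad setting.
#'
#' @param mark Mark name, e.g. `"H3K4me3"`.
#' @return 90 or 95.
#' @export
mark_threshold_percentile <- function(mark) {
  spiky <- c("H3K4me3", "H3K27ac")
  broad <- c("H3K9me3", "H3K27me3", "H4K20ac")
  if (mark %in% spiky) 95 else if (mark %in% broad) 90 else 90
}

#' Threshold a windowed SI track into true/false labels
#'
#' The threshold is the given percentile of SIs over all windows (linear
#' interpolation between order statistics); a window is labeled true when
#' its SI is greater than or equal to the threshold.
#'
#' @param si A `signal_track`, conventionally on a 10-kb grid.
#' @param percentile Percentile in (0, 100), typically 90 or 95 (see
#'   [mark_threshold_percentile()]).
#' @return A `window_labels` object: list with `grid`, `labels` (logical),
#'   `threshold`, `percentile`.
#' @export
label_windows <- function(si, percentile = 90) {
  if (length(si$values) == 0) stop("empty signal track")
  thr <- unname(stats::quantile(si$values, percentile / 100, type = 7))
  out <- list(grid = si$grid, labels = si$values >= thr,
              threshold = thr, percentile = percentile)
  class(out) <- "window_labels"
  out
}

#' @export
print.window_labels <- function(x, ...) {
  cat(sprintf("window_labels: %d/%d true (threshold %.4g = p%g)\n",
              sum(x$labels), length(x$labels), x$threshold, x$percentile))
  invisible(x)
}

#' Jaccard index of two window labelings
#'
#' J = |A intersect B| / |A union B| over the true windows of the two
#' labelings; equivalently TP / (#true + #FP) when one set is taken as
#' truth. J = 1 when the labelings agree exactly on a non-empty set and
#' J = 0 when every positive sits on a false window. When both labelings
#' are all-false the index is undefined and `NA` is returned.
#'
#' @param a,b `window_labels` on the same grid (logical vectors also
#'   accepted).
#' @return J in [0, 1], or `NA` for an empty union.
#' @export
jaccard_index <- function(a, b) {
  la <- if (inherits(a, "window_labels")) a$labels else as.logical(a)
  lb <- if (inherits(b, "window_labels")) b$labels else as.logical(b)
  if (length(la) != length(lb)) stop("labelings are on different grids")
  if (inherits(a, "window_labels") && inherits(b, "window_labels") &&
      !same_grid(a$grid, b$grid))
    stop("labelings are on different grids")
  union <- sum(la | lb)
  if (union == 0) return(NA_real_)
  sum(la & lb) / union
}

#' Jaccard curve of a query track against a matching control
#'
#' Positive labels are set on the query track at each cutoff of a sweep
#' (SI >= cutoff), and the Jaccard index against the fixed control labels
#' is computed, giving similarity as a function of the cutoff level.
#' Cutoffs where both label sets are empty yield `NA` points.
#'
#' @param control A `window_labels` built at the control's own percentile
#'   threshold (the "matching control").
#' @param query_si A `signal_track` on the same grid.
#' @param cutoff_lo,cutoff_hi,cutoff_step Sweep range and step over SI
#'   values; defaults cover SI in [-1, 2] at 0.05 resolution.
#' @return Data frame `cutoff`, `jaccard`, in increasing cutoff order.
#' @export
jaccard_curve <- function(control, query_si, cutoff_lo = -1, cutoff_hi = 2,
                          cutoff_step = 0.05) {
  if (!same_grid(control$grid, query_si$grid))
    stop("control labels and query track are on different grids")
  cutoffs <- seq(cutoff_lo, cutoff_hi, by = cutoff_step)
  j <- vapply(cutoffs, function(ct)
    jaccard_index(control$labels, query_si$values >= ct), numeric(1))
  data.frame(cutoff = cutoffs, jaccard = j)
}

#' All pairwise Jaccard curves of a set of tracks
#'
#' Builds the matching control for each track at its own percentile and
#' sweeps every track against it.
#'
#' @param tracks Named list of `signal_track`s on one grid.
#' @param percentiles Named numeric vector of control percentiles per
#'   track; defaults via [mark_threshold_percentile()] on the names.
#' @param ... Passed to [jaccard_curve()].
#' @return Long data frame `control`, `query`, `cutoff`, `jaccard`.
#' @export
jaccard_curve_matrix <- function(tracks, percentiles = NULL, ...) {
  nm <- names(tracks)
  if (is.null(nm)) stop("tracks must be a named list")
  if (is.null(percentiles))
    percentiles <- vapply(nm, mark_threshold_percentile, numeric(1))
  out <- lapply(nm, function(ctrl) {
    ctl <- label_windows(tracks[[ctrl]], percentiles[[ctrl]])
    curves <- lapply(nm, function(q) {
      cv <- jaccard_curve(ctl, tracks[[q]], ...)
      cbind(control = ctrl, query = q, cv, stringsAsFactors = FALSE)
    })
    do.call(rbind, curves)
  })
  do.call(rbind, out)
}
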