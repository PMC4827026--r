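#' Windowed correlation between two signal tracks
#'
#' Pearson product-moment correlation of two SI tracks, either over every
#' bin of the shared grid (`scope = "genome"`) or over per-gene promoter
#' means (`scope = "tss_flank"`, one paired observation per gene). The
#' statistic always uses all paired values; the returned scatter sample is
#' an optionally downsampled copy for plotting only.
#'
#' @param a,b `signal_track`s on the same grid.
#' @param scope `"genome"` or `"tss_flank"`.
#' @param genes Gene model data frame (required for `"tss_flank"`).
#' @param flank Promoter half-width in bp for `"tss_flank"`.
#' @param scatter_n Maximum scatter points returned; downsampling is
#'   seeded for reproducibility.
#' @param scatter_seed Seed for the downsample.
#' @return List with `n`, `r`, `status` (`"ok"` or
#'   `"zero_variance"`, in which case `r` is `NA`) and `scatter` (data
#'   frame `x`, `y`).
#' @export
windowed_correlation <- function(a, b, scope = c("genome", "tss_flank"),
                                 genes = NULL, flank = 2000,
                                 scatter_n = 50000, scatter_seed = 1) {
  scope <- match.arg(scope)
  if (!same_grid(a$grid, b$grid)) stop("tracks are on different grids")
  if (scope == "genome") {
    x <- a$values
    y <- b$values
  } else {
    if (is.null(genes)) stop("tss_flank scope requires a gene table")
    x <- promoter_mean_si(a, genes, flank)
    y <- promoter_mean_si(b, genes, flank)
  }
  if (length(x) < 2) stop("need at least two paired observations")
  status <- "ok"
  r <- NA_real_
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    status <- "zero_variance"
  } else {
    r <- stats::cor(x, y, method = "pearson")
  }
  idx <- seq_along(x)
  if (length(idx) > scatter_n) {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(scatter_seed)
    idx <- sort(sample(idx, scatter_n))
  }
  list(n = length(x), r = r, status = status,
       scatter = data.frame(x = x[idx], y = y[idx]))
}

## Internal: save/restore the RNG state so plotting-only downsampling does
## not perturb a caller's random stream
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
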