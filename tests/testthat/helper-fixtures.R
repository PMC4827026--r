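# Small in-code fixtures shared across test files.

toy_layout <- function(lens = c(chr1 = 10000, chr2 = 8000)) {
  genome_layout(names(lens), unname(lens))
}

# a deterministic SI track on an arbitrary grid
toy_si <- function(layout, bin_size, values) {
  grid <- bin_grid(layout, bin_size)
  stopifnot(length(values) == nrow(grid))
  signal_track(grid, values, kind = "si")
}

# n reads all at given positions on one chromosome
reads_at <- function(pos, chrom = "chr1", strand = NULL) {
  read_set(rep(chrom, length(pos)), pos, strand)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small simulated experiment reused by several test files
small_sim_config <- function(seed = 42) {
  simulation_config(
    seed = seed, n_chroms = 2, chrom_length = 1e6, n_genes = 200,
    gene_length_range = c(1500, 6000), n_reads_chip = 2e5,
    n_reads_input = 2e5, n_sites = 200
  )
}
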