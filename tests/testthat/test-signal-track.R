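test_that("bin grids tile each chromosome without gaps or overlap", {
  layout <- toy_layout(c(chr1 = 1050, chr2 = 2000))
  grid <- bin_grid(layout, 100)
  for (cn in layout$chrom) {
    b <- grid[grid$chrom == cn, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], chrom_length(layout, cn))
    expect_equal(b$start[-1], b$end[-nrow(b)])  # no gaps, no overlap
  }
  # terminal bin of chr1 is the 50 bp remainder
  expect_equal(min(grid$end - grid$start), 50)
})

test_that("reads land in the unique bin containing their 5' end", {
  layout <- toy_layout(c(chr1 = 200))
  grid <- bin_grid(layout, 100)
  counts <- count_reads_in_bins(reads_at(c(0, 50, 150)), grid)
  expect_equal(counts, c(2, 1))
  expect_equal(count_reads_in_bins(reads_at(numeric()), grid), c(0, 0))
})

test_that("counts are conserved: sum over bins equals total_mapped", {
  layout <- toy_layout()
  grid <- bin_grid(layout, 333)
  set.seed(7)
  n <- 5000
  chrom <- sample(layout$chrom, n, replace = TRUE)
  pos <- floor(runif(n, 0, chrom_length(layout, chrom)))
  rs <- read_set(chrom, pos)
  expect_equal(sum(count_reads_in_bins(rs, grid)), rs$total_mapped)
})

test_that("uniform reads give near-uniform bin counts (binomial oracle)", {
  layout <- genome_layout("chr1", 10000)
  grid <- bin_grid(layout, 1000)
  set.seed(11)
  n <- 10000
  rs <- reads_at(floor(runif(n, 0, 10000)))
  counts <- count_reads_in_bins(rs, grid)
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) < 4 * sigma))
})

test_that("RPKM matches its definition", {
  layout <- genome_layout("chr1", 1000)
  grid <- bin_grid(layout, 1000)
  expect_equal(rpkm_track(10, grid, 1e6)$values, 10)
  expect_equal(rpkm_track(0, grid, 1e6)$values, 0)
  layout2 <- genome_layout("chr1", 200)
  grid2 <- bin_grid(layout2, 200)
  expect_equal(rpkm_track(25, grid2, 2e7)$values, 6.25)  # 25/(0.2*20)
  expect_error(rpkm_track(10, grid, 0), "positive")
})

test_that("signal intensity is the RPKM difference and is antisymmetric", {
  layout <- toy_layout()
  grid <- bin_grid(layout, 1000)
  set.seed(3)
  a <- signal_track(grid, runif(nrow(grid), 0, 10), kind = "rpkm")
  b <- signal_track(grid, runif(nrow(grid), 0, 10), kind = "rpkm")
  expect_equal(signal_intensity(a, b)$values, a$values - b$values)
  expect_equal(signal_intensity(a, b)$values, -signal_intensity(b, a)$values)
  expect_true(all(signal_intensity(a, a)$values == 0))
  grid2 <- bin_grid(layout, 500)
  c2 <- signal_track(grid2, rep(1, nrow(grid2)), kind = "rpkm")
  expect_error(signal_intensity(a, c2), "grid")
})

test_that("region RPKM uses the region's own length and scales with depth", {
  rs <- reads_at(seq(1000, 2999, length.out = 100))
  expect_equal(region_rpkm(rs, "chr1", 1000, 3000, total_mapped = 1e6), 50)
  expect_equal(region_rpkm(rs, "chr1", 1000, 3000, total_mapped = 2e6), 25)
  expect_equal(region_rpkm(reads_at(numeric()), "chr1", 0, 1000,
                           total_mapped = 1e6), 0)
  expect_error(region_rpkm(rs, "chr1", 500, 500, total_mapped = 1e6),
               "positive length")
})

test_that("fold change is the region RPKM ratio with zero-input pseudocount", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 3000, 6000, "+", layout)
  # 40 chip vs 10 input reads in TSS +/- 1kb at equal library sizes -> FC 4
  chip <- reads_at(c(rep(3000, 40), rep(9000, 60)))
  inp <- reads_at(c(rep(3000, 10), rep(9000, 90)))
  fc <- fold_change(chip, inp, genes, "tss1kb", layout)
  expect_equal(fc$fc, 4)
  # identical coverage -> FC 1
  fc1 <- fold_change(chip, chip, genes, "tss1kb", layout)
  expect_equal(fc1$fc, 1)
  # zero input in the region: one read added to both counts
  fc0 <- fold_change(chip, reads_at(rep(9000, 100)), genes, "tss1kb", layout)
  expect_true(is.finite(fc0$fc))
  expect_equal(fc0$fc, (41 / 100) / (1 / 100))
})

test_that("fold-change regions are strand-aware", {
  layout <- toy_layout()
  gplus <- gene_models("gp", "chr1", 2000, 5000, "+", layout)
  gminus <- gene_models("gm", "chr1", 2000, 5000, "-", layout)
  # reads clustered at the RIGHT end (minus-strand TSS)
  chip <- reads_at(rep(4800, 20))
  inp <- reads_at(c(rep(4800, 10), rep(2100, 10)))
  fc_m <- fold_change(chip, inp, gminus, "tss1kb", layout)
  expect_equal(fc_m$fc, 2)  # 20 chip vs 10 input within tss1kb of 4999
  # for the + gene the tss1kb window [1000,3000) holds no chip reads
  fc_p <- fold_change(chip, inp, gplus, "tss1kb", layout)
  expect_equal(fc_p$fc, 0)
})

test_that("gene-body region excludes the first kb downstream of the TSS", {
  layout <- toy_layout()
  gplus <- gene_models("gp", "chr1", 2000, 5000, "+", layout)
  # chip reads only in [2000,3000): inside the gene but within 1 kb of TSS
  chip <- reads_at(rep(2500, 10))
  inp <- reads_at(seq(3000, 4999, length.out = 10))
  fc <- fold_change(chip, inp, gplus, "genebody", layout)
  expect_equal(fc$fc, 0)  # input is nonzero in the body, so no pseudocount
  short <- gene_models("gs", "chr1", 2000, 2800, "+", layout)
  expect_warning(out <- fold_change(chip, inp, short, "genebody", layout),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("naive peak caller returns maximal runs above threshold", {
  layout <- genome_layout("chr1", 2000)
  vals <- rep(0, 20)
  si <- toy_si(layout, 100, vals)
  expect_equal(nrow(naive_peak_call(si, 1, 3)), 0)

  vals[6:10] <- 10  # one block of 5 bins
  si <- toy_si(layout, 100, vals)
  pk <- naive_peak_call(si, 1, 3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 500)
  expect_equal(pk$end, 1000)

  vals2 <- rep(0, 20)
  vals2[3:5] <- 10
  vals2[7:9] <- 10  # two blocks split by one sub-threshold bin
  pk2 <- naive_peak_call(toy_si(layout, 100, vals2), 1, 3)
  expect_equal(nrow(pk2), 2)
  # output is disjoint and sorted
  expect_true(all(pk2$end[-nrow(pk2)] <= pk2$start[-1]))
})

test_that("peak runs do not cross chromosome boundaries", {
  layout <- toy_layout(c(chr1 = 500, chr2 = 500))
  si <- toy_si(layout, 100, rep(5, 10))
  pk <- naive_peak_call(si, 1, 2)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$chrom, c("chr1", "chr2"))
})

test_that("signal tracks round-trip through bedGraph", {
  layout <- toy_layout()
  grid <- bin_grid(layout, 1000)
  set.seed(5)
  si <- signal_track(grid, rnorm(nrow(grid)), kind = "si")
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(si, path)
  back <- read_bedgraph(path, grid, kind = "si")
  expect_equal(back$values, si$values, tolerance = 1e-5)
})
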