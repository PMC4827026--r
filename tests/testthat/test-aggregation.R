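one_group <- function(genes, label = "q0-10") {
  data.frame(gene_id = genes$gene_id, label = label,
             stringsAsFactors = FALSE)
}

test_that("a peak covering [tss, tss+100) yields indicator 1 exactly there", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 1000, 3000, "+", layout)
  peaks <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  pr <- peaks_per_gene_profile(peaks, genes, one_group(genes),
                               flank = 200, step = 50, layout = layout)
  expect_equal(pr$value[pr$offset %in% c(0, 50)], c(1, 1))
  expect_true(all(pr$value[!pr$offset %in% c(0, 50)] == 0))
  expect_true(all(pr$value >= 0 & pr$value <= 1))
})

test_that("minus-strand genes are flipped so upstream peaks map to negative offsets", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 1000, 2000, "-", layout)  # tss = 1999
  # genomically downstream of the right end = upstream in transcription order
  peaks <- data.frame(chrom = "chr1", start = 2100, end = 2200)
  pr <- peaks_per_gene_profile(peaks, genes, one_group(genes),
                               flank = 500, step = 50, layout = layout)
  hit <- pr$offset[pr$value > 0]
  expect_true(all(hit < 0))
  expect_setequal(hit, c(-150, -200))  # pos = 1999 - o in [2100, 2200)
})

test_that("the group profile is the average of per-gene indicators", {
  layout <- toy_layout()
  genes <- gene_models(paste0("g", 1:4), "chr1",
                       c(1000, 3000, 5000, 7000),
                       c(1000, 3000, 5000, 7000) + 800,
                       rep("+", 4), layout)
  # identical anchored peak for two of the four genes
  peaks <- data.frame(chrom = "chr1", start = c(1000, 3000),
                      end = c(1050, 3050))
  pr <- peaks_per_gene_profile(peaks, genes, one_group(genes),
                               flank = 100, step = 50, layout = layout)
  expect_equal(pr$value[pr$offset == 0], 0.5)
})

test_that("empty groups give a zero profile with a warning", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 1000, 2000, "+", layout)
  groups <- data.frame(gene_id = "g1",
                       label = factor("q0-10",
                                      levels = c("q0-10", "zero")))
  peaks <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  expect_warning(
    pr <- peaks_per_gene_profile(peaks, genes, groups, flank = 100,
                                 step = 50, layout = layout),
    "empty")
  expect_true(all(pr$value[pr$group == "zero"] == 0))
})

test_that("metagene body axis maps TSS to 0 and TES to 1 for any gene length", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 2000, 3000, "+", layout)
  # peak covering the first half of the gene body
  peaks <- data.frame(chrom = "chr1", start = 2000, end = 2500)
  mg <- metagene_profile(peaks, genes, one_group(genes), flank = 500,
                         n_body_bins = 10, step = 100, layout = layout)
  body <- mg[mg$segment == "body", ]
  expect_equal(body$axis, (1:10 - 0.5) / 10)
  expect_equal(body$value, as.numeric(body$axis < 0.5))
  # axis index strictly increasing across the composite axis
  expect_true(all(diff(mg$axis_index[mg$group == "q0-10"]) > 0))
})

test_that("uniform coverage gives a flat metagene profile at height 1", {
  layout <- toy_layout()
  genes <- gene_models(c("g1", "g2"), "chr1", c(2000, 6000),
                       c(3500, 8500), c("+", "-"), layout)
  peaks <- data.frame(chrom = "chr1", start = 0, end = 10000)
  mg <- metagene_profile(peaks, genes, one_group(genes), flank = 500,
                         n_body_bins = 10, step = 100, layout = layout)
  expect_true(all(mg$value == 1))
})

test_that("raw-signal TSS profile averages bin SI with strand flipping", {
  layout <- genome_layout("chr1", 20000)
  grid <- bin_grid(layout, 200)
  vals <- rep(0.5, nrow(grid))
  si_const <- signal_track(grid, vals, kind = "si")
  genes <- gene_models(c("g1", "g2"), "chr1", c(4000, 12000),
                       c(6000, 14000), c("+", "+"), layout)
  pr <- raw_signal_tss_profile(si_const, genes, one_group(genes),
                               flank = 1000)
  expect_true(all(pr$value == 0.5))

  # spikes of 2.0 and 4.0 in the TSS bins of the two genes average to 3.0
  vals2 <- rep(0, nrow(grid))
  vals2[bins <- c(4000 / 200 + 1, 12000 / 200 + 1)] <- c(2, 4)
  si_sp <- signal_track(grid, vals2, kind = "si")
  pr2 <- raw_signal_tss_profile(si_sp, genes, one_group(genes),
                                flank = 1000)
  expect_equal(pr2$value[pr2$offset == 0], 3)
  expect_true(all(pr2$value[pr2$offset != 0] == 0))
})

test_that("gene selection by a peak within +/- 1 kb honors the half-open boundary", {
  layout <- toy_layout()
  genes <- gene_models("g1", "chr1", 5000, 7000, "+", layout)  # tss = 5000
  expect_equal(select_enriched_genes(
    data.frame(chrom = "chr1", start = 5400, end = 5600), genes), "g1")
  # peak ending exactly at tss - 1000 shares no base with the window
  expect_equal(length(select_enriched_genes(
    data.frame(chrom = "chr1", start = 3800, end = 4000), genes)), 0)
  # a single overlapping bp selects
  expect_equal(select_enriched_genes(
    data.frame(chrom = "chr1", start = 3800, end = 4001), genes), "g1")
  # chromosome-spanning peak selects every gene on it
  many <- gene_models(c("a", "b"), "chr1", c(1000, 6000), c(2000, 7000),
                      c("+", "-"), layout)
  expect_setequal(select_enriched_genes(
    data.frame(chrom = "chr1", start = 0, end = 10000), many),
    c("a", "b"))
})

test_that("profiles are invariant under chromosome order relabeling", {
  layout_a <- toy_layout(c(chr1 = 10000, chr2 = 8000))
  layout_b <- toy_layout(c(chr2 = 8000, chr1 = 10000))
  genes <- gene_models(c("g1", "g2"), c("chr1", "chr2"), c(2000, 3000),
                       c(4000, 5000), c("+", "-"), layout_a)
  peaks <- data.frame(chrom = c("chr1", "chr2"), start = c(1900, 2900),
                      end = c(2100, 3100))
  pr_a <- peaks_per_gene_profile(peaks, genes, one_group(genes),
                                 flank = 500, step = 100, layout = layout_a)
  pr_b <- peaks_per_gene_profile(peaks, genes, one_group(genes),
                                 flank = 500, step = 100, layout = layout_b)
  expect_equal(pr_a, pr_b)
})
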