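test_that("make_bins tiles chromosomes with half-open 50-kb bins", {
  g <- toy_genome(c(c1 = 150000))
  b <- make_bins(g, 50000)
  expect_equal(b$start, c(0, 50000, 100000))
  expect_equal(b$end, c(50000, 100000, 150000))

  g2 <- toy_genome(c(c1 = 120000))
  b2 <- make_bins(g2, 50000)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$end[3] - b2$start[3], 20000)

  # hg19 chr21: number of bins computed independently from the length
  hg <- hg19_genome()
  len21 <- hg$chromosomes[["chr21"]]
  b21 <- make_bins(toy_genome(c(chr21 = len21)), 50000)
  expect_equal(nrow(b21), ceiling(len21 / 50000))
  expect_equal(nrow(b21), 963)

  expect_error(genome_build("empty", numeric()), "no chromosomes")
  expect_error(make_bins(hg, 0), "bin_size")
})

test_that("bin counting uses 5' start positions and conserves reads", {
  g <- toy_genome(c(c1 = 150000))
  b <- make_bins(g, 50000)
  pos <- data.frame(chrom = "c1", pos = c(0, 49999, 50000))
  p <- bin_counts_from_positions(pos, b)
  expect_equal(p$counts, c(2, 1, 0))

  empty <- bin_counts_from_positions(data.frame(chrom = character(),
                                                pos = numeric()), b)
  expect_equal(empty$counts, c(0, 0, 0))

  expect_error(
    bin_counts_from_positions(data.frame(chrom = "c1", pos = -1), b),
    "negative")

  # conservation incl. dropped reads on unknown chromosomes
  set.seed(7)
  pos <- data.frame(chrom = sample(c("c1", "cUnknown"), 500, replace = TRUE),
                    pos = sample(0:149999, 500, replace = TRUE))
  p <- bin_counts_from_positions(pos, b)
  expect_equal(sum(p$counts) + p$n_dropped, 500)
  # order independence
  p2 <- bin_counts_from_positions(pos[sample(nrow(pos)), ], b)
  expect_identical(p$counts, p2$counts)

  # uniform positions fall in each bin within binomial 99.9% bounds
  set.seed(11)
  pos <- data.frame(chrom = "c1", pos = floor(runif(10000, 0, 150000)))
  p <- bin_counts_from_positions(pos, b)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 10000, 1 / 3)
  expect_true(all(p$counts >= bounds[1] & p$counts <= bounds[2]))
})

test_that("bin-count tables round-trip through the TSV dialect", {
  g <- toy_genome(c(c1 = 150000))
  grid <- make_bins(g, 50000)
  grid$gc <- c(0.41, 0.52, 0.47)
  prof <- count_profile("s1", c(10, 20, 30), grid, batch_id = "fcA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(path, grid, prof)
  back <- read_bin_counts(path)
  expect_equal(back$profile$counts, prof$counts)
  expect_equal(back$profile$sample_id, "s1")
  expect_equal(back$profile$batch_id, "fcA")
  expect_equal(back$grid$gc, grid$gc)

  # mismatched panel grids are rejected naming the first bad bin
  g2 <- make_bins(toy_genome(c(c1 = 200000)), 50000)
  expect_error(check_same_grid(list(grid, g2)), "bin count")
})

test_that("SEG output round-trips and read_positions handles BED and SAM", {
  calls <- data.frame(sample = "s", chrom = "c1", start = 0, end = 100000,
                      n_bins = 2L, log2_ratio = 0.07, segment_fraction = 0.5,
                      z_cbs = 4.2, lor = 1.1, bcl = 1, call = "gain",
                      size_mb = 0.1, label = "1p11-1q11 gain")
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(path, calls)
  back <- read_seg(path)
  expect_equal(back$z_cbs, 4.2)
  expect_equal(back$label, "1p11-1q11 gain")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t27", "c1\t50010\t50037"), bed)
  expect_equal(read_positions(bed)$pos, c(0, 50010))

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "r1\t0\tc1\t1\t42\t27M\t*\t0\t0\tACGT\t####",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t####",
               "r3\t16\tc1\t50001\t42\t27M\t*\t0\t0\tACGT\t####"), sam)
  p <- read_positions(sam)
  expect_equal(p$chrom, c("c1", "c1"))
  expect_equal(p$pos, c(0, 50000))  # SAM POS is 1-based
})

test_that("cohort reader validates stages and cancer types", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "sample_id\tcancer_type\tfigo_stage\tpfs_months\tpfs_event\tos_months\tos_event"
  writeLines(c(hdr,
               "a\tovarian\tIIIB\t10\t1\t20\t0",
               "b\tendometrial\tIA\t5\t0\t9\t0"), path)
  coh <- read_cohort(path)
  expect_equal(coh$figo_major, c("III", "I"))
  expect_equal(coh$stage_group, c("advanced", "early"))

  writeLines(c(hdr, "a\tovarian\tV\t10\t1\t20\t0"), path)
  expect_error(read_cohort(path), "row")
  writeLines(c(hdr, "a\tprostate\tI\t10\t1\t20\t0"), path)
  expect_error(read_cohort(path), "cancer_type")
})

test_that("cytoband reading and interval labelling follow UCSC conventions", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t2300000\tp36.33\tgneg",
               "chr1\t2300000\t5400000\tp36.32\tgpos25"), path)
  cb <- read_cytobands(path)
  expect_equal(cb$start[1], 0)
  expect_equal(cb$end[1], 2300000)
  expect_equal(cb$band[1], "p36.33")
  expect_equal(cb$stain[2], "gpos25")

  toy <- cytoband_map(data.frame(chrom = "chr11",
                                 start = c(0, 100), end = c(100, 200),
                                 band = c("p1", "q1")))
  expect_equal(cytoband_label(toy, "chr11", 10, 90, "loss"), "11p1 loss")
  expect_equal(cytoband_label(toy, "chr11", 50, 150, "gain"), "11p1-11q1 gain")
  expect_equal(cytoband_label(toy, "chr11", 0, 200, "gain"), "11p1-11q1 gain")
  expect_error(cytoband_label(toy, "chr11", 300, 400, "gain"), "outside")

  # idempotence: relabelling the interval reconstructed from the label's
  # band span returns the same label
  lab <- cytoband_label(toy, "chr11", 50, 150, "gain")
  expect_equal(cytoband_label(toy, "chr11", 0, 200, "gain"), lab)
})

test_that("synthetic cytobands are contiguous and labelable", {
  g <- toy_genome(c(chr5 = 60e6))
  cb <- synthetic_cytobands(g)
  expect_s3_class(cb, "cytoband_map")
  expect_equal(min(cb$start), 0)
  expect_equal(max(cb$end), 60e6)
  lab <- cytoband_label(cb, "chr5", 1e6, 55e6, "loss")
  expect_match(lab, "^5p[0-9]+-5q[0-9]+ loss$")
})
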