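test_that("narrowPeak fields map to peaks, with the -1 summit defaulting to the midpoint", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t5.0\t4.0\t3.0\t50",
               "chr1\t300\t400\tp2\t0\t.\t7.5\t4.0\t3.0\t-1"),
             np)
  ps <- read_peaks(np, "narrowPeak", genome = toy_genome())
  # BED [100,200) -> 1-based [101,200]; summit offset 50 -> absolute 0-based 150
  expect_equal(BiocGenerics::start(ps), c(101L, 301L))
  expect_equal(BiocGenerics::end(ps), c(200L, 400L))
  expect_equal(ps$summit, c(151L, 351L))   # -1 maps to the midpoint
  expect_equal(ps$score, c(5.0, 7.5))      # signalValue column
  expect_equal(ps$name, c("p1", "p2"))
})

test_that("malformed or invalid peak lines raise errors naming the line", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t5\t4\t3\t50",
               "chr1\t100\toops\tp2\t0\t.\t5\t4\t3\t50"), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  writeLines(c("chr1\t200\t100\tp1\t0\t.\t5\t4\t3\t50"), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 1")
  writeLines("chr1\t100\t200\tp1\t0\t.\t5\t4\t3\t50", f)
  expect_error(read_peaks(f, "narrowPeak", genome = genome_model(c(chr1 = 150))),
               "bounds")
})

test_that("BED round-trips preserve coordinates, names, scores and summits exactly", {
  g <- toy_genome()
  ps <- random_peaks(40, g, seed = 7)
  ps$name <- sprintf("pk%02d", seq_along(ps))
  f <- tempfile(fileext = ".bed")
  write_peaks(ps, f)
  back <- read_peaks(f, "bed", genome = g)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(ps))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(ps))
  expect_equal(back$summit, ps$summit)
  expect_equal(back$name, ps$name)
  expect_equal(back$score, ps$score)
  # and the file itself is stable under a second round trip
  f2 <- tempfile(fileext = ".bed")
  write_peaks(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("reproducible peak filtering keeps rep1 peaks overlapped by rep2", {
  g <- toy_genome()
  r1 <- make_peaks("chr1", c(100, 500), c(200, 600), genome = g)
  r2 <- make_peaks("chr1", 150, 300, genome = g)
  kept <- reproducible_peaks(r1, r2)
  expect_equal(BiocGenerics::start(kept), 101L)
  # half-open intervals that merely touch do not overlap
  r2b <- make_peaks("chr1", 200, 300, genome = g)
  expect_length(reproducible_peaks(make_peaks("chr1", 100, 200, genome = g), r2b), 0)
  # identity and subset properties on random sets
  a <- random_peaks(60, g, seed = 11)
  b <- random_peaks(60, g, seed = 12)
  expect_identical(reproducible_peaks(a, a), a)
  kept2 <- reproducible_peaks(a, b)
  expect_true(all(kept2$name %in% a$name))
  expect_equal(sort(kept2$name), sort(a$name[oracle_overlaps_any(a, b)]))
  expect_length(reproducible_peaks(a[0], b), 0)
})

test_that("summit windows are centered, clipped and validated", {
  g <- toy_genome()
  pk <- make_peaks("chr1", 900, 1100, summit_off = 100, genome = g)
  w <- summit_window(pk, 100)
  expect_equal(BiocGenerics::start(w), 951L)  # 0-based [950,1050)
  expect_equal(BiocGenerics::end(w), 1050L)
  # clipping at the chromosome start
  pk2 <- make_peaks("chr1", 0, 100, summit_off = 30, genome = g)
  w2 <- summit_window(pk2, 100)
  expect_equal(c(BiocGenerics::start(w2), BiocGenerics::end(w2)), c(1L, 80L))
  # minimal window still contains the summit
  w3 <- summit_window(pk, 2)
  expect_true(BiocGenerics::start(w3) <= pk$summit && pk$summit <= BiocGenerics::end(w3))
  expect_equal(BiocGenerics::width(w3), 2L)
  expect_error(summit_window(pk, 99), "even")
})

test_that("promoter windows are symmetric around each TSS and clipped", {
  g <- toy_genome()
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 10001, 201), c(15000, 15000, 5000)),
    strand = c("+", "+", "+"),
    seqinfo = g)
  genes$gene_id <- c("g1", "g1", "g2")
  genes$tx_id <- c("g1_t1", "g1_t2", "g2_t1")
  pr <- promoter_of(genes, 500)
  expect_length(pr, 3)  # one window per TSS
  expect_equal(BiocGenerics::start(pr)[1], 9501L)   # 0-based [9500,10500)
  expect_equal(BiocGenerics::end(pr)[1], 10500L)
  expect_equal(c(BiocGenerics::start(pr)[3], BiocGenerics::end(pr)[3]), c(1L, 700L))
  # minus-strand TSS sits at the transcript end, same extent
  mgene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 30000),
                                  strand = "-", seqinfo = g)
  mgene$gene_id <- "g3"; mgene$tx_id <- "g3_t1"
  pm <- promoter_of(mgene, 500)
  expect_equal(c(BiocGenerics::start(pm), BiocGenerics::end(pm)), c(29500L, 30499L))
})

test_that("nearest-site distance is edge-based, zero inside, Inf off-chromosome", {
  g <- toy_genome()
  sites <- make_peaks("chr1", c(1500, 5000), c(1600, 5100), genome = g)
  pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1001, 1551), width = 1))
  expect_equal(nearest_site_distance(pos, sites), c(500, 0))
  pos2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(10, width = 1))
  expect_equal(nearest_site_distance(pos2, sites), Inf)
  expect_equal(nearest_site_distance(pos, sites[0]), c(Inf, Inf))
})

test_that("nearest-site distance matches a brute-force linear scan on random instances", {
  g <- toy_genome()
  for (seed in 1:3) {
    sites <- random_peaks(200, g, seed = seed)
    qry <- withr::with_seed(seed + 100, GenomicRanges::GRanges(
      sample(c("chr1", "chr2"), 100, replace = TRUE),
      IRanges::IRanges(sample.int(50000, 100), width = 1)))
    got <- nearest_site_distance(qry, sites)
    want <- oracle_nearest_distance(as.character(GenomeInfoDb::seqnames(qry)),
                                    BiocGenerics::start(qry), sites)
    expect_equal(got, want)
  }
})

test_that("overlap fraction handles identity, disjoint and partial cases and grows with b", {
  g <- toy_genome()
  a <- make_peaks("chr1", c(0, 20), c(10, 30), genome = g)
  b <- make_peaks("chr1", 5, 8, genome = g)
  expect_equal(overlap_fraction(a, a), 1.0)
  expect_equal(overlap_fraction(a, make_peaks("chr2", 0, 10, genome = g)), 0.0)
  expect_equal(overlap_fraction(a, b), 0.5)
  expect_error(overlap_fraction(a[0], b), "empty")
  # monotone non-decreasing as b grows
  big <- random_peaks(80, g, seed = 3)
  fr <- vapply(seq(10, 80, 10), function(k) overlap_fraction(a, big[1:k]), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("gene models round-trip through GTF", {
  g <- toy_genome()
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1000, 1200, 500), c(9000, 9000, 4000)),
    strand = c("+", "+", "-"), seqinfo = g)
  genes$gene_id <- c("gA", "gA", "gB")
  genes$tx_id <- c("gA_t1", "gA_t2", "gB_t1")
  f <- tempfile(fileext = ".gtf")
  write_gene_models(genes, f)
  back <- read_gene_models(f, genome = g)
  back <- back[order(back$tx_id)]
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(genes))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(genes))
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(as.character(BiocGenerics::strand(back)),
               as.character(BiocGenerics::strand(genes)))
})
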