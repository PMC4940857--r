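tx <- function(chrom, start, end, gene, strand = "+", genome = toy_genome()) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, seqinfo = genome)
  gr$gene_id <- gene
  gr$tx_id <- paste0(gene, "_t", seq_along(gr))
  gr
}

test_that("distance CDFs count genes within each cutoff, Inf genes in the denominator", {
  g <- toy_genome()
  genes <- c(tx("chr1", 2001, 6000, "gA"),     # TSS 2001, site at distance 0
             tx("chr1", 30001, 35000, "gB"),   # distance 500
             tx("chr2", 10001, 15000, "gC"))   # no site on chr2 -> Inf
  sites <- make_peaks("chr1", c(1900, 30500), c(2100, 30600), genome = g)
  cdf <- distance_cdf(genes, sites, cutoffs = c(100, 1000, 10000))
  expect_equal(cdf$fraction, c(1 / 3, 2 / 3, 2 / 3))
  expect_equal(cdf$n, 3)
  # sites covering every TSS -> all fractions 1
  all1 <- distance_cdf(genes[1], sites, cutoffs = c(10, 100))
  expect_equal(all1$fraction, c(1, 1))
  # empty site set -> all fractions 0 (everything at Inf)
  expect_equal(background_cdf(genes, sites[0])$fraction,
               rep(0, length(default_distance_cutoffs())))
  expect_error(distance_cdf(genes[0], sites), "empty")
  expect_error(distance_cdf(genes, sites, cutoffs = c(5, 3)), "ascending")
})

test_that("distance CDFs are non-decreasing and match a per-gene linear scan", {
  g <- toy_genome()
  withr::with_seed(71, {
    genes <- suppressWarnings(do.call(c, lapply(1:30, function(i) {
      chrom <- sample(c("chr1", "chr2"), 1)
      st <- sample.int(40000, 1)
      tx(chrom, st, st + 2000, sprintf("g%02d", i),
         strand = sample(c("+", "-"), 1), genome = g)
    })))
  })
  sites <- random_peaks(25, g, seed = 72)
  cdf <- distance_cdf(genes, sites, cutoffs = c(100, 1000, 5000, 20000, 100000))
  expect_true(all(diff(cdf$fraction) >= 0))
  expect_true(all(cdf$fraction >= 0 & cdf$fraction <= 1))
  tssg <- tss_of(genes)
  d_or <- oracle_nearest_distance(as.character(GenomeInfoDb::seqnames(tssg)),
                                  BiocGenerics::start(tssg), sites)
  dmin <- tapply(d_or, tssg$gene_id, min)
  expect_equal(unname(cdf$fraction),
               vapply(cdf$cutoffs, function(cc) mean(dmin <= cc), 0))
})

test_that("CDF enrichment is the signed max gap and mean area difference", {
  g <- toy_genome()
  genes <- tx("chr1", 2001, 6000, "gA")
  sites <- make_peaks("chr1", 1900, 2100, genome = g)
  cdf <- distance_cdf(genes, sites, cutoffs = c(10, 100))
  expect_equal(cdf_enrichment(cdf, cdf), list(gap = 0, area = 0))
  lifted <- cdf
  lifted$fraction <- pmin(cdf$fraction + 0.2, 1)
  shifted <- cdf; shifted$fraction <- cdf$fraction - c(0.2, 0.2)
  e <- cdf_enrichment(cdf, shifted)
  expect_equal(e$gap, 0.2)
  expect_equal(e$area, 0.2)
  mixed <- cdf; mixed$fraction <- cdf$fraction + c(-0.1, 0.3)
  expect_equal(cdf_enrichment(mixed, cdf), list(gap = 0.3, area = 0.1))
  bad <- distance_cdf(genes, sites, cutoffs = c(10, 200))
  expect_error(cdf_enrichment(cdf, bad), "cutoff")
})

test_that("co-occupancy stratification is a true partition matching all-pairs overlap", {
  g <- toy_genome()
  sites <- random_peaks(50, g, seed = 81)
  mark <- random_peaks(30, g, seed = 82)
  parts <- stratify_by_cooccupancy(sites, mark)
  expect_equal(length(parts$with_mark) + length(parts$without_mark), length(sites))
  expect_length(intersect(parts$with_mark$name, parts$without_mark$name), 0)
  expect_equal(sort(parts$with_mark$name),
               sort(sites$name[oracle_overlaps_any(sites, mark)]))
  all_in <- stratify_by_cooccupancy(sites, sites)
  expect_length(all_in$without_mark, 0)
  none <- stratify_by_cooccupancy(sites, mark[0])
  expect_length(none$with_mark, 0)
})

test_that("occupancy-expression correlation matches the rank oracle and a null stays small", {
  rpm <- stats::setNames(c(1, 3, 3, 7, 9, 12, 15, 2, 5, 6, 8, 11),
                         paste0("g", 1:12))
  expr <- rpm^2  # monotone transform
  expect_equal(occupancy_expression_correlation(rpm, expr), 1.0)
  withr::with_seed(91, {
    e2 <- stats::setNames(sample(c(1, 2, 2, 3, 5, 8, 8, 9, 10, 4, 6, 7)),
                          names(rpm))
    expect_equal(occupancy_expression_correlation(rpm, e2),
                 oracle_spearman(rpm, e2[names(rpm)]), tolerance = 1e-12)
    null_rhos <- replicate(30, {
      occupancy_expression_correlation(rpm, stats::setNames(stats::rnorm(12), names(rpm)))
    })
    expect_lt(max(abs(null_rhos)), 0.95)
    expect_lt(abs(mean(null_rhos)), 0.25)
  })
  expect_error(occupancy_expression_correlation(rpm[1:5], expr), ">= 10")
})

test_that("concordance fraction follows the direction/zero rules and recovers a planted split", {
  up_set <- structure(list(direction = "up", genes = paste0("g", 1:4)),
                      class = "gene_set")
  expect_equal(concordance_fraction(up_set, stats::setNames(c(1, 2, 0.5, 3), paste0("g", 1:4))), 1)
  expect_equal(concordance_fraction(up_set, stats::setNames(rep(0, 4), paste0("g", 1:4))), 0)
  down_set <- structure(list(direction = "down", genes = paste0("g", 1:100)),
                        class = "gene_set")
  planted <- stats::setNames(c(rep(-1, 80), rep(1, 20)), paste0("g", 1:100))
  expect_equal(concordance_fraction(down_set, planted), 0.80)
  expect_error(concordance_fraction(up_set, planted[1:2]), "absent")
  all_set <- structure(list(direction = "all", genes = "g1"), class = "gene_set")
  expect_error(concordance_fraction(all_set, planted), "directional")
})

test_that("repression mechanism calls follow the promoter/body decision table", {
  calls <- classify_repression_mechanism(
    c("a", "b", "c", "d", "e"),
    promoter_ratio = c(0.8, -0.5, 0.3, 0, 1.2),
    body_ratio = c(-1.2, -0.9, 0.2, -1, 0.1))
  expect_equal(calls$mechanism,
               c("pausing_consistent", "reduced_initiation", "indeterminate",
                 "indeterminate", "indeterminate"))
  expect_error(classify_repression_mechanism("x", 1, -1, rna_direction = "up"),
               "repressed")
})

test_that("exact rank-sum p matches enumeration; approximation is close at the boundary", {
  r <- ranksum_test(1:3, 4:6)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(ranksum_test(c(5, 5, 5), c(5, 5, 5))$p, 1)
  withr::with_seed(101, {
    for (i in 1:8) {
      x <- sample(1:20, sample(3:6, 1), replace = TRUE)  # ties likely
      y <- sample(1:20, sample(3:6, 1), replace = TRUE)
      expect_equal(ranksum_test(x, y)$p, oracle_ranksum_exact(x, y),
                   tolerance = 1e-12)
    }
    # tie-free cases also agree with the classical exact distribution
    for (i in 1:4) {
      x <- sample(1:1000, 5); y <- sample(setdiff(1:1000, x), 7)
      expect_equal(ranksum_test(x, y)$p,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # n = 8 per group: normal approximation within 0.01 of the exact answer
    for (i in 1:4) {
      x <- stats::rnorm(8); y <- stats::rnorm(8, 0.5)
      exact <- ranksum_test(x, y)$p
      approx <- ranksum_test(x, y, exact_max = 0)$p
      expect_lt(abs(exact - approx), 0.01)
    }
  })
})

test_that("the stratified ratio test separates planted near/far location shifts", {
  withr::with_seed(111, {
    near <- stats::setNames(stats::rnorm(50, -1, 0.5), paste0("n", 1:50))
    far <- stats::setNames(stats::rnorm(50, 0, 0.5), paste0("f", 1:50))
    res <- stratified_ratio_test(c(near, far), names(near), names(far))
    expect_lt(res$p, 0.001)
    expect_equal(res$method, "normal_tie_corrected")
  })
  expect_error(stratified_ratio_test(c(a = 1, b = 2), c("a", "b"), c("a")),
               "disjoint")
  expect_error(stratified_ratio_test(c(a = 1, b = 2, c = 3), c("a", "b"), "c"),
               ">= 3")
})

test_that("distance strata exclude the intermediate band and respect strict bounds", {
  g <- toy_genome()
  genes <- c(tx("chr1", 5001, 9000, "gNear"),    # site 2 kb away
             tx("chr1", 50001, 54000, "gMid"))   # site 43 kb away
  sites <- make_peaks("chr1", 3000, 3100, genome = g)
  st <- distance_strata(genes, sites, near_max = 1e4, far_min = 1e5)
  expect_equal(st$near, "gNear")
  expect_length(st$far, 0)   # 43 kb is intermediate: excluded from both
  big <- genome_model(c(chr1 = 1e6))
  farg <- tx("chr1", 500001, 504000, "gFar", genome = big)
  sites2 <- make_peaks("chr1", 3000, 3100, genome = big)
  st2 <- distance_strata(farg, sites2)
  expect_equal(st2$far, "gFar")
})
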