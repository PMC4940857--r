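small_cfg <- function(seed = 5, n_sites = 200, ...) {
  sim_config(seed = seed, n_genes = 80, n_sites = n_sites, chrom_length = 8e5,
             n_motif_seqs = 40, n_pausing_genes = 40, ...)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg()
  g1 <- sim_genome_genes(cfg); g2 <- sim_genome_genes(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  # gene placement is independent of whether sequences are drawn
  g3 <- sim_genome_genes(cfg, sequences = FALSE)
  expect_null(g3$genome)
  expect_identical(g3$genes, g1$genes)
  o1 <- sim_occupancy(cfg, g1$seqinfo); o2 <- sim_occupancy(cfg, g1$seqinfo)
  expect_identical(o1$om$counts, o2$om$counts)
  expect_identical(o1$truth, o2$truth)
  e1 <- sim_expression(cfg, g1$genes); e2 <- sim_expression(cfg, g1$genes)
  expect_identical(e1$table, e2$table)
  p1 <- sim_pausing(cfg); p2 <- sim_pausing(cfg)
  expect_identical(p1$promoter, p2$promoter)
  # a different seed changes the draw
  expect_false(identical(sim_occupancy(small_cfg(6), g1$seqinfo)$om$counts,
                         o1$om$counts))
})

test_that("simulated genomes hold the requested genes within bounds", {
  cfg <- small_cfg(7)
  gg <- sim_genome_genes(cfg)
  expect_equal(length(unique(gg$genes$gene_id)), cfg$n_genes)
  expect_equal(sum(nchar(as.character(gg$genome))), 2 * cfg$chrom_length)
  sl <- GenomeInfoDb::seqlengths(gg$seqinfo)[
    as.character(GenomeInfoDb::seqnames(gg$genes))]
  expect_true(all(BiocGenerics::start(gg$genes) >= 1))
  expect_true(all(BiocGenerics::end(gg$genes) <= sl))
  tssg <- tss_of(gg$genes)
  expect_true(all(BiocGenerics::start(tssg) >= 1 &
                    BiocGenerics::start(tssg) <= sl))
  # gene bodies of distinct genes do not overlap
  bodies <- unlist(range(GenomicRanges::split(gg$genes, gg$genes$gene_id)))
  expect_equal(sum(GenomicRanges::countOverlaps(bodies, bodies) != 1), 0)
  expect_error(sim_genome_genes(sim_config(n_genes = 500, chrom_length = 1e6)),
               "cannot fit")
})

test_that("occupancy truth labels partition sites and the null effect collapses classes", {
  cfg <- small_cfg(9)
  gg <- sim_genome_genes(cfg, sequences = FALSE)
  occ <- sim_occupancy(cfg, gg$seqinfo)
  expect_setequal(occ$truth$site_id, occ$sites$site_id)
  expect_true(all(occ$truth$class %in% c("gained", "lost", "stable")))
  expect_equal(sum(occ$truth$class == "gained"), round(0.2 * cfg$n_sites))
  # with effect 1 the planted classes are indistinguishable in distribution:
  # late/early mean count ratios match between planted and stable sites
  cfg0 <- small_cfg(9, effect_size = 1, n_sites = 1000)
  occ0 <- sim_occupancy(cfg0, gg$seqinfo)
  tp <- occ0$om$samples$timepoint
  ratio <- rowMeans(occ0$om$counts[, tp == 48]) + 1
  ratio <- log2(ratio / (rowMeans(occ0$om$counts[, tp == 2]) + 1))
  grp <- split(ratio, occ0$truth$class)
  expect_lt(abs(mean(grp$gained) - mean(grp$stable)), 0.1)
  expect_lt(abs(mean(grp$lost) - mean(grp$stable)), 0.1)
})

test_that("motif simulation plants occurrences at the configured rate", {
  nr <- cistrodyn_pwms()$NR_DR4
  cfg0 <- small_cfg(11, motif_rate = 0)
  s0 <- sim_motif_sequences(cfg0, nr)
  expect_false(any(s0$truth$planted))
  cfg1 <- small_cfg(11, motif_rate = 1)
  s1 <- sim_motif_sequences(cfg1, nr)
  expect_true(all(s1$truth$planted))
  expect_true(all(!is.na(s1$truth$position)))
  expect_true(all(Biostrings::width(s1$seqs) == 100))
  expect_error(sim_motif_sequences(cfg1, nr, width = 10), "longer")
})

test_that("expression simulation plants proximity structure for repressed genes", {
  cfg <- small_cfg(13, proximity_fraction = 0.8)
  gg <- sim_genome_genes(cfg, sequences = FALSE)
  occ <- sim_occupancy(cfg, gg$seqinfo)
  ex <- sim_expression(cfg, gg$genes, occ$sites)
  near <- ex$truth$gene_id[ex$truth$near_site]
  expect_true(all(ex$truth$status[ex$truth$near_site] == "down"))
  # every flagged gene really has a site within 10 kb of a TSS
  gset <- gg$genes[gg$genes$gene_id %in% near]
  d <- nearest_site_distance(tss_of(gset), ex$sites)
  dmin <- tapply(d, tss_of(gset)$gene_id, min)
  expect_true(all(dmin < 1e4))
  # null genes cannot pass the default cutoffs
  nulls <- ex$table[ex$truth$status == "null", ]
  expect_true(all(abs(nulls$fold_change) < 2))
})

test_that("pausing scenario is noiseless-recoverable and fully labeled", {
  cfg <- small_cfg(15, pausing_noise_sd = 0)
  pa <- sim_pausing(cfg)
  calls <- classify_repression_mechanism(
    pa$truth$gene_id,
    log2(pa$promoter$rpm_48h / pa$promoter$rpm_0h),
    log2(pa$body$rpm_48h / pa$body$rpm_0h))
  expect_equal(calls$mechanism, pa$truth$mechanism)
  expect_identical(pa$truth$gene_id, pa$promoter$gene_id)
  expect_identical(pa$truth$gene_id, pa$body$gene_id)
})

test_that("written bundles round-trip through the package readers", {
  cfg <- small_cfg(17)
  out <- tempfile("bundle")
  objs <- sim_write_bundle(cfg, out)
  expect_true(all(file.exists(file.path(out, c(
    "genome.fa", "genome.chrom.sizes", "genes.gtf", "sites.bed",
    "occupancy_counts.tsv", "de_drugA.tsv", "truth_sites.tsv")))))
  si <- read_chrom_sizes(file.path(out, "genome.chrom.sizes"))
  expect_identical(si, objs$genome$seqinfo)
  peaks <- read_peaks(file.path(out, "sites.bed"), "bed", genome = si)
  expect_equal(BiocGenerics::start(peaks), BiocGenerics::start(objs$occupancy$sites))
  expect_equal(peaks$summit, objs$occupancy$sites$summit)
  genes <- read_gene_models(file.path(out, "genes.gtf"), genome = si)
  expect_equal(length(genes), length(objs$genome$genes))
  tab <- read_de_table(file.path(out, "de_drugA.tsv"))
  expect_equal(tab$fold_change, objs$expressionA$table$fold_change)
  fa <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  expect_equal(as.character(fa), as.character(objs$genome$genome))
})
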