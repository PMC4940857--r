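#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the study design the pipeline targets: replicate ChIP-seq occupancy at
#' an early (2 h) and late (48 h) timepoint with negative-binomial counts,
#' planted gained/lost/stable site classes with 4-fold mean shifts,
#' expression tables with |fold change| >= 4 planted responders against the
#' p < 0.01 / fold +-2 cutoffs, repressed genes preferentially given a
#' binding site within 10 kb of a TSS, and a promoter-pausing scenario
#' (promoter signal up ~2-fold, gene-body elongation mark down ~2-fold,
#' log-normal noise sd 0.2 on the log2 scale).
#'
#' @param seed master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_chrom,chrom_length genome shape (default 2 x 5 Mb).
#' @param n_genes number of genes (default 500).
#' @param n_sites binding sites per factor/timepoint (default 2000).
#' @param n_reps ChIP-seq replicates per timepoint (default 2).
#' @param timepoints occupancy timepoints in hours (default `c(2, 48)`).
#' @param nb_mean,nb_dispersion negative-binomial count model
#'   (`var = mu + dispersion * mu^2`); defaults 100 and 0.05.
#' @param site_mean_sdlog log-normal spread of per-site mean strength.
#' @param frac_gained,frac_lost planted dynamic-site fractions (rest stable).
#' @param effect_size late/early mean fold for planted dynamic sites.
#' @param site_width peak width in bp.
#' @param total_reads simulated library size per sample.
#' @param frac_up,frac_down planted responsive-gene fractions.
#' @param fc_effect minimum |linear fold change| of planted responders.
#' @param motif_rate motif insertion probability per site sequence.
#' @param n_motif_seqs sequences per motif simulation (default 200).
#' @param proximity_fraction fraction of repressed genes given a site
#'   within 10 kb of a TSS.
#' @param n_pausing_genes genes in the pausing scenario (default 200).
#' @param pausing_fraction fraction of repressed genes planted as pausing
#'   (rest as reduced initiation / transcript degradation).
#' @param prom_effect,body_effect planted log2 effects on promoter RNAP2
#'   and gene-body H3K36me3 (defaults +1 / -1).
#' @param pausing_noise_sd log2-scale noise sd in the pausing scenario.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 5e6,
                       n_genes = 500L, n_sites = 2000L, n_reps = 2L,
                       timepoints = c(2, 48), nb_mean = 100,
                       nb_dispersion = 0.05, site_mean_sdlog = 1.2,
                       frac_gained = 0.2, frac_lost = 0.2, effect_size = 4,
                       site_width = 200L, total_reads = 2e7,
                       frac_up = 0.1, frac_down = 0.1, fc_effect = 4,
                       motif_rate = 0.8, n_motif_seqs = 200L,
                       proximity_fraction = 0.8, n_pausing_genes = 200L,
                       pausing_fraction = 0.5, prom_effect = 1,
                       body_effect = -1, pausing_noise_sd = 0.2) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_gained, cfg$frac_lost, cfg$frac_up, cfg$frac_down,
          cfg$motif_rate, cfg$proximity_fraction, cfg$pausing_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_gained + cfg$frac_lost > 1) stop("gained + lost fractions > 1")
  if (cfg$frac_up + cfg$frac_down > 1) stop("up + down fractions > 1")
  if (cfg$nb_dispersion <= 0 || cfg$nb_mean <= 0) stop("NB parameters must be > 0")
  if (length(cfg$timepoints) != 2) stop("occupancy design uses 2 timepoints")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with non-overlapping gene models
#'
#' Uniform random base composition; genes of 2-20 kb laid out without
#' overlap, each with 1-3 transcripts whose TSSs fall within the first
#' 500 bp of the gene (strand random).
#'
#' @param config a [sim_config()].
#' @param sequences draw chromosome sequences (default `TRUE`); gene
#'   placement uses an independent seeded stream, so gene models are
#'   identical either way.
#' @return list: `genome` (`DNAStringSet`, `NULL` when `sequences = FALSE`),
#'   `seqinfo` (`Seqinfo`), `genes` (transcript `GRanges` with
#'   `gene_id`/`tx_id`).
#' @export
sim_genome_genes <- function(config, sequences = TRUE) {
  chroms <- paste0("chr", seq_len(config$n_chrom))
  genome <- NULL
  if (sequences) {
    genome <- withr::with_seed(derive_seed(config$seed, 11L),
      Biostrings::DNAStringSet(vapply(chroms, function(cc)
        paste(sample(BASES, config$chrom_length, replace = TRUE),
              collapse = ""), "")))
    names(genome) <- chroms
  }
  withr::with_seed(derive_seed(config$seed, 13L), {
    si <- genome_model(stats::setNames(rep(config$chrom_length, config$n_chrom),
                                       chroms))
    per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
    gl <- list()
    for (ci in seq_len(config$n_chrom)) {
      n <- per[ci]
      if (n == 0) next
      w <- sample(2000:20000, n, replace = TRUE)
      slack <- config$chrom_length - sum(w) - 2000
      if (slack <= n) stop("genes cannot fit on chromosome ", chroms[ci])
      gaps <- diff(c(0, sort(sample(slack, n))))
      starts <- 1000 + cumsum(gaps) + cumsum(c(0, utils::head(w, -1)))
      gl[[ci]] <- GenomicRanges::GRanges(
        chroms[ci], IRanges::IRanges(start = starts, width = w),
        strand = sample(c("+", "-"), n, replace = TRUE), seqinfo = si)
    }
    bodies <- suppressWarnings(do.call(c, gl))
    bodies$gene_id <- sprintf("gene_%04d", seq_along(bodies))
    ntx <- sample(1:3, length(bodies), replace = TRUE)
    tx <- rep(bodies, ntx)
    off <- unlist(lapply(ntx, function(k) c(0, sample(1:500, k - 1))))
    plus <- as.character(BiocGenerics::strand(tx)) == "+"
    newstart <- ifelse(plus, BiocGenerics::start(tx) + off, BiocGenerics::start(tx))
    newend <- ifelse(plus, BiocGenerics::end(tx), BiocGenerics::end(tx) - off)
    tx <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx),
                                 IRanges::IRanges(newstart, newend),
                                 strand = BiocGenerics::strand(tx), seqinfo = si)
    tx$gene_id <- rep(bodies$gene_id, ntx)
    tx$tx_id <- paste0(tx$gene_id, "_t", unlist(lapply(ntx, seq_len)))
    list(genome = genome, seqinfo = si, genes = tx)
  })
}

#' Simulate temporal ChIP-seq occupancy
#'
#' Per-site mean strengths are log-normal; planted gained sites have their
#' late-timepoint mean multiplied by `effect_size`, lost sites divided,
#' stable sites unchanged. Replicate counts are negative-binomial
#' (`var = mu + dispersion mu^2`). Peak calls (with summit at the site
#' center) are emitted per timepoint alongside the count matrix, sample
#' metadata, and the planted truth labels.
#'
#' @param config a [sim_config()].
#' @param seqinfo genome `Seqinfo` (e.g. from [sim_genome_genes()]).
#' @return list: `sites` (peak-set `GRanges` with `site_id`), `om`
#'   ([occupancy_matrix()]), `truth` (data frame `site_id`, `class`),
#'   `times` (per-sample hours).
#' @export
sim_occupancy <- function(config, seqinfo) {
  withr::with_seed(derive_seed(config$seed, 23L), {
    chroms <- GenomeInfoDb::seqnames(seqinfo)
    n <- config$n_sites
    chr <- sample(chroms, n, replace = TRUE)
    start <- sapply(chr, function(cc)
      sample(1000:(GenomeInfoDb::seqlengths(seqinfo)[[cc]] - 1000 - config$site_width), 1))
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = config$site_width),
                                 seqinfo = seqinfo)
    gr <- BiocGenerics::sort(gr)
    site_id <- sprintf("site_%05d", seq_len(n))
    mu0 <- stats::rlnorm(n, log(config$nb_mean), config$site_mean_sdlog)
    n_g <- round(config$frac_gained * n); n_l <- round(config$frac_lost * n)
    class <- sample(rep(c("gained", "lost", "stable"),
                        c(n_g, n_l, n - n_g - n_l)))
    mult <- ifelse(class == "gained", config$effect_size,
                   ifelse(class == "lost", 1 / config$effect_size, 1))
    size <- 1 / config$nb_dispersion
    samples <- expand.grid(replicate = paste0("r", seq_len(config$n_reps)),
                           timepoint = config$timepoints,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("t%g_%s", samples$timepoint, samples$replicate)
    samples$factor <- "NR"
    samples$total_reads <- config$total_reads
    counts <- sapply(seq_len(nrow(samples)), function(j) {
      late <- samples$timepoint[j] == max(config$timepoints)
      mu <- if (late) mu0 * mult else mu0
      stats::rnbinom(n, mu = mu, size = size)
    })
    rownames(counts) <- site_id
    colnames(counts) <- samples$sample_id
    peaks <- peak_set(gr, summit = BiocGenerics::start(gr) + config$site_width %/% 2,
                      score = mu0, factor = "NR",
                      timepoint = min(config$timepoints), genome = seqinfo)
    peaks$name <- site_id
    peaks$site_id <- site_id
    list(sites = peaks,
         om = occupancy_matrix(counts, samples[c("sample_id", "factor",
                                                 "timepoint", "replicate",
                                                 "total_reads")]),
         truth = data.frame(site_id = site_id, class = class,
                            stringsAsFactors = FALSE),
         times = samples$timepoint)
  })
}

#' Simulate site sequences with planted motif occurrences
#'
#' Each site sequence is uniform random DNA of `width` bp; with probability
#' `motif_rate` a motif occurrence (sampled column-wise from the PWM) is
#' planted at a random position, on a random strand.
#'
#' @param config a [sim_config()].
#' @param motif a [pwm()].
#' @param width sequence width in bp (default 100, the summit-window width).
#' @return list: `seqs` (`DNAStringSet`), `truth` (data frame `seq_id`,
#'   `planted`, `position`).
#' @export
sim_motif_sequences <- function(config, motif, width = 100L) {
  if (motif$length > width) stop("motif longer than sequence")
  withr::with_seed(derive_seed(config$seed, 37L), {
    n <- config$n_motif_seqs
    seqs <- character(n)
    planted <- stats::runif(n) < config$motif_rate
    pos <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      s <- sample(BASES, width, replace = TRUE)
      if (planted[i]) {
        ins <- vapply(seq_len(motif$length), function(j)
          sample(BASES, 1, prob = motif$prob[, j]), "")
        if (stats::runif(1) < 0.5) {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          ins <- unname(rev(comp[ins]))
        }
        p <- sample(width - motif$length + 1, 1)
        s[p:(p + motif$length - 1)] <- ins
        pos[i] <- p
      }
      seqs[i] <- paste(s, collapse = "")
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("seq_%04d", seq_len(n))
    list(seqs = out,
         truth = data.frame(seq_id = names(out), planted = planted,
                            position = pos, stringsAsFactors = FALSE))
  })
}

#' Simulate a differential-expression table with binding proximity structure
#'
#' Planted up/down genes receive signed linear fold changes of at least
#' `fc_effect` and small adjusted p-values; null genes get |fold| < 2 and
#' uniform p. A configured fraction of the down-regulated genes receives a
#' binding site planted within 10 kb of one of its TSSs (appended to
#' `sites`), emulating repression near late binding events.
#'
#' @param config a [sim_config()].
#' @param genes transcript `GRanges` from [sim_genome_genes()].
#' @param sites peak-set `GRanges` to augment (may be empty).
#' @param share_truth optional truth table of a first treatment; planted
#'   labels are reused for `share_frac` of genes to create a correlated
#'   second treatment.
#' @param share_frac fraction of planted labels shared (default 0.6).
#' @param salt integer mixed into the seed so several tables can be drawn
#'   from one config.
#' @return list: `table` (DE data frame), `truth` (data frame `gene_id`,
#'   `status`, `near_site`), `sites` (augmented peak set).
#' @export
sim_expression <- function(config, genes, sites = NULL, share_truth = NULL,
                           share_frac = 0.6, salt = 0L) {
  withr::with_seed(derive_seed(config$seed, 53L + salt), {
    gid <- unique(genes$gene_id)
    n <- length(gid)
    n_up <- round(config$frac_up * n); n_dn <- round(config$frac_down * n)
    status <- sample(rep(c("up", "down", "null"), c(n_up, n_dn, n - n_up - n_dn)))
    names(status) <- gid
    if (!is.null(share_truth)) {
      keep <- stats::runif(n) < share_frac
      status[share_truth$gene_id[keep]] <- share_truth$status[keep]
    }
    fc <- ifelse(status == "null",
                 sample(c(-1, 1), n, replace = TRUE) * 2^stats::runif(n, 0, 0.8),
                 ifelse(status == "up", 1, -1) *
                   config$fc_effect * 2^stats::runif(n, 0, 1))
    padj <- ifelse(status == "null", stats::runif(n),
                   10^stats::runif(n, -8, log10(0.005)))
    rpkm <- stats::rlnorm(n, log(20), 1)
    near <- rep(FALSE, n); names(near) <- gid
    dn <- gid[status == "down"]
    plant <- dn[stats::runif(length(dn)) < config$proximity_fraction]
    near[plant] <- TRUE
    if (length(plant)) {
      tss <- tss_of(genes[genes$gene_id %in% plant])
      tss <- tss[!duplicated(tss$gene_id)]
      d <- sample(500:9000, length(tss), replace = TRUE) *
        sample(c(-1, 1), length(tss), replace = TRUE)
      st <- pmax(BiocGenerics::start(tss) + d - config$site_width %/% 2, 1)
      sl <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(genes))
      lim <- sl[as.character(GenomeInfoDb::seqnames(tss))] - config$site_width
      st <- pmin(st, lim)
      new_gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
                                       IRanges::IRanges(st, width = config$site_width),
                                       seqinfo = GenomeInfoDb::seqinfo(genes))
      new <- peak_set(new_gr,
                      summit = BiocGenerics::start(new_gr) + config$site_width %/% 2,
                      score = rep(1, length(new_gr)))
      new$name <- paste0("prox_", seq_along(new))
      new$site_id <- new$name
      sites <- if (is.null(sites) || length(sites) == 0) new else {
        m <- S4Vectors::metadata(sites)
        out <- c(sites, new)
        S4Vectors::metadata(out) <- m
        out
      }
    }
    list(table = data.frame(gene_id = gid, fold_change = fc, padj = padj,
                            rpkm = rpkm, stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gid, status = unname(status),
                            near_site = unname(near), stringsAsFactors = FALSE),
         sites = sites)
  })
}

#' Simulate the promoter-pausing vs transcript-degradation scenario
#'
#' All genes are RNA-down. Pausing-planted genes gain promoter RNAP2
#' occupancy at 48 h while their gene-body H3K36me3 falls; degradation /
#' reduced-initiation genes lose both. Baselines are log-normal RPM and
#' effects act multiplicatively on the log2 scale with Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list: `promoter` (data frame `gene_id`, `rpm_0h`, `rpm_48h`),
#'   `body` (same shape for H3K36me3), `direction` (all "down"),
#'   `truth` (data frame `gene_id`, `mechanism`).
#' @export
sim_pausing <- function(config) {
  withr::with_seed(derive_seed(config$seed, 71L), {
    n <- config$n_pausing_genes
    gid <- sprintf("pgene_%04d", seq_len(n))
    n_p <- round(config$pausing_fraction * n)
    mech <- sample(rep(c("pausing_consistent", "reduced_initiation"),
                       c(n_p, n - n_p)))
    prom0 <- stats::rlnorm(n, log(30), 0.5)
    body0 <- stats::rlnorm(n, log(30), 0.5)
    prom_eff <- ifelse(mech == "pausing_consistent", config$prom_effect,
                       -config$prom_effect)
    prom48 <- prom0 * 2^(prom_eff + stats::rnorm(n, 0, config$pausing_noise_sd))
    body48 <- body0 * 2^(config$body_effect + stats::rnorm(n, 0, config$pausing_noise_sd))
    list(promoter = data.frame(gene_id = gid, rpm_0h = prom0, rpm_48h = prom48,
                               stringsAsFactors = FALSE),
         body = data.frame(gene_id = gid, rpm_0h = body0, rpm_48h = body48,
                           stringsAsFactors = FALSE),
         direction = stats::setNames(rep("down", n), gid),
         truth = data.frame(gene_id = gid, mechanism = mech,
                            stringsAsFactors = FALSE))
  })
}

#' Write a full synthetic data bundle to disk
#'
#' Emits FASTA, chrom.sizes, GTF gene models, per-timepoint narrowPeak-style
#' BED peaks, the count matrix, DE tables and truth tables; TSV outputs
#' carry the seed in a comment header.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
sim_write_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gg <- sim_genome_genes(config)
  occ <- sim_occupancy(config, gg$seqinfo)
  expA <- sim_expression(config, gg$genes, occ$sites, salt = 0L)
  expB <- sim_expression(config, gg$genes, occ$sites, share_truth = expA$truth,
                         salt = 1000L)
  paus <- sim_pausing(config)
  seed_hdr <- paste0("seed=", config$seed)
  Biostrings::writeXStringSet(gg$genome, file.path(outdir, "genome.fa"))
  write_chrom_sizes(gg$seqinfo, file.path(outdir, "genome.chrom.sizes"))
  write_gene_models(gg$genes, file.path(outdir, "genes.gtf"))
  write_peaks(occ$sites, file.path(outdir, "sites.bed"))
  cm <- data.frame(site_id = rownames(occ$om$counts), occ$om$counts,
                   check.names = FALSE)
  write_tsv0(cm, file.path(outdir, "occupancy_counts.tsv"), seed_hdr)
  write_tsv0(occ$om$samples, file.path(outdir, "samples.tsv"), seed_hdr)
  write_tsv0(occ$truth, file.path(outdir, "truth_sites.tsv"), seed_hdr)
  write_tsv0(expA$table, file.path(outdir, "de_drugA.tsv"), seed_hdr)
  write_tsv0(expB$table, file.path(outdir, "de_drugB.tsv"), seed_hdr)
  write_tsv0(expA$truth, file.path(outdir, "truth_genes_drugA.tsv"), seed_hdr)
  write_tsv0(expB$truth, file.path(outdir, "truth_genes_drugB.tsv"), seed_hdr)
  write_tsv0(paus$promoter, file.path(outdir, "pausing_promoter.tsv"), seed_hdr)
  write_tsv0(paus$body, file.path(outdir, "pausing_body.tsv"), seed_hdr)
  write_tsv0(paus$truth, file.path(outdir, "truth_pausing.tsv"), seed_hdr)
  invisible(list(genome = gg, occupancy = occ, expressionA = expA,
                 expressionB = expB, pausing = paus))
}
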