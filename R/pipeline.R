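#' Analysis configuration
#'
#' Every analysis constant of the pipeline, defaulting to the published
#' conventions: 100-bp summit windows, 500-bp promoter flanks, DE cutoffs
#' adjusted p < 0.01 with fold +-2 (and a +-1.5 companion), top 50% of
#' p-ranked dynamic sites for motif work, top 500 sites by score, near/far
#' distance strata at 10 kb / 100 kb, log2 ratios with RPM pseudocount 1,
#' alpha 0.05, 10 scrambles for the motif null.
#'
#' @param summit_width summit window width in bp.
#' @param promoter_flank promoter half-width in bp.
#' @param p_cut adjusted-p cutoff for responsiveness.
#' @param fc_cuts linear fold-change cutoffs reported side by side.
#' @param top_fraction fraction of p-ranked dynamic sites kept.
#' @param top_n_sites score-ranked site count for motif analysis.
#' @param near_max,far_min distance strata bounds in bp.
#' @param pseudocount RPM pseudocount for log2 ratios.
#' @param alpha trend-classification significance level.
#' @param n_scrambles scrambles for the motif null.
#' @param seed master seed.
#' @param cutoffs distance-CDF grid.
#' @param inputs optional named list of input file paths (validated before
#'   any stage runs; see [run_pipeline()]).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(summit_width = 100L, promoter_flank = 500L,
                            p_cut = 0.01, fc_cuts = c(2, 1.5),
                            top_fraction = 0.5, top_n_sites = 500L,
                            near_max = 1e4, far_min = 1e5, pseudocount = 1,
                            alpha = 0.05, n_scrambles = 10L, seed = 1L,
                            cutoffs = default_distance_cutoffs(),
                            inputs = NULL) {
  cfg <- as.list(environment())
  if (cfg$summit_width %% 2 != 0) stop("summit_width must be even")
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  class(cfg) <- "analysis_config"
  cfg
}

write_config <- function(cfg, path) {
  flat <- cfg[!vapply(cfg, is.null, TRUE)]
  flat <- flat[!names(flat) %in% "inputs"]
  lines <- vapply(names(flat), function(k)
    paste0(k, " = ", paste(flat[[k]], collapse = ",")), "")
  writeLines(c(paste0("# seed=", cfg$seed), lines), path)
  invisible(path)
}

#' Read a plain key=value configuration file
#'
#' Values are comma-split and converted to numeric where possible; lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  stats::setNames(out, vapply(kv, `[`, "", 1))
}

.stage <- function(name, msg) message(sprintf("[%s] %s", name, msg))

#' Run the integrated temporal-cistrome analysis end to end
#'
#' Executes simulate -> quantify -> dynamics -> motif -> concordance ->
#' integrate on a synthetic data bundle and writes every stage table plus a
#' run manifest to `outdir`. Runs are pure functions of
#' (`sim_cfg`, `cfg`): the same configuration and seed give byte-identical
#' outputs. When `cfg$inputs` names file paths (elements `de_a`, `de_b` for
#' the two treatment DE tables; `peaks` for a binding-site BED/narrowPeak;
#' `genes` for a GTF), those files replace the corresponding simulated
#' inputs; all paths are checked before any stage runs and a missing one
#' aborts with its name.
#'
#' @param sim_cfg a [sim_config()] for the synthetic inputs.
#' @param cfg an [analysis_config()].
#' @param outdir output directory.
#' @param motif a [pwm()] for the motif stage; default the bundled
#'   nuclear-receptor direct-repeat motif (see [cistrodyn_pwms()]).
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), cfg = analysis_config(),
                         outdir, motif = NULL) {
  inp <- cfg$inputs
  if (!is.null(inp)) {
    paths <- unlist(inp)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("missing input path(s): ", paste(names(absent), "=", absent,
                                            collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(motif)) motif <- cistrodyn_pwms()[["NR_DR4"]]
  seed_hdr <- paste0("seed=", sim_cfg$seed)

  .stage("simulate", "generating genome, cistrome, expression and pausing data")
  gg <- sim_genome_genes(sim_cfg)
  if (!is.null(inp$genes)) gg$genes <- read_gene_models(inp$genes, gg$seqinfo)
  occ <- sim_occupancy(sim_cfg, gg$seqinfo)
  sites <- if (!is.null(inp$peaks))
    read_peaks(inp$peaks, format = "bed", genome = gg$seqinfo) else occ$sites
  expA <- sim_expression(sim_cfg, gg$genes, sites, salt = 0L)
  expB <- sim_expression(sim_cfg, gg$genes, sites, share_truth = expA$truth,
                         salt = 1000L)
  tabA <- if (!is.null(inp$de_a)) read_de_table(inp$de_a) else expA$table
  tabB <- if (!is.null(inp$de_b)) read_de_table(inp$de_b) else expB$table
  paus <- sim_pausing(sim_cfg)

  .stage("quantify", sprintf("%d sites x %d samples", nrow(occ$om$counts),
                             ncol(occ$om$counts)))
  om <- occ$om
  rpm_out <- data.frame(site_id = rownames(om$rpm), om$rpm, check.names = FALSE)
  write_tsv0(rpm_out, file.path(outdir, "occupancy_rpm.tsv"), seed_hdr)
  reps <- split(om$samples$sample_id, om$samples$timepoint)
  conc <- data.frame(
    timepoint = as.numeric(names(reps)),
    rho = vapply(reps, function(s) replicate_concordance(om, s[1], s[2]), 0),
    row.names = NULL)
  write_tsv0(conc, file.path(outdir, "replicate_concordance.tsv"), seed_hdr)
  tp <- sort(unique(om$samples$timepoint))
  mean_rpm <- vapply(tp, function(t)
    rowMeans(om$rpm[, om$samples$sample_id[om$samples$timepoint == t], drop = FALSE]),
    numeric(nrow(om$rpm)))
  ratios <- depth_ratio(mean_rpm[, 2], mean_rpm[, 1], cfg$pseudocount)
  names(ratios) <- rownames(om$rpm)
  dirs <- majority_direction(ratios)
  write_tsv0(data.frame(direction = names(dirs), fraction = as.numeric(dirs)),
             file.path(outdir, "ratio_direction.tsv"), seed_hdr)

  .stage("dynamics", "per-site linear trends")
  trends <- fit_trends(om$rpm, occ$times, alpha = cfg$alpha)
  write_tsv0(trends, file.path(outdir, "trends.tsv"), seed_hdr)
  top <- list(gained = select_top_fraction(trends, "gained", cfg$top_fraction),
              lost = select_top_fraction(trends, "lost", cfg$top_fraction))
  write_tsv0(data.frame(class = rep(names(top), lengths(top)),
                        site = unlist(top, use.names = FALSE)),
             file.path(outdir, "top_sites.tsv"), seed_hdr)
  .stage("dynamics", sprintf("gained %d, lost %d, stable %d",
                             sum(trends$class == "gained"),
                             sum(trends$class == "lost"),
                             sum(trends$class == "stable")))

  .stage("motif", sprintf("fold enrichment of '%s' vs scrambled null", motif$name))
  sim_seqs <- sim_motif_sequences(sim_cfg, motif, width = cfg$summit_width)
  enr <- motif_fold_enrichment(sim_seqs$seqs, motif,
                               n_scrambles = cfg$n_scrambles, seed = cfg$seed)
  write_tsv0(data.frame(motif = enr$motif, observed = enr$observed,
                        null_mean = enr$null_mean, fold = enr$fold,
                        n_scrambles = enr$n_scrambles, seed = enr$seed),
             file.path(outdir, "motif_enrichment.tsv"), seed_hdr)

  .stage("concord", "responsive-gene counts and treatment concordance")
  counts_tab <- do.call(rbind, lapply(cfg$fc_cuts, function(fc) {
    ca <- responsive_counts(tabA, cfg$p_cut, fc)
    cb <- responsive_counts(tabB, cfg$p_cut, fc)
    data.frame(fc_cut = fc, treatment = c("drugA", "drugB"),
               up = c(ca["up"], cb["up"]), down = c(ca["down"], cb["down"]),
               row.names = NULL)
  }))
  write_tsv0(counts_tab, file.path(outdir, "responsive_counts.tsv"), seed_hdr)
  conc_tab <- do.call(rbind, lapply(cfg$fc_cuts, function(fc) {
    r <- overlap_concordance(tabA, tabB, cfg$p_cut, fc)
    data.frame(fc_cut = fc, overlap = r$overlap,
               overlap_percent = r$overlap_percent, concordant = r$concordant,
               discordant = r$discordant,
               percent_concordant = r$percent_concordant,
               p_hyper = r$p_hyper, universe = r$universe)
  }))
  write_tsv0(conc_tab, file.path(outdir, "concordance.tsv"), seed_hdr)

  .stage("integrate", "distance CDFs, strata test and pausing calls")
  sitesA <- expA$sites
  down_set <- filter_responsive(tabA, cfg$p_cut, cfg$fc_cuts[1], "down")
  down_genes <- gg$genes[gg$genes$gene_id %in% down_set$genes]
  cdf_b <- background_cdf(gg$genes, sitesA, cfg$cutoffs)
  if (length(down_genes)) {
    cdf_t <- distance_cdf(down_genes, sitesA, cfg$cutoffs, label = "repressed")
    ce <- cdf_enrichment(cdf_t, cdf_b)
  } else {
    .stage("integrate", "no repressed genes pass the cutoffs; CDF enrichment skipped")
    cdf_t <- NULL
    ce <- list(gap = NA_real_, area = NA_real_)
  }
  write_tsv0(data.frame(cutoff_bp = cfg$cutoffs,
                        repressed = if (is.null(cdf_t)) NA_real_ else cdf_t$fraction,
                        background = cdf_b$fraction),
             file.path(outdir, "distance_cdf.tsv"), seed_hdr)
  write_tsv0(data.frame(gap = ce$gap, area = ce$area),
             file.path(outdir, "cdf_enrichment.tsv"), seed_hdr)
  strata <- distance_strata(gg$genes, sitesA, cfg$near_max, cfg$far_min)
  calls <- classify_repression_mechanism(
    paus$truth$gene_id,
    depth_ratio(paus$promoter$rpm_48h, paus$promoter$rpm_0h, cfg$pseudocount),
    depth_ratio(paus$body$rpm_48h, paus$body$rpm_0h, cfg$pseudocount))
  write_tsv0(calls, file.path(outdir, "pausing_calls.tsv"), seed_hdr)
  recov <- mean(calls$mechanism == paus$truth$mechanism)
  strata_res <- NULL
  if (length(strata$near) >= 3 && length(strata$far) >= 3) {
    # per-gene temporal ratio proxy: mean ratio of each gene's nearest site
    tssg <- tss_of(gg$genes)
    idx <- GenomicRanges::nearest(tssg, occ$sites, select = "arbitrary",
                                  ignore.strand = TRUE)
    ok <- !is.na(idx)
    per_gene <- tapply(ratios[occ$sites$site_id[idx[ok]]],
                       tssg$gene_id[ok], mean)
    gene_body_ratio <- stats::setNames(as.numeric(per_gene), names(per_gene))
    near <- intersect(strata$near, names(gene_body_ratio))
    far <- intersect(strata$far, names(gene_body_ratio))
    if (length(near) >= 3 && length(far) >= 3) {
      strata_res <- stratified_ratio_test(gene_body_ratio, near, far)
      write_tsv0(data.frame(n_near = length(near), n_far = length(far),
                            statistic = strata_res$statistic, p = strata_res$p,
                            method = strata_res$method),
                 file.path(outdir, "strata_test.tsv"), seed_hdr)
    }
  }

  write_config(cfg, file.path(outdir, "analysis_config.txt"))
  write_config(sim_cfg, file.path(outdir, "sim_config.txt"))
  manifest <- data.frame(
    key = c("package", "version", "seed", "config_md5", "sim_config_md5"),
    value = c("cistrodyn", as.character(utils::packageVersion("cistrodyn")),
              as.character(sim_cfg$seed),
              unname(tools::md5sum(file.path(outdir, "analysis_config.txt"))),
              unname(tools::md5sum(file.path(outdir, "sim_config.txt")))))
  write_tsv0(manifest, file.path(outdir, "manifest.tsv"))
  .stage("done", paste("outputs in", outdir))
  invisible(list(occupancy = om, trends = trends, top_sites = top,
                 motif = enr, responsive = counts_tab, concordance = conc_tab,
                 cdf = list(target = cdf_t, background = cdf_b, enrichment = ce),
                 pausing = list(calls = calls, recovery = recov),
                 strata = strata_res))
}

#' Bundled position weight matrices
#'
#' Reads the PWMs shipped with the package: a nuclear-receptor direct
#' repeat (DR4-type, the LXR-class response element), a PPARG-type DR1,
#' and the AP1 TPA-response element. These are synthetic textbook-consensus
#' matrices for testing and examples, not database entries.
#'
#' @return named list of [pwm()] objects.
#' @export
cistrodyn_pwms <- function() {
  read_jaspar(system.file("extdata", "pwm_synthetic.jaspar",
                          package = "cistrodyn"))
}
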