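#' Default distance grid for CDF analyses
#'
#' Log-spaced cutoffs from 1 kb to 1 Mb (25 points), matching the range over
#' which binding-to-promoter distances are informative.
#'
#' @return integer vector of cutoffs in bp, ascending.
#' @export
default_distance_cutoffs <- function() {
  unique(round(10^seq(3, 6, length.out = 25)))
}

#' Cumulative distribution of nearest-site distances for a gene set
#'
#' For each gene, the distance from its promoter to the nearest binding
#' site is the minimum over the gene's TSSs of [nearest_site_distance()];
#' the CDF reports, per distance cutoff, the fraction of genes whose
#' nearest site lies within that cutoff. Genes on chromosomes without any
#' site stay in the denominator (distance `Inf`).
#'
#' @param genes transcript `GRanges` (all transcripts of the gene set).
#' @param sites peak-set `GRanges`.
#' @param cutoffs ascending positive distance cutoffs in bp.
#' @param label set label carried into the result.
#' @return object of class `distance_cdf`: `label`, `cutoffs`, `fraction`,
#'   `n`, `distances` (per-gene named distances).
#' @export
distance_cdf <- function(genes, sites, cutoffs = default_distance_cutoffs(),
                         label = "target") {
  if (length(genes) == 0) stop("empty gene set")
  if (is.unsorted(cutoffs, strictly = TRUE) || any(cutoffs <= 0))
    stop("cutoffs must be ascending and positive")
  tss <- tss_of(genes)
  d <- nearest_site_distance(tss, sites)
  dmin <- vapply(split(d, tss$gene_id), min, 0)
  frac <- vapply(cutoffs, function(cc) mean(dmin <= cc), 0)
  structure(list(label = label, cutoffs = cutoffs, fraction = frac,
                 n = length(dmin), distances = dmin),
            class = "distance_cdf")
}

#' Background distance CDF over all annotated genes
#'
#' @param all_genes transcript `GRanges` for the whole annotation.
#' @inheritParams distance_cdf
#' @return a `distance_cdf` labeled `"background"`.
#' @export
background_cdf <- function(all_genes, sites,
                           cutoffs = default_distance_cutoffs()) {
  distance_cdf(all_genes, sites, cutoffs, label = "background")
}

#' @export
print.distance_cdf <- function(x, ...) {
  cat(sprintf("distance_cdf '%s': %d genes, %d cutoffs (%g..%g bp), final fraction %.3f\n",
              x$label, x$n, length(x$cutoffs), min(x$cutoffs), max(x$cutoffs),
              x$fraction[length(x$fraction)]))
  invisible(x)
}

#' Enrichment of a target CDF over a background CDF
#'
#' Quantifies the visual dominance of one cumulative curve over another:
#' `gap` is the maximum signed vertical difference (target - background)
#' across cutoffs, `area` the mean difference.
#'
#' @param target,background `distance_cdf` objects on identical cutoffs.
#' @return list with `gap` and `area` (both signed).
#' @export
cdf_enrichment <- function(target, background) {
  if (!identical(target$cutoffs, background$cutoffs))
    stop("CDFs computed on different cutoff grids")
  d <- target$fraction - background$fraction
  list(gap = max(d), area = mean(d))
}

#' Partition sites by co-occupancy with a second mark
#'
#' @param sites,mark peak-set `GRanges`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list `with_mark` / `without_mark`; a true partition of `sites`.
#' @export
stratify_by_cooccupancy <- function(sites, mark, min_overlap = 1L) {
  hit <- GenomicRanges::countOverlaps(sites, mark, minoverlap = min_overlap) > 0
  list(with_mark = sites[hit], without_mark = sites[!hit])
}

#' Rank correlation between promoter occupancy and expression
#'
#' Spearman correlation (average-rank ties) between per-gene promoter RPM
#' and expression, over the genes present in both vectors.
#'
#' @param promoter_rpm named numeric vector (gene id -> promoter RPM).
#' @param expression named numeric vector (gene id -> expression).
#' @return Spearman rho.
#' @export
occupancy_expression_correlation <- function(promoter_rpm, expression) {
  shared <- intersect(names(promoter_rpm), names(expression))
  if (length(shared) < 10) stop("need >= 10 shared genes")
  stats::cor(promoter_rpm[shared], expression[shared], method = "spearman")
}

#' Fraction of genes whose occupancy change matches their expression change
#'
#' For an up-regulated gene set, the fraction with positive occupancy
#' ratio; for a down-regulated set, the fraction with negative ratio.
#' Ratios of exactly zero count as discordant.
#'
#' @param gene_set a `gene_set` with direction `"up"` or `"down"`.
#' @param ratios named log2 ratio vector covering all set members.
#' @return fraction in `[0, 1]`.
#' @export
concordance_fraction <- function(gene_set, ratios) {
  if (!gene_set$direction %in% c("up", "down"))
    stop("gene set must be directional (up or down)")
  if (length(gene_set$genes) == 0) stop("empty gene set")
  missing <- setdiff(gene_set$genes, names(ratios))
  if (length(missing))
    stop("gene(s) absent from ratio vector: ", paste(utils::head(missing, 3), collapse = ", "))
  r <- ratios[gene_set$genes]
  if (gene_set$direction == "up") mean(r > 0) else mean(r < 0)
}

#' Classify the repression mechanism of RNA-down genes
#'
#' For a repressed gene, a rise in promoter RNAP2 occupancy combined with a
#' fall in gene-body H3K36me3 is the signature of promoter-proximal pausing
#' (polymerase accumulates at the promoter while productive elongation
#' drops); a fall in both is consistent with reduced initiation; any other
#' pattern is indeterminate. The classifier is defined for repressed genes
#' only.
#'
#' @param gene_id gene identifiers.
#' @param promoter_ratio per-gene promoter RNAP2 log2 ratio (late / control).
#' @param body_ratio per-gene gene-body H3K36me3 log2 ratio.
#' @param rna_direction per-gene expression direction; must all be `"down"`.
#' @return data frame of pausing calls: `gene_id`, `promoter_ratio`,
#'   `body_ratio`, `rna_direction`, `mechanism`.
#' @export
classify_repression_mechanism <- function(gene_id, promoter_ratio, body_ratio,
                                          rna_direction = "down") {
  rna_direction <- rep_len(rna_direction, length(gene_id))
  if (any(rna_direction != "down"))
    stop("classifier defined for repressed (RNA-down) genes only")
  mech <- ifelse(promoter_ratio > 0 & body_ratio < 0, "pausing_consistent",
          ifelse(promoter_ratio < 0 & body_ratio < 0, "reduced_initiation",
                 "indeterminate"))
  data.frame(gene_id = gene_id, promoter_ratio = promoter_ratio,
             body_ratio = body_ratio, rna_direction = rna_direction,
             mechanism = mech, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all group assignments when the smaller group has
#' <= `exact_max` observations (ties handled by average ranks within each
#' enumeration), otherwise the normal approximation with tie-corrected
#' variance and continuity correction. The statistic is the rank sum of
#' `x`.
#'
#' @param x,y numeric samples.
#' @param exact_max largest small-group size for exact enumeration
#'   (default 8).
#' @return list `statistic` (rank sum of `x`), `p`, `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (min(n1, n2) <= exact_max) {
    dev <- abs(W - mu)
    sums <- utils::combn(N, n1, FUN = function(i) sum(rk[i]))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    method <- "exact"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  list(statistic = W, p = p, method = method)
}

#' Compare gene-body ratios between near- and far-binding genes
#'
#' Tests whether genes with a binding site near their promoter (< 10 kb by
#' default) show a different distribution of gene-body log2 ratios than
#' genes devoid of nearby binding (> 100 kb); genes at intermediate
#' distances are excluded by construction and the two groups must be
#' disjoint.
#'
#' @param ratios named per-gene gene-body log2 ratios.
#' @param near_genes,far_genes gene ids of the two strata (>= 3 each).
#' @return object of class `strata_test`: per-group ratios, rank-sum
#'   statistic, two-sided p, method.
#' @export
stratified_ratio_test <- function(ratios, near_genes, far_genes) {
  if (length(intersect(near_genes, far_genes)))
    stop("near and far gene groups must be disjoint")
  if (length(near_genes) < 3 || length(far_genes) < 3)
    stop("each stratum needs >= 3 genes")
  missing <- setdiff(c(near_genes, far_genes), names(ratios))
  if (length(missing))
    stop("gene(s) absent from ratio vector: ", paste(utils::head(missing, 3), collapse = ", "))
  ht <- ranksum_test(ratios[near_genes], ratios[far_genes])
  structure(list(near = ratios[near_genes], far = ratios[far_genes],
                 statistic = ht$statistic, p = ht$p, method = ht$method),
            class = "strata_test")
}

#' @export
print.strata_test <- function(x, ...) {
  cat(sprintf(
    "rank-sum strata test: near n=%d (median %.3f), far n=%d (median %.3f), W=%g, two-sided p=%.4g (%s)\n",
    length(x$near), stats::median(x$near), length(x$far),
    stats::median(x$far), x$statistic, x$p, x$method))
  invisible(x)
}

#' Genes stratified by distance to nearest binding site
#'
#' @param genes transcript `GRanges`.
#' @param sites peak-set `GRanges`.
#' @param near_max distances strictly below this are "near" (default 10 kb).
#' @param far_min distances strictly above this are "far" (default 100 kb).
#' @return list `near` / `far` of gene ids (intermediate genes dropped).
#' @export
distance_strata <- function(genes, sites, near_max = 1e4, far_min = 1e5) {
  tss <- tss_of(genes)
  d <- nearest_site_distance(tss, sites)
  dmin <- vapply(split(d, tss$gene_id), min, 0)
  list(near = names(dmin)[dmin < near_max],
       far = names(dmin)[dmin > far_min])
}
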