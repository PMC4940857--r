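.check_de_table <- function(tab) {
  req <- c("gene_id", "fold_change", "padj")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("differential-expression table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$fold_change == 0, na.rm = TRUE))
    stop("signed linear fold changes cannot be 0")
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE))
    stop("adjusted p must lie in [0, 1]")
  invisible(tab)
}

#' Convert log2 fold changes to the signed linear scale
#'
#' Signed linear fold change: `2^lfc` for up-regulation, `-2^(-lfc)` for
#' down-regulation, so a 2-fold repression is -2 (matching the "fold change
#' cutoff +-2" convention).
#'
#' @param lfc log2 fold changes.
#' @return signed linear fold changes.
#' @export
signed_linear_fc <- function(lfc) ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))

#' Read a differential-expression table
#'
#' Expects a TSV with columns `gene_id`, `fold_change` (or `log2fc`, which
#' is converted with [signed_linear_fc()]), `padj`, and optionally `rpkm`.
#' This is the output format of count-based DE tools; the DE model itself is
#' never fitted here.
#'
#' @param path TSV path.
#' @return data frame with `gene_id`, signed linear `fold_change`, `padj`
#'   (and `rpkm` when present).
#' @export
read_de_table <- function(path) {
  tab <- read_tsv0(path)
  if (!"fold_change" %in% names(tab) && "log2fc" %in% names(tab))
    tab$fold_change <- signed_linear_fc(tab$log2fc)
  .check_de_table(tab)
}

#' Filter a DE table to the responsive gene set
#'
#' Up-regulated: `fold_change >= fc_cut` with `padj < p_cut`; down:
#' `fold_change <= -fc_cut` with `padj < p_cut`. The fold bound is
#' inclusive, the p bound strict.
#'
#' @param tab DE table (see [read_de_table()]).
#' @param p_cut adjusted-p cutoff (default 0.01).
#' @param fc_cut linear fold-change cutoff, >= 1 (default 2).
#' @param direction `"up"`, `"down"` or `"all"`.
#' @return object of class `gene_set`: `direction`, `p_cut`, `fc_cut`,
#'   `genes` (character), `sign` (named per-gene fold-change sign).
#' @export
filter_responsive <- function(tab, p_cut = 0.01, fc_cut = 2,
                              direction = c("up", "down", "all")) {
  direction <- match.arg(direction)
  if (fc_cut < 1) stop("fc_cut must be >= 1")
  .check_de_table(tab)
  keep <- switch(direction,
    up = tab$fold_change >= fc_cut & tab$padj < p_cut,
    down = tab$fold_change <= -fc_cut & tab$padj < p_cut,
    all = abs(tab$fold_change) >= fc_cut & tab$padj < p_cut)
  keep <- keep & !is.na(keep)
  structure(list(direction = direction, p_cut = p_cut, fc_cut = fc_cut,
                 genes = tab$gene_id[keep],
                 sign = stats::setNames(sign(tab$fold_change[keep]),
                                        tab$gene_id[keep])),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes (%s; padj < %g, |fc| >= %g)\n",
              length(x$genes), x$direction, x$p_cut, x$fc_cut))
  invisible(x)
}

#' Count up- and down-responsive genes
#'
#' @inheritParams filter_responsive
#' @return named counts `c(up = , down = )`.
#' @export
responsive_counts <- function(tab, p_cut = 0.01, fc_cut = 2) {
  c(up = length(filter_responsive(tab, p_cut, fc_cut, "up")$genes),
    down = length(filter_responsive(tab, p_cut, fc_cut, "down")$genes))
}

#' High-confidence intersection of two responsive gene sets
#'
#' Genes passing significance and fold-change cutoffs under both
#' treatments; both sets must share direction and cutoffs.
#'
#' @param a,b `gene_set` objects from [filter_responsive()].
#' @return a `gene_set` restricted to the intersection.
#' @export
high_confidence_intersection <- function(a, b) {
  if (!identical(a$direction, b$direction))
    stop("gene sets differ in direction: ", a$direction, " vs ", b$direction)
  if (a$p_cut != b$p_cut || a$fc_cut != b$fc_cut)
    stop("gene sets were filtered with different cutoffs")
  genes <- intersect(a$genes, b$genes)
  structure(list(direction = a$direction, p_cut = a$p_cut, fc_cut = a$fc_cut,
                 genes = genes, sign = a$sign[genes]),
            class = "gene_set")
}

#' Overlap and concordance between two treatment responses
#'
#' Genes responsive (either direction) under both treatments form the
#' overlap; concordant genes change in the same direction, discordant in
#' opposite directions. Percent concordant is reported to 1 decimal (half
#' away from zero). Overlap significance is the upper-tail hypergeometric
#' probability of drawing at least the observed overlap, given the two
#' responsive-set sizes and the gene universe (defaulting to the genes
#' tested in both tables).
#'
#' @param a,b DE tables for the two treatments (`a` is the reference set
#'   for the overlap percentage).
#' @param p_cut,fc_cut responsiveness cutoffs applied to both tables.
#' @param universe universe size for the hypergeometric test; default
#'   `length(intersect(a$gene_id, b$gene_id))`.
#' @return object of class `concordance_result`: `overlap`, `concordant`,
#'   `discordant`, `percent_concordant`, `overlap_percent` (of `a`'s
#'   responsive set), `p_hyper`, `universe`, set sizes `n_a`, `n_b`.
#' @export
overlap_concordance <- function(a, b, p_cut = 0.01, fc_cut = 2,
                                universe = NULL) {
  sa <- filter_responsive(a, p_cut, fc_cut, "all")
  sb <- filter_responsive(b, p_cut, fc_cut, "all")
  if (is.null(universe)) universe <- length(intersect(a$gene_id, b$gene_id))
  if (universe < length(union(sa$genes, sb$genes)))
    stop("universe smaller than the union of responsive sets")
  ov <- intersect(sa$genes, sb$genes)
  conc <- sum(sa$sign[ov] == sb$sign[ov])
  disc <- length(ov) - conc
  pc <- if (length(ov)) round_half_away(100 * conc / length(ov), 1) else NA_real_
  op <- if (length(sa$genes))
    round_half_away(100 * length(ov) / length(sa$genes), 1) else NA_real_
  p <- stats::phyper(length(ov) - 1, length(sa$genes),
                     universe - length(sa$genes), length(sb$genes),
                     lower.tail = FALSE)
  structure(list(overlap = length(ov), concordant = conc, discordant = disc,
                 percent_concordant = pc, overlap_percent = op,
                 p_hyper = p, universe = universe,
                 n_a = length(sa$genes), n_b = length(sb$genes),
                 p_cut = p_cut, fc_cut = fc_cut),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d (%.1f%% of %d) | concordant %d, discordant %d (%.1f%% concordant) | hypergeometric p = %.3g (universe %d)\n",
    x$overlap, x$overlap_percent, x$n_a, x$concordant, x$discordant,
    x$percent_concordant, x$p_hyper, x$universe))
  invisible(x)
}
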