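#' Per-site linear trend of occupancy over time
#'
#' Ordinary least-squares regression of normalized read depth (RPM) on time
#' in hours, treating every replicate observation as an independent point.
#' The p-value is the two-sided t-test on the slope with
#' `df = n_obs - 2`; with zero residual variance the p-value is floored at
#' 1e-300 (and is 1 for an exactly flat fit).
#'
#' @param values RPM observations, one per (timepoint, replicate).
#' @param times matching times in hours; >= 2 distinct timepoints with >= 2
#'   replicates each are required.
#' @return list with `slope` (RPM/h), `intercept`, `se`, `df`, `p`.
#' @export
fit_site_trend <- function(values, times) {
  if (length(values) != length(times)) stop("values and times differ in length")
  tp <- table(times)
  if (length(tp) < 2) stop("need >= 2 distinct timepoints")
  if (any(tp < 2)) stop("need >= 2 replicates per timepoint")
  n <- length(values)
  mx <- mean(times); my <- mean(values)
  sxx <- sum((times - mx)^2)
  slope <- sum((times - mx) * (values - my)) / sxx
  rss <- sum((values - my - slope * (times - mx))^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 1e-300
  } else {
    p <- max(2 * stats::pt(-abs(slope / se), df), 1e-300)
  }
  list(slope = slope, intercept = my - slope * mx, se = se, df = df, p = p)
}

#' Fit trends for every row of an occupancy matrix
#'
#' Vectorized [fit_site_trend()] across sites, plus gained/lost/stable
#' classification at level `alpha` (see [classify_dynamics()]). An optional
#' Benjamini-Hochberg adjusted p column can be added; classification always
#' uses the raw p (the analysis ranks sites rather than thresholding a
#' corrected p).
#'
#' @param rpm matrix of RPM values, sites in rows, samples in columns.
#' @param times per-column times in hours.
#' @param alpha significance threshold for dynamic classification.
#' @param adjust add a `p_adj` (BH) column.
#' @return data frame: `site`, `slope`, `p`, (`p_adj`,) `class`.
#' @export
fit_trends <- function(rpm, times, alpha = 0.05, adjust = FALSE) {
  rpm <- as.matrix(rpm)
  if (ncol(rpm) != length(times)) stop("one time per sample column")
  tp <- table(times)
  if (length(tp) < 2 || any(tp < 2))
    stop("need >= 2 timepoints with >= 2 replicates each")
  n <- length(times)
  mx <- mean(times)
  cx <- times - mx
  sxx <- sum(cx^2)
  my <- rowMeans(rpm)
  slope <- (rpm %*% cx)[, 1] / sxx
  fitted <- my + outer(slope, cx)
  rss <- rowSums((rpm - fitted)^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- pmax(2 * stats::pt(-abs(tstat), df), 1e-300)
  p[se == 0 & slope == 0] <- 1
  out <- data.frame(site = rownames(rpm) %||% as.character(seq_len(nrow(rpm))),
                    slope = slope, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$class <- classify_dynamics(out$slope, out$p, alpha)
  out
}

#' Classify a temporal trend as gained, lost or stable
#'
#' Gained: positive slope with p below `alpha`; lost: negative slope with p
#' below `alpha`; anything else (including an exactly zero slope) is stable.
#'
#' @param slope,p vectors from a trend fit.
#' @param alpha significance threshold (default 0.05).
#' @return character vector in `{gained, lost, stable}`.
#' @export
classify_dynamics <- function(slope, p, alpha = 0.05) {
  ifelse(slope > 0 & p < alpha, "gained",
         ifelse(slope < 0 & p < alpha, "lost", "stable"))
}

#' Top p-value-ranked fraction of a dynamic class
#'
#' Within the requested class, sites are ranked by ascending p (ties broken
#' by descending absolute slope, then site id) and the first
#' `ceiling(n * fraction)` are returned — the subset used for cofactor motif
#' analyses.
#'
#' @param trends data frame from [fit_trends()].
#' @param class `"gained"` or `"lost"`.
#' @param fraction fraction in (0, 1] (default 0.5).
#' @return character vector of site ids.
#' @export
select_top_fraction <- function(trends, class = c("gained", "lost"),
                                fraction = 0.5) {
  class <- match.arg(class)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  sub <- trends[trends$class == class, , drop = FALSE]
  if (nrow(sub) == 0) return(character(0))
  sub <- sub[order(sub$p, -abs(sub$slope), sub$site), , drop = FALSE]
  sub$site[seq_len(ceiling(nrow(sub) * fraction))]
}

#' Count sites gained and lost between two conditions
#'
#' Gained: treated peaks with no overlap (>= `min_overlap` bp) in the
#' control set; lost: control peaks with no overlap in the treated set.
#'
#' @param control,treated peak-set `GRanges` for the same mark.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return named counts `c(gained = , lost = )`.
#' @export
gained_lost_counts <- function(control, treated, min_overlap = 1L) {
  gained <- sum(GenomicRanges::countOverlaps(treated, control,
                                             minoverlap = min_overlap) == 0)
  lost <- sum(GenomicRanges::countOverlaps(control, treated,
                                           minoverlap = min_overlap) == 0)
  c(gained = gained, lost = lost)
}

#' Percent excess of the larger of two counts
#'
#' `100 * (a - b) / a`, rounded half away from zero to the nearest integer —
#' the "x % more" comparison between two site tallies, with the larger count
#' as denominator.
#'
#' @param a the larger count (> 0).
#' @param b the smaller count (>= 0).
#' @return integer percent.
#' @export
#' @examples
#' percent_excess(6500, 3162)  # 51
#' percent_excess(7179, 6273)  # 13
percent_excess <- function(a, b) {
  if (a == 0) stop("denominator count is zero")
  if (!(a >= b && b >= 0)) stop("need a >= b >= 0")
  as.integer(round_half_away(100 * (a - b) / a))
}
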