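#' Count reads over regions from a coverage source
#'
#' For coverage tracks the per-region count is the sum of the per-base
#' signal across the region (so a uniform 1x track over a 100-bp region
#' yields 100).
#'
#' @param regions `GRanges` of regions (e.g. summit windows or promoters).
#' @param coverage an `RleList` of per-base coverage, one element per
#'   chromosome (as returned by [read_bedgraph_coverage()] or
#'   [IRanges::coverage()]).
#' @return numeric vector of per-region totals, in region order.
#' @export
count_reads <- function(regions, coverage) {
  if (length(regions) == 0) return(numeric(0))
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  missing <- setdiff(unique(chr), names(coverage))
  if (length(missing))
    stop("chromosome(s) absent from coverage: ", paste(missing, collapse = ", "))
  out <- numeric(length(regions))
  for (c in unique(chr)) {
    i <- which(chr == c)
    cov <- coverage[[c]]
    # clip to track length; bases beyond the track contribute 0
    st <- pmin(BiocGenerics::start(regions)[i], length(cov) + 1L)
    en <- pmin(BiocGenerics::end(regions)[i], length(cov))
    ok <- st <= en
    v <- IRanges::Views(cov, start = st[ok], end = en[ok])
    out[i[ok]] <- IRanges::viewSums(v)
  }
  out
}

#' Read a bedGraph file into per-chromosome coverage
#'
#' @param path bedGraph path (columns chrom, start, end, value).
#' @return an `RleList` of per-base signal.
#' @export
read_bedgraph_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

#' Library-size normalization to reads per million
#'
#' RPM = count / total aligned reads x 1e6; invariant under joint rescaling
#' of counts and library size.
#'
#' @param counts raw counts (vector or matrix with samples in columns).
#' @param total_reads total aligned reads per sample.
#' @return RPM values with the shape of `counts`.
#' @export
normalize_depth <- function(counts, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (is.matrix(counts)) {
    if (length(total_reads) != ncol(counts))
      stop("need one total per sample column")
    sweep(counts, 2, total_reads, "/") * 1e6
  } else {
    counts / total_reads * 1e6
  }
}

#' Occupancy matrix: sites x samples normalized depth
#'
#' Bundles a raw count matrix, its RPM normalization, and per-sample
#' metadata (factor, timepoint in hours, replicate, total aligned reads).
#'
#' @param counts integer matrix, regions in rows (rownames = region ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data frame with columns `sample_id`, `factor`,
#'   `timepoint`, `replicate`, `total_reads`, one row per column of `counts`.
#' @return an object of class `occupancy_matrix` with elements `counts`,
#'   `rpm`, `samples`.
#' @export
occupancy_matrix <- function(counts, samples) {
  req <- c("sample_id", "factor", "timepoint", "replicate", "total_reads")
  if (!all(req %in% names(samples)))
    stop("samples must have columns: ", paste(req, collapse = ", "))
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(samples)) stop("one samples row per counts column")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop("counts column names must match samples$sample_id")
  if (any(counts < 0) || any(!is.finite(counts))) stop("counts must be finite and >= 0")
  structure(list(counts = counts,
                 rpm = normalize_depth(counts, samples$total_reads),
                 samples = samples),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("occupancy_matrix:", nrow(x$counts), "regions x", ncol(x$counts),
      "samples\n")
  cat("factors:", paste(unique(x$samples$factor), collapse = ", "),
      "| timepoints (h):", paste(sort(unique(x$samples$timepoint)), collapse = ", "), "\n")
  invisible(x)
}

#' Log2 read-depth ratio with pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; positive values mean the
#' first argument is the stronger condition.
#'
#' @param a,b non-negative RPM values (vectors recycle as usual).
#' @param pseudocount additive RPM pseudocount, > 0 (default 1).
#' @return log2 ratios.
#' @export
depth_ratio <- function(a, b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("negative depth values")
  log2((a + pseudocount) / (b + pseudocount))
}

#' Replicate concordance as Spearman rank correlation
#'
#' @param om an [occupancy_matrix()].
#' @param s1,s2 the two sample ids to compare.
#' @return Spearman rho (ties get average ranks).
#' @export
replicate_concordance <- function(om, s1, s2) {
  if (!all(c(s1, s2) %in% colnames(om$rpm)))
    stop("unknown sample id(s)")
  if (nrow(om$rpm) < 3) stop("need >= 3 shared regions")
  stats::cor(om$rpm[, s1], om$rpm[, s2], method = "spearman")
}

#' Direction summary of a ratio vector
#'
#' @param ratios log2 ratio vector.
#' @return named fractions `up` (> 0), `down` (< 0), `zero` (= 0), summing to 1.
#' @export
majority_direction <- function(ratios) {
  if (length(ratios) == 0) stop("empty ratio vector")
  c(up = mean(ratios > 0), down = mean(ratios < 0), zero = mean(ratios == 0))
}

#' Strongest quantified region for a gene
#'
#' When a gene has several promoters or transcripts, the region of the
#' requested kind with the strongest enrichment in the reference sample is
#' used; exact ties resolve to the 5'-most region (gene-strand aware).
#'
#' @param gene_id gene to look up.
#' @param om an [occupancy_matrix()] whose rows are region ids.
#' @param regions `GRanges` describing the matrix rows, with `region_id`,
#'   `gene_id` and `kind` metadata columns.
#' @param kind `"promoter"` or `"gene_body"`.
#' @param reference reference sample id; defaults to the earliest-timepoint
#'   sample (the control condition).
#' @return the selected region id.
#' @export
strongest_region_for_gene <- function(gene_id, om, regions,
                                      kind = c("promoter", "gene_body"),
                                      reference = NULL) {
  kind <- match.arg(kind)
  if (is.null(reference)) {
    reference <- om$samples$sample_id[which.min(om$samples$timepoint)]
  }
  sel <- which(regions$gene_id == gene_id & regions$kind == kind)
  if (!length(sel)) stop("gene not quantified for kind '", kind, "': ", gene_id)
  ids <- regions$region_id[sel]
  if (!all(ids %in% rownames(om$rpm))) stop("region ids missing from matrix")
  vals <- om$rpm[ids, as.character(reference)]
  best <- which(vals == max(vals))
  if (length(best) > 1) {
    minus <- as.character(BiocGenerics::strand(regions))[sel[best]] == "-"
    coord <- ifelse(minus, -BiocGenerics::end(regions)[sel[best]],
                    BiocGenerics::start(regions)[sel[best]])
    best <- best[order(coord)][1]
  }
  ids[best[1]]
}
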