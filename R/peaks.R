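#' Construct a peak set
#'
#' A peak set is a `GRanges` with a `summit` metadata column (absolute
#' 1-based position of maximal signal) and a numeric `score`, plus
#' factor/timepoint/replicate labels stored in `metadata()`. It represents
#' the cistrome of one factor in one condition at one time point.
#'
#' @param gr a `GRanges` of peak intervals.
#' @param summit absolute 1-based summit positions; defaults to the interval
#'   midpoint (left-of-center for even widths).
#' @param score per-peak enrichment score; defaults to 0.
#' @param factor,timepoint,replicate condition labels attached as metadata.
#' @param genome optional `Seqinfo`; when supplied, peaks are validated
#'   against chromosome bounds.
#' @return a `GRanges` peak set.
#' @export
peak_set <- function(gr, summit = NULL, score = NULL, factor = NA_character_,
                     timepoint = NA_real_, replicate = NA_character_,
                     genome = NULL) {
  if (is.null(summit)) summit <- summit_midpoint(gr)
  if (is.null(score)) score <- gr$score %||% rep(0, length(gr))
  bad <- which(summit < BiocGenerics::start(gr) | summit > BiocGenerics::end(gr))
  if (length(bad))
    stop("validation error: summit outside peak interval at entry ", bad[1])
  gr$summit <- as.integer(summit)
  gr$score <- as.numeric(score)
  if (is.null(gr$name)) gr$name <- paste0("peak_", seq_along(gr))
  if (!is.null(genome)) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chr), GenomeInfoDb::seqnames(genome))
    if (length(unknown))
      stop("validation error: unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    sl <- GenomeInfoDb::seqlengths(genome)[chr]
    oob <- which(BiocGenerics::start(gr) < 1 | BiocGenerics::end(gr) > sl)
    if (length(oob))
      stop("validation error: peak outside chromosome bounds at entry ", oob[1])
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  S4Vectors::metadata(gr)$factor <- factor
  S4Vectors::metadata(gr)$timepoint <- timepoint
  S4Vectors::metadata(gr)$replicate <- replicate
  gr
}

summit_midpoint <- function(gr) {
  # midpoint of the half-open interval: BED [start0, end0) -> start0 + w/2
  as.integer(BiocGenerics::start(gr) + floor(BiocGenerics::width(gr) / 2))
}

.split_fields <- function(lines) {
  strsplit(sub("\\s+$", "", lines), "\\s+")
}

#' Read peak calls from narrowPeak or BED
#'
#' narrowPeak column 10 is the 0-based summit offset from the interval start;
#' a value of -1 (peak-caller convention for "no summit") maps the summit to
#' the interval midpoint. Plain BED may carry a 7th column with the same
#' offset semantics; without one the midpoint is used. BED coordinates
#' (0-based half-open) are converted to the in-memory 1-based closed
#' convention on read; [write_peaks()] inverts the conversion so round-trips
#' are exact.
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bed"` (BED6 with optional summit column).
#' @param genome optional `Seqinfo` for bounds validation.
#' @inheritParams peak_set
#' @return a peak-set `GRanges`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed"), genome = NULL,
                       factor = NA_character_, timepoint = NA_real_,
                       replicate = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    gr$summit <- integer(0); gr$score <- numeric(0); gr$name <- character(0)
    return(peak_set(gr, summit = integer(0), score = numeric(0),
                    factor = factor, timepoint = timepoint,
                    replicate = replicate, genome = genome))
  }
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  minf <- if (format == "narrowPeak") 10L else 3L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < minf)
      stop("parse error at line ", i, ": expected >= ", minf, " fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop("parse error at line ", i, ": non-numeric coordinates")
  }
  start0 <- as.integer(vapply(fields, `[`, "", 2))
  end0 <- as.integer(vapply(fields, `[`, "", 3))
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("validation error at line ", bad[1],
         ": need 0 <= start < end (half-open)")
  name <- if (all(nf >= 4)) vapply(fields, `[`, "", 4) else paste0("peak_", seq_along(fields))
  score <- if (all(nf >= 5)) suppressWarnings(as.numeric(vapply(fields, `[`, "", 5))) else rep(0, length(fields))
  score[is.na(score)] <- 0
  strand <- if (all(nf >= 6)) vapply(fields, `[`, "", 6) else rep("*", length(fields))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(fields, `[`, "", 1),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand)
  gr$name <- name
  if (format == "narrowPeak") {
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 7)))  # signalValue
    score[is.na(score)] <- 0
    off <- as.integer(vapply(fields, `[`, "", 10))
  } else if (all(nf >= 7)) {
    off <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7)))
    off[is.na(off)] <- -1L
  } else {
    off <- rep(-1L, length(gr))
  }
  if (any(off >= BiocGenerics::width(gr)))
    stop("validation error: summit offset beyond peak width at line ",
         which(off >= BiocGenerics::width(gr))[1])
  summit <- ifelse(off < 0L, summit_midpoint(gr), start0 + off + 1L)
  peak_set(gr, summit = summit, score = score, factor = factor,
           timepoint = timepoint, replicate = replicate, genome = genome)
}

#' Write a peak set as BED6 (+ summit offset column)
#'
#' @param peaks a peak-set `GRanges`.
#' @param path output path.
#' @param summit_col append the 0-based summit offset as a 7th column.
#' @export
write_peaks <- function(peaks, path, summit_col = TRUE) {
  start0 <- BiocGenerics::start(peaks) - 1L
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = start0,
    end = BiocGenerics::end(peaks),
    name = peaks$name %||% paste0("peak_", seq_along(peaks)),
    score = peaks$score %||% rep(0, length(peaks)),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(peaks))))
  if (summit_col) df$summit <- peaks$summit - 1L - start0
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep peaks reproduced in a replicate experiment
#'
#' Retains the peaks of `rep1` overlapped by at least `min_overlap` bp with
#' any `rep2` peak. Summits and scores are taken from `rep1`. Only
#' replicate-reproducible binding sites feed downstream analyses.
#'
#' @param rep1,rep2 peak-set `GRanges` for the two replicates.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return the reproducible subset of `rep1`.
#' @export
reproducible_peaks <- function(rep1, rep2, min_overlap = 1L) {
  f1 <- S4Vectors::metadata(rep1)$factor; f2 <- S4Vectors::metadata(rep2)$factor
  t1 <- S4Vectors::metadata(rep1)$timepoint; t2 <- S4Vectors::metadata(rep2)$timepoint
  if (!is.null(f1) && !is.null(f2) && !is.na(f1) && !is.na(f2) && !identical(f1, f2))
    stop("replicates carry different factor labels: ", f1, " vs ", f2)
  if (!is.null(t1) && !is.null(t2) && !is.na(t1) && !is.na(t2) && !identical(t1, t2))
    stop("replicates carry different timepoints: ", t1, " vs ", t2)
  if (length(rep1) == 0 || length(rep2) == 0) return(rep1[integer(0)])
  hit <- GenomicRanges::countOverlaps(rep1, rep2, minoverlap = min_overlap) > 0
  rep1[hit]
}

#' Fixed-width window centered on each peak summit
#'
#' Read quantification uses a `width`-bp sequence centered on the summit of
#' each binding site; windows are clipped at chromosome edges when the peak
#' set carries a genome.
#'
#' @param peaks a peak-set `GRanges` with a `summit` column.
#' @param width window width in bp; must be even and >= 2 (default 100).
#' @return a `GRanges` of summit windows (names and scores preserved).
#' @export
summit_window <- function(peaks, width = 100L) {
  if (width < 2 || width %% 2 != 0) stop("width must be even and >= 2")
  if (is.null(peaks$summit)) stop("peak set lacks a summit column")
  c0 <- peaks$summit - 1L  # 0-based summit
  gr <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(peaks),
    ranges = IRanges::IRanges(start = pmax(c0 - width %/% 2 + 1L, 1L),
                              end = c0 + width %/% 2),
    strand = BiocGenerics::strand(peaks),
    seqinfo = GenomeInfoDb::seqinfo(peaks))
  gr <- GenomicRanges::trim(gr)
  gr$name <- peaks$name
  gr$score <- peaks$score
  gr
}

#' TSS positions of gene models
#'
#' Gene models are a `GRanges` of transcripts (one range per transcript
#' body) with `gene_id` and `tx_id` metadata columns; the TSS is the start
#' for plus-strand and the end for minus-strand transcripts.
#'
#' @param genes transcript `GRanges`.
#' @return width-1 `GRanges` of TSSs with `gene_id`/`tx_id` carried over.
#' @export
tss_of <- function(genes) {
  plus <- as.character(BiocGenerics::strand(genes)) != "-"
  pos <- ifelse(plus, BiocGenerics::start(genes), BiocGenerics::end(genes))
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                               IRanges::IRanges(pos, width = 1L),
                               strand = BiocGenerics::strand(genes),
                               seqinfo = GenomeInfoDb::seqinfo(genes))
  gr$gene_id <- genes$gene_id
  gr$tx_id <- genes$tx_id
  gr
}

#' Promoter windows around each TSS
#'
#' A promoter is the symmetric window within `flank` bp of a transcription
#' start site; strand does not change the window extent. One window per
#' transcript is returned, clipped at chromosome edges.
#'
#' @param genes transcript `GRanges` (see [tss_of()]).
#' @param flank half-width in bp (default 500).
#' @return promoter `GRanges` with `gene_id`/`tx_id` columns.
#' @export
promoter_of <- function(genes, flank = 500L) {
  if (flank <= 0) stop("flank must be > 0")
  tss <- tss_of(genes)
  t1 <- BiocGenerics::start(tss)
  gr <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(tss),
    ranges = IRanges::IRanges(start = pmax(t1 - flank, 1L), end = t1 + flank - 1L),
    strand = BiocGenerics::strand(tss),
    seqinfo = GenomeInfoDb::seqinfo(tss))
  gr <- GenomicRanges::trim(gr)
  gr$gene_id <- tss$gene_id
  gr$tx_id <- tss$tx_id
  gr
}

#' Distance from positions to the nearest binding site
#'
#' Distance is measured from each query position (typically a TSS) to the
#' nearest edge base of the nearest site on the same chromosome; 0 when the
#' position falls inside a site; `Inf` when the chromosome carries no site.
#'
#' @param positions width-1 `GRanges` (or a peak-set-like `GRanges`, in which
#'   case starts are used).
#' @param sites peak-set `GRanges`.
#' @return numeric vector of distances in bp (with `Inf` sentinels).
#' @export
nearest_site_distance <- function(positions, sites) {
  if (length(positions) == 0) return(numeric(0))
  if (length(sites) == 0) return(rep(Inf, length(positions)))
  idx <- GenomicRanges::nearest(positions, sites, select = "arbitrary",
                                ignore.strand = TRUE)
  pos <- BiocGenerics::start(positions)
  d <- rep(Inf, length(positions))
  ok <- !is.na(idx)
  s <- BiocGenerics::start(sites)[idx[ok]]
  e <- BiocGenerics::end(sites)[idx[ok]]
  d[ok] <- pmax(0L, s - pos[ok], pos[ok] - e)
  d
}

#' Fraction of one peak set overlapped by another
#'
#' The co-occupancy fraction: proportion of `a`'s peaks overlapped by at
#' least `min_overlap` bp with any peak of `b`. The companion fraction of the
#' inverse comparison is obtained by swapping the arguments.
#'
#' @param a,b peak-set `GRanges`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return a fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, min_overlap = 1L) {
  if (length(a) == 0) stop("empty query peak set: overlap fraction undefined")
  mean(GenomicRanges::countOverlaps(a, b, minoverlap = min_overlap) > 0)
}
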