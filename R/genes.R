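#' Read gene models from a GTF file
#'
#' Transcript features are read with [rtracklayer::import()] (which converts
#' the GTF 1-based closed coordinates to the in-memory convention) and
#' returned as one range per transcript body with `gene_id`/`tx_id` columns.
#' Files lacking explicit `transcript` rows fall back to the span of each
#' transcript's exons.
#'
#' @param path GTF file path.
#' @param genome optional `Seqinfo` for bounds validation.
#' @return transcript `GRanges`.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gff <- rtracklayer::import(path, format = "gtf")
  tx <- gff[gff$type == "transcript"]
  if (length(tx) == 0) {
    ex <- gff[gff$type == "exon"]
    if (length(ex) == 0) stop("no transcript or exon features in ", path)
    spl <- split(ex, ex$transcript_id)
    tx <- unlist(range(spl))
    tx$transcript_id <- names(tx)
    tx$gene_id <- ex$gene_id[match(tx$transcript_id, ex$transcript_id)]
    names(tx) <- NULL
  }
  out <- GenomicRanges::granges(tx)
  out$gene_id <- tx$gene_id
  out$tx_id <- tx$transcript_id
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(out) <- genome
    sl <- GenomeInfoDb::seqlengths(genome)[as.character(GenomeInfoDb::seqnames(out))]
    if (any(BiocGenerics::start(out) < 1 | BiocGenerics::end(out) > sl))
      stop("validation error: transcript outside chromosome bounds")
  }
  out
}

#' Write gene models as GTF
#'
#' @param genes transcript `GRanges` (with `gene_id`/`tx_id`).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- genes
  gr$type <- "transcript"
  gr$source <- "cistrodyn"
  gr$transcript_id <- genes$tx_id
  gr$tx_id <- NULL
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
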