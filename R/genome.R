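#' Genome model from chromosome lengths
#'
#' A genome model is a [GenomeInfoDb::Seqinfo] mapping chromosome names to
#' lengths; it is attached to every interval container so coordinates can be
#' validated and windows clipped at chromosome edges.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @return a `Seqinfo` object.
#' @export
#' @examples
#' genome_model(c(chr1 = 1e6, chr2 = 5e5))
genome_model <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be present and unique")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_lengths),
                        seqlengths = as.integer(chrom_lengths))
}

#' Read a UCSC chrom.sizes file
#'
#' @param path two-column whitespace-separated file (name, length).
#' @return a `Seqinfo` genome model.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_model(stats::setNames(tab[[2]], tab[[1]]))
}

#' Write a chrom.sizes file
#' @param genome a `Seqinfo` object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(genome), GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract interval sequences from an in-memory genome
#'
#' @param genome a named [Biostrings::DNAStringSet], one entry per chromosome.
#' @param regions a `GRanges` of regions to extract.
#' @return a `DNAStringSet`, one sequence per region, reverse-complemented for
#'   minus-strand regions.
#' @export
extract_sequences <- function(genome, regions) {
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  missing <- setdiff(unique(chr), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i) {
    s <- Biostrings::subseq(genome[[chr[i]]],
                            start = BiocGenerics::start(regions)[i],
                            end = BiocGenerics::end(regions)[i])
    if (as.character(BiocGenerics::strand(regions))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  }))
  nm <- regions$name
  names(seqs) <- if (!is.null(nm)) nm else as.character(regions)
  seqs
}
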