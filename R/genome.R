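#' Read a genome (or any nucleotide) FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first whitespace-delimited token so sequences can be looked
#' up by chromosome name.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract genomic sequence on 0-based half-open coordinates
#'
#' @param genome A named `DNAStringSet` (see [read_genome()]).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A character scalar (plus-strand sequence).
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome '", chrom, "' not found in genome"))
  }
  if (end < start || start < 0 || end > length(genome[[chrom]])) {
    abort("interval out of range")
  }
  if (end == start) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_nt <- function(x) {
  if (nchar(x) < 3) return("")
  x <- substr(x, 1L, nchar(x) - nchar(x) %% 3L)
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(x),
    if.fuzzy.codon = "X"
  )))
}
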