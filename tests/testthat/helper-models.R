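# Hand-built toy models and genomes used across tests.

# plus-strand gene with explicit exon grid: exons [0,100) [200,300) ...
toy_model <- function(n_exons = 4, exon_len = 100, intron_len = 100,
                      gene_id = "toy", chrom = "chrT", strand = "+",
                      cds_start = 10, cds_end = NULL) {
  step <- exon_len + intron_len
  starts <- (seq_len(n_exons) - 1) * step
  ends <- starts + exon_len
  if (is.null(cds_end)) {
    cds_end <- ends[n_exons] - 10
    # trim so the exonic CDS length is a multiple of 3
    exonic <- function(ce) sum(pmax(0, pmin(ends, ce) -
                                      pmax(starts, cds_start)))
    cds_end <- cds_end - exonic(cds_end) %% 3
  }
  gene_model(gene_id, chrom, strand, starts, ends, cds_start, cds_end)
}

# genome for a toy model: a designed transcript threaded through the exons
# (5'UTR + ATG + codons + TAA + 3'UTR), introns/pads filled with C
toy_genome <- function(model, cds_codons = NULL) {
  ex <- splicerescue:::exon_intervals(model)
  n <- length(ex$exon_start)
  exonic_len <- sum(ex$exon_end - ex$exon_start)
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  # exonic offsets of the CDS bounds
  off_of <- function(g) {
    sum(pmax(0, pmin(ex$exon_end, g) - ex$exon_start))
  }
  u5 <- off_of(cs)
  cds_len <- off_of(ce) - u5
  stopifnot(cds_len %% 3 == 0)
  if (is.null(cds_codons)) {
    body <- paste(rep("GCA", cds_len / 3 - 2), collapse = "")
    cds <- paste0("ATG", body, "TAA")
  } else {
    cds <- cds_codons
    stopifnot(nchar(cds) == cds_len)
  }
  transcript <- paste0(strrep("C", u5), cds,
                       strrep("C", exonic_len - u5 - cds_len))
  chrom_len <- max(ex$exon_end) + 50
  g <- rep("C", chrom_len)
  pos <- 1
  for (i in seq_len(n)) {
    seg <- substr(transcript, pos, pos + (ex$exon_end[i] - ex$exon_start[i]) - 1)
    g[(ex$exon_start[i] + 1):ex$exon_end[i]] <- strsplit(seg, "")[[1]]
    pos <- pos + (ex$exon_end[i] - ex$exon_start[i])
  }
  Biostrings::DNAStringSet(setNames(paste(g, collapse = ""),
                                    model$chrom[1]))
}

# place the bases of `motif` (transcript orientation) at mutant-transcript
# positions starting at tx position t, editing the genome accordingly
edit_tx_bases <- function(genome, model, tx, t, motif) {
  seqs <- as.character(genome)
  s <- seqs[[model$chrom[1]]]
  minus <- model$strand[1] == "-"
  for (k in seq_len(nchar(motif))) {
    g <- tx$tx2genome(t + k - 1L)
    stopifnot(!is.na(g))
    b <- substr(motif, k, k)
    if (minus) b <- splicerescue:::revcomp(b)
    substr(s, g + 1L, g + 1L) <- b
  }
  seqs[[model$chrom[1]]] <- s
  Biostrings::DNAStringSet(seqs)
}
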