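#' Construct a gene model tibble
#'
#' A gene model is a tibble with one row per exon of the representative
#' transcript of a gene. All coordinates are 0-based, half-open and genomic;
#' `exon_rank` orders exons in transcript (5' to 3') orientation, so on the
#' minus strand rank 1 is the rightmost exon. `cds_start`/`cds_end` delimit
#' the genomic span of the coding sequence including the stop codon.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon bounds (0-based,
#'   half-open), in genomic (left-to-right) order.
#' @param cds_start,cds_end Genomic bounds of the CDS span (0-based,
#'   half-open, stop codon included). Use `NA` for a non-coding gene.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `exon_rank`,
#'   `exon_start`, `exon_end`, `cds_start`, `cds_end`.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(length(exon_starts) == length(exon_ends),
            strand %in% c("+", "-"))
  ord <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[ord])
  exon_ends <- as.integer(exon_ends[ord])
  if (any(exon_ends <= exon_starts)) abort("empty or inverted exon")
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] < exon_ends[-length(exon_ends)])) {
    abort(paste0("overlapping exons in gene ", gene_id))
  }
  n <- length(exon_starts)
  rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exon_rank = rank,
    exon_start = exon_starts, exon_end = exon_ends,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  ) |>
    arrange(.data$exon_rank)
}

#' Validate gene-model invariants
#'
#' Checks that exons are disjoint, that the CDS bounds fall inside exons and,
#' when a genome is supplied, that the spliced CDS is a multiple of 3 long
#' and translates to a protein with exactly one stop codon, at its end.
#'
#' @param models Gene-model tibble (possibly many genes).
#' @param genome Optional `DNAStringSet` for sequence-level checks.
#' @return `models`, invisibly; problems raise errors.
#' @export
validate_gene_models <- function(models, genome = NULL) {
  for (g in unique(models$gene_id)) {
    m <- dplyr::filter(models, .data$gene_id == g) |>
      arrange(.data$exon_start)
    if (nrow(m) > 1 && any(m$exon_start[-1] < m$exon_end[-nrow(m)])) {
      abort(paste0("overlapping exons in gene ", g))
    }
    cs <- m$cds_start[1]; ce <- m$cds_end[1]
    if (!is.na(cs)) {
      in_exon <- function(p) any(m$exon_start <= p & p < m$exon_end)
      if (!in_exon(cs) || !in_exon(ce - 1L)) {
        abort(paste0("CDS bounds outside exons in gene ", g))
      }
      if (!is.null(genome)) {
        cds <- spliced_cds(m, genome)
        if (nchar(cds) %% 3 != 0) {
          abort(paste0("CDS length not a multiple of 3 in gene ", g))
        }
        aa <- translate_nt(cds)
        if (str_sub(aa, -1) != "*" ||
            str_detect(str_sub(aa, 1, -2), stringr::fixed("*"))) {
          abort(paste0("CDS of gene ", g,
                       " does not end in a unique stop codon"))
        }
      }
    }
  }
  invisible(models)
}

#' Exonic intervals of one gene, genomic order
#' @noRd
exon_intervals <- function(model) {
  o <- order(model$exon_start)
  list(exon_start = model$exon_start[o], exon_end = model$exon_end[o])
}

#' Spliced CDS sequence of the canonical isoform
#'
#' @param model Gene-model tibble for a single gene.
#' @param genome Named `DNAStringSet`.
#' @return Character scalar: the CDS in transcript orientation, stop included.
#' @export
spliced_cds <- function(model, genome) {
  stopifnot(length(unique(model$gene_id)) == 1)
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  if (is.na(cs)) abort("non-coding gene has no CDS")
  ex <- exon_intervals(model)
  ss <- pmax(ex$exon_start, cs); ee <- pmin(ex$exon_end, ce)
  keep <- ee > ss
  seq <- paste0(purrr::map2_chr(ss[keep], ee[keep], function(s, e) {
    genome_seq(genome, model$chrom[1], s, e)
  }), collapse = "")
  if (model$strand[1] == "-") seq <- revcomp(seq)
  seq
}

#' Enumerate the canonical splice junctions of gene models
#'
#' Each annotated intron gives one junction; a gene with n exons yields
#' n - 1 junctions. Junction coordinates are the 0-based half-open interval
#' of the excised intron.
#'
#' @param models Gene-model tibble (one or many genes).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `intron_rank` (transcript order).
#' @export
canonical_junctions <- function(models) {
  models |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(m, key) {
      m <- arrange(m, .data$exon_start)
      if (nrow(m) < 2) {
        return(tibble(chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      intron_rank = integer()))
      }
      ist <- m$exon_end[-nrow(m)]
      ien <- m$exon_start[-1]
      rank <- if (m$strand[1] == "+") seq_along(ist) else rev(seq_along(ist))
      tibble(chrom = m$chrom[1], strand = m$strand[1],
             intron_start = ist, intron_end = ien, intron_rank = rank)
    }) |>
    ungroup() |>
    arrange(.data$gene_id, .data$intron_start)
}

#' Transcription span of each gene
#' @param models Gene-model tibble.
#' @return Tibble `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`.
#' @export
gene_spans <- function(models) {
  models |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              tx_start = min(.data$exon_start), tx_end = max(.data$exon_end),
              cds_start = first(.data$cds_start),
              cds_end = first(.data$cds_end),
              n_exons = n(), .groups = "drop")
}

#' Introns of one gene as an interval tibble (genomic order)
#' @noRd
intron_intervals <- function(model) {
  ex <- exon_intervals(model)
  n <- length(ex$exon_start)
  if (n < 2) return(list(start = integer(), end = integer()))
  list(start = ex$exon_end[-n], end = ex$exon_start[-1])
}
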