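#' Load gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features into one gene model per gene, keeping a
#' single representative transcript (the first mRNA of each gene; additional
#' transcripts are dropped with a warning). Genes without CDS features are
#' flagged non-coding and excluded from the returned models with a warning,
#' as they cannot enter frame analysis. GFF3 1-based closed coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional named `DNAStringSet`; when supplied, models are
#'   validated at the sequence level (in-frame CDS with terminal stop).
#' @return A gene-model tibble (see [gene_model()]).
#' @export
read_gene_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr)) |>
    mutate(seqnames = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  mrna <- df |> dplyr::filter(.data$type %in% c("mRNA", "transcript"))
  if (nrow(mrna) == 0) abort("no mRNA/transcript features in GFF3")
  mrna <- mrna |>
    mutate(parent_gene = vapply(.data$Parent, function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1)))
  dup <- mrna |> count(.data$parent_gene) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(paste0(nrow(dup), " gene(s) have multiple transcripts; ",
                "keeping the first (representative) transcript of each"))
  }
  mrna <- mrna |> group_by(.data$parent_gene) |> slice(1) |> ungroup()

  parent_of <- function(sub) {
    vapply(sub$Parent, function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
  }
  exons <- df |> dplyr::filter(.data$type == "exon")
  exons$parent_tx <- parent_of(exons)
  cds <- df |> dplyr::filter(.data$type == "CDS")
  cds$parent_tx <- parent_of(cds)

  out <- vector("list", nrow(mrna))
  skipped <- character()
  for (i in seq_len(nrow(mrna))) {
    tx <- mrna[i, ]
    gid <- tx$parent_gene %||% tx$ID
    ex <- exons |> dplyr::filter(.data$parent_tx == tx$ID) |>
      arrange(.data$start)
    if (nrow(ex) == 0) {
      warn(paste0("transcript ", tx$ID, " has no exons; record rejected"))
      next
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      warn(paste0("overlapping exons in transcript ", tx$ID,
                  "; record rejected"))
      next
    }
    cd <- cds |> dplyr::filter(.data$parent_tx == tx$ID)
    if (nrow(cd) == 0) {
      skipped <- c(skipped, gid)
      next
    }
    out[[i]] <- gene_model(
      gene_id = gid, chrom = tx$seqnames, strand = tx$strand,
      exon_starts = ex$start - 1L, exon_ends = ex$end,
      cds_start = min(cd$start) - 1L, cds_end = max(cd$end)
    )
  }
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " gene(s) without CDS flagged non-coding ",
                "and excluded: ", paste(skipped, collapse = ", ")))
  }
  models <- list_rbind(purrr::compact(out))
  if (nrow(models) == 0) abort("no coding gene models could be loaded")
  validate_gene_models(models, genome)
  models
}

#' Write gene models back to GFF3
#'
#' Emits gene, mRNA, exon and CDS features; reloading with
#' [read_gene_models()] reproduces the exon and CDS coordinates exactly.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  for (g in unique(models$gene_id)) {
    m <- models |> dplyr::filter(.data$gene_id == g) |>
      arrange(.data$exon_start)
    span <- c(min(m$exon_start), max(m$exon_end))
    tx_id <- paste0(g, ".1")
    rows[[length(rows) + 1]] <- tibble(
      seqid = m$chrom[1], type = c("gene", "mRNA"),
      start = span[1] + 1L, end = span[2], strand = m$strand[1],
      attributes = c(paste0("ID=", g),
                     paste0("ID=", tx_id, ";Parent=", g))
    )
    rows[[length(rows) + 1]] <- tibble(
      seqid = m$chrom[1], type = "exon",
      start = m$exon_start + 1L, end = m$exon_end, strand = m$strand[1],
      attributes = paste0("ID=", tx_id, ".exon", seq_len(nrow(m)),
                          ";Parent=", tx_id)
    )
    cs <- m$cds_start[1]; ce <- m$cds_end[1]
    if (!is.na(cs)) {
      cd <- m |>
        mutate(s = pmax(.data$exon_start, cs), e = pmin(.data$exon_end, ce)) |>
        dplyr::filter(.data$e > .data$s)
      rows[[length(rows) + 1]] <- tibble(
        seqid = cd$chrom, type = "CDS",
        start = cd$s + 1L, end = cd$e, strand = cd$strand,
        attributes = paste0("ID=", tx_id, ".cds;Parent=", tx_id)
      )
    }
  }
  tab <- list_rbind(rows)
  lines <- c("##gff-version 3",
             paste(tab$seqid, "splicerescue", tab$type, tab$start, tab$end,
                   ".", tab$strand, ".", tab$attributes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write junctions as 6-column BED
#'
#' BED uses 0-based half-open coordinates, matching the package convention,
#' so intron bounds are written as-is. The score column carries read counts
#' when a `reads` column is present.
#'
#' @param junctions Junction tibble with `chrom`, `intron_start`,
#'   `intron_end`, `strand` and optionally `name` and `reads`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  name <- if ("name" %in% names(junctions)) {
    junctions$name
  } else {
    paste0(junctions$chrom, ":", junctions$intron_start, "-",
           junctions$intron_end)
  }
  score <- if ("reads" %in% names(junctions)) {
    junctions$reads
  } else {
    rep(0L, nrow(junctions))
  }
  writeLines(paste(junctions$chrom, junctions$intron_start,
                   junctions$intron_end, name, score, junctions$strand,
                   sep = "\t"), path)
  invisible(path)
}
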