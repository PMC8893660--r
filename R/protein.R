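#' Translate an isoform (with optional variant) to protein
#'
#' Builds the mature transcript, locates the annotated start codon and
#' translates with the standard code up to the first stop. A transcript
#' with no in-frame stop is translated to its end and flagged.
#'
#' @param model Gene-model tibble for one gene.
#' @param genome Named `DNAStringSet`.
#' @param isoform Intron-chain tibble (default: canonical chain).
#' @param variant Optional one-row variant tibble.
#' @return A one-row tibble: `protein` (amino acids, no stop symbol),
#'   `length_aa`, `stopped` (`FALSE` flags a non-stop transcript),
#'   `start_found`.
#' @export
translate_isoform <- function(model, genome, isoform = NULL,
                              variant = NULL) {
  if (is.null(isoform)) isoform <- make_isoform(model)
  tx <- build_mature_transcript(model, genome, introns = isoform,
                                variant = variant)
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  minus <- model$strand[1] == "-"
  start_g <- if (minus) ce - 1L else cs
  start_tx <- tx$genome2tx(start_g)
  if (is.na(start_tx)) {
    return(tibble(protein = "", length_aa = 0L, stopped = FALSE,
                  start_found = FALSE))
  }
  aa <- translate_nt(str_sub(tx$seq, start_tx))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    prot <- str_sub(aa, 1L, stop_at - 1L)
    stopped <- TRUE
  } else {
    prot <- aa
    stopped <- FALSE
  }
  tibble(protein = prot, length_aa = nchar(prot), stopped = stopped,
         start_found = TRUE)
}

#' Global alignment identity between two proteins
#'
#' Percent identity under a global (Needleman-Wunsch) alignment with fixed
#' scoring: match 1, mismatch 0, gap -1 per residue, end gaps penalised.
#' Identity is matching columns over total alignment columns, in percent.
#'
#' @param p1,p2 Amino-acid sequences (character scalars).
#' @return Identity percentage in `[0, 100]`; an empty sequence gives 0
#'   with a warning.
#' @export
global_identity <- function(p1, p2) {
  if (nchar(p1) == 0 || nchar(p2) == 0) {
    warn("empty protein sequence; identity set to 0")
    return(0)
  }
  aln <- align_global(p1, p2)
  100 * sum(aln$a == aln$b & aln$a != "-") / length(aln$a)
}

# global alignment (match 1 / mismatch 0 / gap -1, end gaps penalised)
# returning the aligned columns
align_global <- function(p1, p2) {
  chars <- unique(c(strsplit(p1, "")[[1]], strsplit(p2, "")[[1]]))
  mat <- matrix(0, length(chars), length(chars),
                dimnames = list(chars, chars))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(p1), Biostrings::BString(p2),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(a = a, b = b)
}

#' Read protein domain intervals
#'
#' TSV with columns `gene_id`, `domain_name`, `aa_start`, `aa_end`
#' (1-based, closed, on the wild-type protein).
#'
#' @param path Path to the TSV file.
#' @return A tibble of domain intervals.
#' @export
read_domains <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "domain_name", "aa_start", "aa_end") %in%
                  names(d)))
  d
}

#' Assess the rescue competence of an isoform protein
#'
#' An isoform is rescue-competent when it preserves all wild-type domains
#' and its global identity to the wild type exceeds `min_identity`. A
#' domain is preserved when, in the global alignment, every wild-type
#' domain residue aligns to an identical isoform residue with at most
#' `mismatch_tolerance` interrupted columns (gap or mismatch). With no
#' domains supplied, preservation holds vacuously and is flagged.
#'
#' @param wt_protein,iso_protein Amino-acid sequences.
#' @param domains Tibble with `aa_start`, `aa_end` (1-based closed
#'   intervals on the wild-type protein), possibly zero rows.
#' @param min_identity Identity threshold in percent (default 90).
#' @param mismatch_tolerance Interrupted columns allowed inside a domain
#'   (default 0).
#' @return One-row tibble: `identity_pct`, `domains_preserved`,
#'   `rescue_competent`, `no_domain_flag`.
#' @export
assess_rescue_competence <- function(wt_protein, iso_protein, domains,
                                     min_identity = 90,
                                     mismatch_tolerance = 0) {
  identity_pct <- global_identity(wt_protein, iso_protein)
  no_domain <- is.null(domains) || nrow(domains) == 0
  if (no_domain) {
    preserved <- TRUE
  } else {
    stopifnot(all(domains$aa_end <= nchar(wt_protein)))
    aln <- align_global(wt_protein, iso_protein)
    wt_pos <- cumsum(aln$a != "-")
    preserved <- all(purrr::map_lgl(seq_len(nrow(domains)), function(i) {
      cols <- which(wt_pos >= domains$aa_start[i] &
                      wt_pos <= domains$aa_end[i] & aln$a != "-")
      bad <- sum(aln$a[cols] != aln$b[cols])
      # wt residues of the domain deleted in the isoform appear as
      # mismatch-to-gap columns and are counted by `bad` already
      bad <= mismatch_tolerance
    }))
  }
  tibble(identity_pct = identity_pct,
         domains_preserved = preserved,
         rescue_competent = preserved & identity_pct > min_identity,
         no_domain_flag = no_domain)
}
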