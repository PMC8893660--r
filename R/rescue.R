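#' Read indel/SNV variant specifications from a VCF file
#'
#' Single-sample, unphased VCF; one row per ALT allele. Coordinates are
#' converted to the package's 0-based convention (`pos` is the 0-based
#' position of the first REF base).
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `kind`
#'   (`"indel"`/`"snv"`), `delta_nt` and `frame_class`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  out <- fx |>
    tidyr::separate_rows("ALT", sep = ",") |>
    mutate(chrom = .data$CHROM,
           pos = as.integer(.data$POS) - 1L,
           ref = .data$REF, alt = .data$ALT) |>
    select("chrom", "pos", "ref", "alt")
  variant_spec(out$chrom, out$pos, out$ref, out$alt)
}

#' Construct a variant specification tibble
#'
#' @param chrom,pos,ref,alt Vectors describing replacement-style variants:
#'   the reference bases at 0-based position `pos` are replaced by `alt`
#'   (`ref = ""` denotes a pure insertion before `pos`).
#' @return A tibble with derived `kind`, `delta_nt` and `frame_class`.
#' @export
variant_spec <- function(chrom, pos, ref, alt) {
  delta <- nchar(alt) - nchar(ref)
  tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    kind = if_else(delta == 0L & nchar(ref) == 1L, "snv", "indel"),
    delta_nt = as.integer(delta),
    frame_class = if_else(delta %% 3L == 0L, "3n", "non-3n")
  )
}

#' Distance from an indel to the nearest annotated splice site
#'
#' The minimum, over both indel boundaries, of the distance in bp to the
#' nearest annotated intron boundary (splice site) of the gene. Intronic
#' variants are flagged with `NA`.
#'
#' @param variant One-row variant tibble (`pos`, `ref`).
#' @param model Gene-model tibble for one gene.
#' @return Integer distance in bp (`NA` when the variant is not exonic).
#' @export
indel_distance_to_splice_site <- function(variant, model) {
  ex <- exon_intervals(model)
  ci <- intron_intervals(model)
  pos <- variant$pos
  rlen <- nchar(variant$ref)
  hit <- which(ex$exon_start <= pos & pos < ex$exon_end)
  if (length(hit) == 0) {
    warn("variant is not exonic; distance to splice site undefined")
    return(NA_integer_)
  }
  sites <- unique(c(ci$start, ci$end))
  if (length(sites) == 0) return(NA_integer_)
  bounds <- c(pos, pos + max(rlen, 0L))
  # left boundary measured to sites at or left of it, etc.; the distance of
  # an indel abutting an exon start is 0
  d <- min(vapply(bounds, function(b) min(abs(sites - b)), numeric(1)))
  as.integer(d)
}

#' Decide whether an isoform rescues a frameshifting variant
#'
#' The caller combines (i) the structural frame delta of the junction chain
#' within the CDS, (ii) the retained part of the variant's length change,
#' and (iii) an ORF scan of the mutant mature transcript. The verdict is
#' `rescue` iff the net coding-length change is 0 mod 3, the first in-frame
#' stop of the mutant transcript is the canonical stop, and no premature
#' stop intervenes. A 3n indel is `not_applicable` (it never breaks the
#' frame); a nonsense SNV can be rescued only when the PTC-creating base is
#' excised by the chain.
#'
#' @param model Gene-model tibble for one gene.
#' @param genome Named `DNAStringSet`.
#' @param variant One-row variant tibble (see [variant_spec()]).
#' @param isoform Intron-chain tibble (see [make_isoform()]), or a tibble of
#'   novel junctions with `novel = TRUE` attribute semantics via
#'   [make_isoform()]; pass the full chain.
#' @return A one-row tibble with the rescue call: `gene_id`, variant
#'   columns, `junction_delta`, `variant_retained`, `variant_delta`,
#'   `net_delta_mod3`, `canonical_stop_used`, `first_stop_pos`,
#'   `ptc_status`, `verdict`, `form_class`, `ptc_mode`,
#'   `indel_to_splice_site_bp`.
#' @export
call_rescue <- function(model, genome, variant, isoform) {
  if (is.na(model$cds_start[1])) abort("non-coding gene")
  span <- c(min(model$exon_start), max(model$exon_end))
  gid <- model$gene_id[1]
  base_row <- tibble(
    gene_id = gid, chrom = variant$chrom, pos = variant$pos,
    ref = variant$ref, alt = variant$alt, kind = variant$kind,
    variant_delta_nt = variant$delta_nt
  )
  if (variant$pos < span[1] || variant$pos >= span[2]) {
    return(base_row |> mutate(
      junction_delta = NA_integer_, variant_retained = NA,
      variant_delta = NA_integer_, net_delta_mod3 = NA_integer_,
      canonical_stop_used = NA, first_stop_pos = NA_integer_,
      ptc_status = NA_character_, verdict = "not_applicable",
      form_class = "not_applicable", ptc_mode = "not_applicable",
      indel_to_splice_site_bp = NA_integer_))
  }

  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  minus <- model$strand[1] == "-"
  o <- order(isoform$intron_start)
  chain <- list(intron_start = isoform$intron_start[o],
                intron_end = isoform$intron_end[o])
  canon <- make_isoform(model)

  # structural frame delta of the chain, coding bases only
  kept_cds <- function(introns) {
    segs <- clip_segments(span, introns)
    sum(pmax(0, pmin(segs$e, ce) - pmax(segs$s, cs)))
  }
  junction_delta <- as.integer(kept_cds(chain) - kept_cds(canon))

  # retained variant contribution within the CDS
  segs <- clip_segments(span, chain)
  rlen <- nchar(variant$ref)
  in_cds <- variant$pos >= cs && variant$pos < ce
  if (rlen == 0) {
    applied <- any(segs$s < variant$pos & variant$pos < segs$e)
    variant_retained <- applied
    variant_delta <- if (applied && in_cds) nchar(variant$alt) else 0L
  } else {
    retained <- sum(pmax(0, pmin(segs$e, variant$pos + rlen) -
                           pmax(segs$s, variant$pos)))
    retained_cds <- sum(pmax(0, pmin(segs$e, variant$pos + rlen, ce) -
                               pmax(segs$s, variant$pos, cs)))
    variant_retained <- retained > 0
    variant_delta <- if (retained == rlen) {
      if (in_cds) nchar(variant$alt) - rlen else 0L
    } else {
      -retained_cds
    }
  }
  variant_delta <- as.integer(variant_delta)
  net <- (junction_delta + variant_delta) %% 3L

  # ORF scan of the mutant mature transcript
  tx <- build_mature_transcript(model, genome, introns = chain,
                                variant = variant)
  start_g <- if (minus) ce - 1L else cs
  stop_g <- if (minus) cs + 2L else ce - 3L
  cds_start_tx <- tx$genome2tx(start_g)
  canonical_stop_tx <- tx$genome2tx(stop_g)
  orf <- scan_orf(tx$seq, cds_start_tx, canonical_stop_tx)

  # mode of failure/rescue under canonical splicing (for PTC bookkeeping)
  frame_ok <- net == 0L
  verdict <- "no_rescue"
  applicable <- TRUE
  if (variant$kind == "indel") {
    if (variant$delta_nt %% 3L == 0L) applicable <- FALSE
  } else {
    # nonsense SNV: only applicable when the substitution creates a PTC
    # under canonical splicing
    ctx <- build_mature_transcript(model, genome, introns = canon,
                                   variant = variant)
    corf <- scan_orf(ctx$seq, ctx$genome2tx(start_g),
                     ctx$genome2tx(stop_g))
    if (!identical(corf$ptc_status, "premature")) applicable <- FALSE
    # rescue then requires the PTC to be removed from the mature
    # transcript — usually by excising the mutated base, occasionally by
    # splitting its codon at a junction; the ORF scan below decides
  }
  if (!applicable) {
    verdict <- "not_applicable"
  } else if (frame_ok && orf$canonical_stop_used &&
             !identical(orf$ptc_status, "premature")) {
    verdict <- "rescue"
  }

  call <- base_row |> mutate(
    junction_delta = junction_delta,
    variant_retained = variant_retained,
    variant_delta = variant_delta,
    net_delta_mod3 = net,
    canonical_stop_used = orf$canonical_stop_used,
    first_stop_pos = orf$first_stop_pos %||% NA_integer_,
    ptc_status = orf$ptc_status,
    verdict = verdict,
    form_class = "not_applicable", ptc_mode = "not_applicable",
    indel_to_splice_site_bp = suppressWarnings(
      indel_distance_to_splice_site(variant, model))
  )
  if (verdict == "rescue") {
    call$form_class <- classify_form(call, model, chain, variant)
    call$ptc_mode <- classify_ptc_mode(model, genome, variant, chain)
  }
  call
}

#' Classify the rescue form (exon-skip taxonomy)
#'
#' Four-way classification of a rescue call by (junction chain 3n vs
#' non-3n) and (an entire annotated exon excised vs not): a 3n chain
#' skipping the whole indel-bearing exon is `A1_3n_exon_skip`; other 3n
#' rescues are `A_3n_other`; a non-3n chain that wholly skips some
#' annotated exon is `A6_non3n_exon_skip`; other non-3n rescues are
#' `A_non3n_other`.
#'
#' @param call One-row rescue call tibble (`verdict`, `junction_delta`).
#' @param model Gene-model tibble.
#' @param chain Intron-chain tibble used for the call.
#' @param variant One-row variant tibble.
#' @return Character scalar form class.
#' @export
classify_form <- function(call, model, chain, variant) {
  if (!identical(call$verdict, "rescue")) return("not_applicable")
  ex <- exon_intervals(model)
  wholly_skipped <- purrr::map_lgl(seq_along(ex$exon_start), function(i) {
    any(chain$intron_start <= ex$exon_start[i] &
          chain$intron_end >= ex$exon_end[i])
  })
  chain_3n <- call$junction_delta %% 3L == 0L
  indel_exon <- which(ex$exon_start <= variant$pos &
                        variant$pos < ex$exon_end)
  indel_exon_skipped <- length(indel_exon) == 1 &&
    wholly_skipped[indel_exon]
  if (chain_3n) {
    if (indel_exon_skipped) "A1_3n_exon_skip" else "A_3n_other"
  } else {
    if (any(wholly_skipped)) "A6_non3n_exon_skip" else "A_non3n_other"
  }
}

#' Classify the PTC rescue mode (A-H taxonomy)
#'
#' For a rescue call, locates the premature stop that the variant would
#' create under canonical splicing and classifies how the rescue chain
#' deals with it: modes are the cross of (indel and PTC in the same
#' annotated exon vs different exons) with (PTC excised by whole-exon
#' skipping / PTC excised by a non-exon-skip junction / PTC retained but
#' frame compensated with no upstream exon skip / PTC retained and rescued
#' by skipping an exon before the PTC). When the canonical-splicing stop
#' falls behind the canonical stop the mode is `posterior_stop`.
#'
#' @param model Gene-model tibble.
#' @param genome Named `DNAStringSet`.
#' @param variant One-row variant tibble.
#' @param chain Rescue intron-chain tibble.
#' @return One of `"A"`..`"H"`, `"posterior_stop"`, `"not_applicable"`.
#' @export
classify_ptc_mode <- function(model, genome, variant, chain) {
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  minus <- model$strand[1] == "-"
  canon <- make_isoform(model)
  ctx <- build_mature_transcript(model, genome, introns = canon,
                                 variant = variant)
  start_g <- if (minus) ce - 1L else cs
  stop_g <- if (minus) cs + 2L else ce - 3L
  corf <- scan_orf(ctx$seq, ctx$genome2tx(start_g), ctx$genome2tx(stop_g))
  if (identical(corf$ptc_status, "posterior_to_canonical")) {
    return("posterior_stop")
  }
  if (!identical(corf$ptc_status, "premature")) return("not_applicable")
  ptc_g <- ctx$tx2genome(corf$first_stop_pos)
  if (is.na(ptc_g)) {
    # PTC starts inside inserted bases; anchor at the variant position
    ptc_g <- variant$pos
  }
  ex <- exon_intervals(model)
  exon_of <- function(p) {
    w <- which(ex$exon_start <= p & p < ex$exon_end)
    if (length(w)) w[1] else NA_integer_
  }
  ptc_exon <- exon_of(ptc_g)
  indel_exon <- exon_of(variant$pos)
  same_exon <- !is.na(ptc_exon) && !is.na(indel_exon) &&
    ptc_exon == indel_exon

  wholly_skipped <- purrr::map_lgl(seq_along(ex$exon_start), function(i) {
    any(chain$intron_start <= ex$exon_start[i] &
          chain$intron_end >= ex$exon_end[i])
  })
  ptc_excised <- any(chain$intron_start <= ptc_g & ptc_g < chain$intron_end)
  category <- if (ptc_excised) {
    if (!is.na(ptc_exon) && wholly_skipped[ptc_exon]) "skip" else "novel"
  } else {
    upstream_skip <- if (any(wholly_skipped)) {
      skipped_idx <- which(wholly_skipped)
      if (minus) {
        any(ex$exon_start[skipped_idx] >= ptc_g)
      } else {
        any(ex$exon_end[skipped_idx] <= ptc_g)
      }
    } else FALSE
    if (upstream_skip) "upstream_skip" else "compensated"
  }
  key <- paste(if (same_exon) "same" else "diff", category)
  c("same skip" = "A", "same novel" = "B", "same compensated" = "C",
    "same upstream_skip" = "D", "diff skip" = "E", "diff novel" = "F",
    "diff compensated" = "G", "diff upstream_skip" = "H")[[key]]
}

#' Call rescue for every variant against every candidate isoform
#'
#' For each variant of each gene, builds the single-novel-junction isoform
#' of every non-canonical junction in the catalogue (plus any explicitly
#' supplied chains) and returns one rescue call per (variant, isoform).
#'
#' @param models Gene-model tibble.
#' @param genome Named `DNAStringSet`.
#' @param variants Variant tibble (see [variant_spec()]); a `gene_id`
#'   column, if absent, is derived by locating each variant in a gene span.
#' @param catalog Classified junction catalogue (see
#'   [classify_junctions()]).
#' @return Tibble of rescue calls, one row per (variant, junction).
#' @export
call_rescue_all <- function(models, genome, variants, catalog) {
  spans <- gene_spans(models)
  if (!"gene_id" %in% names(variants)) {
    variants$gene_id <- purrr::map2_chr(variants$chrom, variants$pos,
                                        function(ch, p) {
      hit <- spans |> dplyr::filter(.data$chrom == ch, .data$tx_start <= p,
                                    p < .data$tx_end)
      if (nrow(hit)) hit$gene_id[1] else NA_character_
    })
  }
  nc <- catalog |> dplyr::filter(!.data$canonical, !is.na(.data$gene_id))
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (is.na(v$gene_id)) next
    model <- models |> dplyr::filter(.data$gene_id == v$gene_id)
    jset <- nc |> dplyr::filter(.data$gene_id == v$gene_id) |>
      distinct(.data$intron_start, .data$intron_end, .keep_all = TRUE)
    for (k in seq_len(nrow(jset))) {
      chain <- make_isoform(model, jset[k, ])
      call <- call_rescue(model, genome, v, chain)
      call$intron_start <- jset$intron_start[k]
      call$intron_end <- jset$intron_end[k]
      rows[[length(rows) + 1]] <- call
    }
  }
  list_rbind(rows)
}
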