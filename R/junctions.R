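#' Read a junction evidence table
#'
#' Expects a TSV with columns `chrom`, `intron_start`, `intron_end`,
#' `strand`, `sample_id`, `condition`, `read_count` (0-based half-open
#' intron coordinates, as produced by converting aligner junction output).
#'
#' @param path Path to the TSV file.
#' @return A tibble of junction evidence.
#' @export
read_junction_table <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("chrom", "intron_start", "intron_end", "strand",
              "sample_id", "condition", "read_count")
  missing <- setdiff(needed, names(ev))
  if (length(missing) > 0) {
    abort(paste0("junction table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(ev$read_count < 0)) abort("negative read_count")
  ev
}

#' Assign junctions to genes
#'
#' Each junction is assigned to the same-chromosome, same-strand gene whose
#' CDS span overlaps its intron the most; junctions overlapping no gene span
#' are flagged `intergenic`. Ties in CDS overlap are flagged.
#'
#' @param junctions Tibble with `chrom`, `intron_start`, `intron_end`,
#'   `strand`.
#' @param models Gene-model tibble.
#' @return `junctions` with `gene_id`, `intergenic` and `gene_tie` columns.
#' @export
assign_junction_gene <- function(junctions, models) {
  spans <- gene_spans(models)
  res <- pmap(list(junctions$chrom, junctions$intron_start,
                   junctions$intron_end, junctions$strand),
              function(ch, s, e, st) {
    cand <- spans |>
      dplyr::filter(.data$chrom == ch, .data$strand == st,
                    .data$tx_start < e, .data$tx_end > s)
    if (nrow(cand) == 0) {
      return(tibble(gene_id = NA_character_, intergenic = TRUE,
                    gene_tie = FALSE))
    }
    ov <- pmin(cand$cds_end, e) - pmax(cand$cds_start, s)
    ov[is.na(ov)] <- 0
    ov <- pmax(ov, 0)
    best <- which(ov == max(ov))
    tibble(gene_id = cand$gene_id[best[1]], intergenic = FALSE,
           gene_tie = length(best) > 1)
  })
  dplyr::bind_cols(junctions, list_rbind(res))
}

#' Classify a junction as canonical or non-canonical
#'
#' A junction is canonical when its intron interval exactly matches an
#' annotated intron of the gene model.
#'
#' @param junctions Tibble with `intron_start`, `intron_end` (and
#'   optionally `chrom`, `strand`).
#' @param model Gene-model tibble for one gene.
#' @return Logical vector, `TRUE` for canonical.
#' @export
classify_canonical <- function(junctions, model) {
  ci <- intron_intervals(model)
  paste(junctions$intron_start, junctions$intron_end) %in%
    paste(ci$start, ci$end)
}

#' Structural frame delta of junctions against one gene model
#'
#' The delta is the change, in nucleotides, of the mature-transcript exonic
#' length when the junction's intron replaces the canonical introns it
#' overlaps. It is computed by set arithmetic on the affected genomic
#' window: `delta = retained_under_junction - retained_under_annotation`,
#' where the window is the union of the junction's intron with every
#' overlapping annotated intron. Canonical junctions get delta 0; a junction
#' lying entirely inside one exon (exitron-like) loses its whole intron
#' length. `frame_class` is `"non-3n"` iff `delta_nt %% 3 != 0`.
#'
#' @param junctions Tibble with `intron_start`, `intron_end`.
#' @param model Gene-model tibble for one gene.
#' @param cds_only When `TRUE`, only bases inside the annotated CDS span
#'   count toward the delta (used by the rescue caller, where only coding
#'   bases can shift the reading frame).
#' @return A tibble with columns `delta_nt` (integer) and `frame_class`
#'   (`"3n"` or `"non-3n"`).
#' @export
junction_frame_delta <- function(junctions, model, cds_only = FALSE) {
  ci <- intron_intervals(model)
  ex <- exon_intervals(model)
  lo <- if (cds_only) model$cds_start[1] else -Inf
  hi <- if (cds_only) model$cds_end[1] else Inf
  clip_len <- function(s, e) max(0, min(e, hi) - max(s, lo))
  delta <- purrr::map2_int(junctions$intron_start, junctions$intron_end,
                           function(s, e) {
    ov <- ci$start < e & ci$end > s
    ws <- min(s, ci$start[ov]); we <- max(e, ci$end[ov])
    # bases of the window kept when splicing with this junction
    kept_alt <- clip_len(ws, s) + clip_len(e, we)
    # bases of the window kept under the annotation (exonic bases)
    aa <- pmax(ex$exon_start, ws); bb <- pmin(ex$exon_end, we)
    kept_ann <- sum(vapply(seq_along(aa), function(i) {
      if (bb[i] > aa[i]) clip_len(aa[i], bb[i]) else 0
    }, numeric(1)))
    as.integer(kept_alt - kept_ann)
  })
  tibble(delta_nt = delta,
         frame_class = if_else(delta %% 3L == 0L, "3n", "non-3n"))
}

#' Classify the alternative-splicing event type of non-canonical junctions
#'
#' Labels follow the standard event taxonomy: `SE_single`/`SE_multi` when the
#' junction's intron wholly contains one/several annotated exons with both
#' junction ends at annotated splice sites; `A5E`/`A5S` when only the donor
#' deviates (novel donor inside a canonical intron = exon extension, inside
#' an exon = exon shortening); `A3E`/`A3S` likewise for the acceptor; `MXE`
#' only when a partner junction with a disjoint skipped exon and an
#' overlapping intron exists in `catalog`; anything else (including
#' exitron-like junctions and junctions with both ends in canonical introns)
#' is `other`.
#'
#' @param junctions Tibble with `intron_start`, `intron_end`.
#' @param model Gene-model tibble for one gene.
#' @param catalog Optional tibble of all junctions of the gene, used for
#'   mutually-exclusive-exon detection; single junctions are never `MXE`.
#' @return Character vector of event labels.
#' @export
classify_as_event <- function(junctions, model, catalog = NULL) {
  ci <- intron_intervals(model)
  ex <- exon_intervals(model)
  minus <- model$strand[1] == "-"
  base <- purrr::map2_chr(junctions$intron_start, junctions$intron_end,
                          function(s, e) {
    event_label_one(s, e, ci, ex, minus)
  })
  if (!is.null(catalog) && nrow(catalog) > 1) {
    skipped <- purrr::map2(catalog$intron_start, catalog$intron_end,
                           function(s, e) {
      which(ex$exon_start > s & ex$exon_end < e)
    })
    cat_lab <- purrr::map2_chr(catalog$intron_start, catalog$intron_end,
                               function(s, e) {
      event_label_one(s, e, ci, ex, minus)
    })
    is_mxe <- function(s, e, sk) {
      if (length(sk) == 0) return(FALSE)
      any(purrr::pmap_lgl(
        list(catalog$intron_start, catalog$intron_end, skipped, cat_lab),
        function(s2, e2, sk2, lab2) {
          lab2 %in% c("SE_single", "SE_multi") &&
            length(sk2) > 0 && !any(sk2 %in% sk) &&
            s2 < e && e2 > s && !(s2 == s && e2 == e)
        }
      ))
    }
    for (i in seq_len(nrow(junctions))) {
      if (base[i] %in% c("SE_single", "SE_multi")) {
        sk <- which(ex$exon_start > junctions$intron_start[i] &
                      ex$exon_end < junctions$intron_end[i])
        if (is_mxe(junctions$intron_start[i], junctions$intron_end[i], sk)) {
          base[i] <- "MXE"
        }
      }
    }
  }
  base
}

event_label_one <- function(s, e, ci, ex, minus) {
  donors <- if (minus) ci$end else ci$start
  acceptors <- if (minus) ci$start else ci$end
  jd <- if (minus) e else s
  ja <- if (minus) s else e
  donor_ok <- jd %in% donors
  acceptor_ok <- ja %in% acceptors
  inside_exons <- sum(ex$exon_start > s & ex$exon_end < e)
  if (inside_exons > 0) {
    if (donor_ok && acceptor_ok) {
      return(if (inside_exons == 1) "SE_single" else "SE_multi")
    }
    return("other")
  }
  if (donor_ok && acceptor_ok) return("other")  # non-canonical recombination
  in_intron <- function(p) any(ci$start < p & p < ci$end)
  in_exon <- function(p) any(ex$exon_start < p & p < ex$exon_end)
  if (acceptor_ok && !donor_ok) {
    if (in_intron(jd)) return("A5E")
    if (in_exon(jd)) return("A5S")
    return("other")
  }
  if (donor_ok && !acceptor_ok) {
    if (in_intron(ja)) return("A3E")
    if (in_exon(ja)) return("A3S")
    return("other")
  }
  "other"
}

#' Classify a junction catalogue against gene models
#'
#' Convenience wrapper: assigns genes, then per gene adds `canonical`,
#' `delta_nt`, `frame_class` and `event` columns. Intergenic junctions are
#' retained with `canonical = FALSE` and `event = NA`.
#'
#' @param junctions Junction tibble (`chrom`, `intron_start`, `intron_end`,
#'   `strand`, optionally `gene_id`).
#' @param models Gene-model tibble.
#' @param detect_mxe Detect mutually exclusive exon pairs within each gene.
#' @return The classified catalogue tibble.
#' @export
classify_junctions <- function(junctions, models, detect_mxe = FALSE) {
  if (!"gene_id" %in% names(junctions) || anyNA(junctions$gene_id)) {
    junctions <- assign_junction_gene(
      junctions |> select(-dplyr::any_of(c("gene_id", "intergenic",
                                           "gene_tie"))),
      models)
  }
  if (!"intergenic" %in% names(junctions)) {
    junctions$intergenic <- is.na(junctions$gene_id)
  }
  parts <- junctions |>
    dplyr::group_split(.data$gene_id, .keep = TRUE)
  out <- purrr::map(parts, function(jg) {
    gid <- jg$gene_id[1]
    if (is.na(gid)) {
      jg$canonical <- FALSE
      jg$delta_nt <- NA_integer_
      jg$frame_class <- NA_character_
      jg$event <- NA_character_
      return(jg)
    }
    model <- models |> dplyr::filter(.data$gene_id == gid)
    jg$canonical <- classify_canonical(jg, model)
    fd <- junction_frame_delta(jg, model)
    jg$delta_nt <- fd$delta_nt
    jg$frame_class <- fd$frame_class
    jg$event <- NA_character_
    nc <- !jg$canonical
    if (any(nc)) {
      jg$event[nc] <- classify_as_event(
        jg[nc, ], model,
        catalog = if (detect_mxe) jg[nc, ] else NULL)
    }
    jg
  })
  list_rbind(out)
}

#' Keep junctions replicated across samples
#'
#' Retains junctions observed with at least one read in `k` or more distinct
#' samples.
#'
#' @param evidence Junction evidence tibble with `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `sample_id`, `read_count`.
#' @param k Minimum number of distinct samples (>= 1).
#' @return The subset of distinct junctions passing the filter.
#' @export
replication_filter <- function(evidence, k) {
  stopifnot(k >= 1)
  evidence |>
    dplyr::filter(.data$read_count > 0) |>
    group_by(.data$chrom, .data$intron_start, .data$intron_end,
             .data$strand) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample_id),
              .groups = "drop") |>
    dplyr::filter(.data$n_samples >= k)
}
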