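#' Type gene regions by splicing behaviour
#'
#' Partitions every exonic base of a gene into one region class — `CE`
#' (canonical exon, no non-canonical end), `UE` (unaffected part of an
#' affected exon), `SE` (skipped exon), `A5S`/`A3S` (shortened exon part) —
#' and labels intronic bases adjacent to non-canonical events as
#' `A5E`/`A3E` (intronic extension converted to exon) or `UI` (unaffected
#' intronic part of an affected intron). Overlapping events are resolved by
#' precedence (`SE` > `A5S`/`A3S` > `UE` for exonic bases; `A5E`/`A3E` >
#' `UI` for intronic bases); conflicts are reported via a message.
#'
#' @param model Gene-model tibble for one gene.
#' @param catalog Classified non-canonical junctions of the gene (needs
#'   `intron_start`, `intron_end`, `event`).
#' @return Tibble `gene_id`, `start`, `end`, `region_class` (0-based
#'   half-open, disjoint intervals).
#' @export
type_regions <- function(model, catalog) {
  ex <- exon_intervals(model)
  ci <- intron_intervals(model)
  span <- c(min(model$exon_start), max(model$exon_end))
  n <- span[2] - span[1]
  # per-base labels over the gene span; position i (0-based offset)
  lab <- rep(NA_character_, n)
  pr <- rep(0L, n)  # precedence of current label
  idx <- function(s, e) {
    s <- max(s, span[1]); e <- min(e, span[2])
    if (e <= s) return(integer(0))
    seq.int(s - span[1] + 1L, e - span[1])
  }
  assign_lab <- function(s, e, label, precedence) {
    ii <- idx(s, e)
    conflict <- !is.na(lab[ii]) & lab[ii] != label & pr[ii] >= precedence
    if (any(conflict)) {
      inform(paste0("region conflict at ", sum(conflict), " base(s): ",
                    label, " vs ", paste(unique(lab[ii][conflict]),
                                         collapse = "/")))
    }
    take <- precedence > pr[ii]
    lab[ii[take]] <<- label
    pr[ii[take]] <<- precedence
  }
  # baseline: exons CE (precedence 1), introns untouched
  n_ex <- length(ex$exon_start)
  n_ci <- length(ci$start)
  for (i in seq_len(n_ex)) assign_lab(ex$exon_start[i], ex$exon_end[i],
                                      "CE", 1L)
  affected_exon <- rep(FALSE, n_ex)
  affected_intron <- rep(FALSE, n_ci)
  cat_nc <- catalog |> dplyr::filter(is.na(.data$event) |
                                       .data$event != "canonical")
  for (k in seq_len(nrow(cat_nc))) {
    s <- cat_nc$intron_start[k]; e <- cat_nc$intron_end[k]
    ev <- cat_nc$event[k]
    ovi <- which(ci$start < e & ci$end > s)
    affected_intron[ovi] <- TRUE
    touched <- which(ex$exon_start < e & ex$exon_end > s |
                       ex$exon_end == s | ex$exon_start == e)
    affected_exon[touched] <- TRUE
    if (isTRUE(ev %in% c("SE_single", "SE_multi", "MXE"))) {
      inside <- which(ex$exon_start >= s & ex$exon_end <= e)
      for (i in inside) assign_lab(ex$exon_start[i], ex$exon_end[i],
                                   "SE", 4L)
    } else if (isTRUE(ev %in% c("A5S", "A3S"))) {
      # shortened exonic part: exonic bases inside the junction's intron
      for (i in seq_len(n_ex)) {
        a <- max(ex$exon_start[i], s); b <- min(ex$exon_end[i], e)
        if (b > a) assign_lab(a, b, ev, 3L)
      }
    } else if (isTRUE(ev %in% c("A5E", "A3E"))) {
      # intronic extension: canonical-intronic bases flanking the novel
      # intron within the overlapped canonical intron
      for (i in ovi) {
        if (s > ci$start[i]) assign_lab(ci$start[i], s, ev, 3L)
        if (e < ci$end[i]) assign_lab(e, ci$end[i], ev, 3L)
      }
    } else {
      # 'other' events still mark their exons/introns as affected
      for (i in seq_len(n_ex)) {
        a <- max(ex$exon_start[i], s); b <- min(ex$exon_end[i], e)
        if (b > a) assign_lab(a, b, "UE", 2L)
      }
    }
  }
  # unaffected parts of affected exons -> UE; affected introns' remaining
  # bases -> UI
  for (i in which(affected_exon)) {
    assign_lab(ex$exon_start[i], ex$exon_end[i], "UE", 2L)
  }
  for (i in which(affected_intron)) {
    ii <- idx(ci$start[i], ci$end[i])
    fill <- is.na(lab[ii])
    lab[ii[fill]] <- "UI"
    pr[ii[fill]] <- 1L
  }
  # collapse the per-base labelling to intervals
  r <- rle(ifelse(is.na(lab), ".", lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != "."
  tibble(gene_id = model$gene_id[1],
         start = as.integer(span[1] + starts[keep]),
         end = as.integer(span[1] + ends[keep]),
         region_class = r$values[keep])
}
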