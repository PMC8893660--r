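#' Build the isoform intron chain containing given novel junctions
#'
#' The chain consists of all canonical introns that do not overlap any of
#' the novel junctions, plus the novel junctions themselves — i.e. the
#' isoform is spliced canonically everywhere except where a novel junction
#' locally replaces the annotation.
#'
#' @param model Gene-model tibble for one gene.
#' @param novel Optional tibble of novel junctions (`intron_start`,
#'   `intron_end`); `NULL` gives the canonical chain.
#' @return Tibble of introns (`intron_start`, `intron_end`), genomic order.
#' @export
make_isoform <- function(model, novel = NULL) {
  ci <- intron_intervals(model)
  chain <- tibble(intron_start = ci$start, intron_end = ci$end)
  if (!is.null(novel) && nrow(novel) > 0) {
    keep <- purrr::map2_lgl(chain$intron_start, chain$intron_end,
                            function(s, e) {
      !any(novel$intron_start < e & novel$intron_end > s)
    })
    chain <- bind_rows(chain[keep, ],
                       novel |> select("intron_start", "intron_end"))
  }
  chain <- chain |> arrange(.data$intron_start)
  if (nrow(chain) > 1 &&
      any(chain$intron_start[-1] < chain$intron_end[-nrow(chain)])) {
    abort("isoform junction chain has overlapping introns")
  }
  chain
}

#' Build a mature transcript sequence with coordinate maps
#'
#' Constructs the mature transcript implied by an intron chain: the gene's
#' transcription span minus all chain introns, with an optional variant
#' applied by sequence replacement when its reference bases survive
#' excision. A variant whose reference interval is only partially retained
#' is partially applied (retained reference bases are removed, the
#' alternative allele is not inserted) and flagged `boundary_spanning`.
#'
#' @param model Gene-model tibble for one gene.
#' @param genome Named `DNAStringSet`.
#' @param introns Intron chain tibble (`intron_start`, `intron_end`);
#'   default is the canonical chain.
#' @param variant Optional one-row tibble/list with `pos` (0-based genomic
#'   position of the first reference base), `ref` and `alt` (either may be
#'   the empty string; a pure insertion with `ref = ""` is placed before
#'   `pos`).
#' @return A list with elements `seq` (transcript-orientation sequence),
#'   `length`, `genome2tx` and `tx2genome` (1-based transcript coordinate
#'   maps, `NA` for excised/inserted bases), `variant_applied`,
#'   `boundary_spanning`.
#' @export
build_mature_transcript <- function(model, genome, introns = NULL,
                                    variant = NULL) {
  if (is.null(introns)) introns <- make_isoform(model)
  span <- c(min(model$exon_start), max(model$exon_end))
  # retained plus-strand segments: span minus chain introns
  segs <- clip_segments(span, introns)

  chrom <- model$chrom[1]
  # pieces: genomic pieces (a,b) or insertion pieces (seq)
  pieces <- lapply(seq_along(segs$s), function(i) {
    list(g = c(segs$s[i], segs$e[i]), ins = NULL)
  })
  variant_applied <- FALSE
  boundary_spanning <- FALSE
  if (!is.null(variant)) {
    pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
    rlen <- nchar(ref)
    if (rlen == 0) {
      # pure insertion before genomic position `pos`
      hit <- which(segs$s < pos & pos < segs$e)
      if (length(hit) == 1) {
        p <- pieces[[hit]]
        pieces <- append(pieces[-hit], list(
          list(g = c(p$g[1], pos), ins = NULL),
          list(g = NULL, ins = alt),
          list(g = c(pos, p$g[2]), ins = NULL)
        ), after = hit - 1)
        variant_applied <- TRUE
      }
    } else {
      retained <- sum(pmax(0, pmin(segs$e, pos + rlen) - pmax(segs$s, pos)))
      if (retained == rlen) {
        # fully retained: replace ref by alt (ref may span several segments
        # only when fully exonic across a junction is impossible here since
        # retained == rlen forces a single segment unless segments abut)
        new_pieces <- list()
        inserted <- FALSE
        for (p in pieces) {
          if (is.null(p$g)) { new_pieces <- c(new_pieces, list(p)); next }
          a <- p$g[1]; b <- p$g[2]
          if (b <= pos || a >= pos + rlen) {
            new_pieces <- c(new_pieces, list(p))
          } else {
            if (a < pos) {
              new_pieces <- c(new_pieces, list(list(g = c(a, pos),
                                                    ins = NULL)))
            }
            if (!inserted && nchar(alt) > 0) {
              new_pieces <- c(new_pieces, list(list(g = NULL, ins = alt)))
              inserted <- TRUE
            }
            if (b > pos + rlen) {
              new_pieces <- c(new_pieces,
                              list(list(g = c(pos + rlen, b), ins = NULL)))
            }
          }
        }
        pieces <- new_pieces
        variant_applied <- TRUE
      } else if (retained > 0) {
        # partially retained: drop retained ref bases, do not insert alt
        boundary_spanning <- TRUE
        new_pieces <- list()
        for (p in pieces) {
          if (is.null(p$g)) { new_pieces <- c(new_pieces, list(p)); next }
          a <- p$g[1]; b <- p$g[2]
          if (b <= pos || a >= pos + rlen) {
            new_pieces <- c(new_pieces, list(p))
          } else {
            if (a < pos) {
              new_pieces <- c(new_pieces, list(list(g = c(a, pos),
                                                    ins = NULL)))
            }
            if (b > pos + rlen) {
              new_pieces <- c(new_pieces,
                              list(list(g = c(pos + rlen, b), ins = NULL)))
            }
          }
        }
        pieces <- new_pieces
        variant_applied <- TRUE
      }
    }
  }
  pieces <- Filter(function(p) {
    (!is.null(p$g) && p$g[2] > p$g[1]) ||
      (!is.null(p$ins) && nchar(p$ins) > 0)
  }, pieces)
  piece_len <- vapply(pieces, function(p) {
    if (is.null(p$g)) nchar(p$ins) else as.integer(p$g[2] - p$g[1])
  }, integer(1))
  L <- sum(piece_len)
  offsets <- cumsum(c(0L, piece_len))[seq_along(pieces)]

  chrom_str <- as.character(genome[[chrom]])
  plus_seq <- paste0(vapply(pieces, function(p) {
    if (is.null(p$g)) p$ins else substr(chrom_str, p$g[1] + 1L, p$g[2])
  }, character(1)), collapse = "")
  minus <- model$strand[1] == "-"
  seq <- if (minus) revcomp(plus_seq) else plus_seq

  plus_g2t <- function(g) {
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]
      if (!is.null(p$g) && p$g[1] <= g && g < p$g[2]) {
        return(offsets[i] + (g - p$g[1]) + 1L)
      }
    }
    NA_integer_
  }
  plus_t2g <- function(t) {
    if (is.na(t) || t < 1 || t > L) return(NA_integer_)
    i <- findInterval(t - 1L, cumsum(c(0L, piece_len)),
                      rightmost.closed = FALSE)
    p <- pieces[[i]]
    if (is.null(p$g)) return(NA_integer_)
    as.integer(p$g[1] + (t - 1L - offsets[i]))
  }
  genome2tx <- if (minus) {
    function(g) { p <- plus_g2t(g); if (is.na(p)) NA_integer_ else L - p + 1L }
  } else plus_g2t
  tx2genome <- if (minus) {
    function(t) plus_t2g(L - t + 1L)
  } else plus_t2g

  list(seq = seq, length = L, genome2tx = genome2tx, tx2genome = tx2genome,
       variant_applied = variant_applied,
       boundary_spanning = boundary_spanning)
}

clip_segments <- function(span, introns) {
  s <- span[1]
  out_s <- integer(); out_e <- integer()
  n <- length(introns$intron_start)
  if (n > 0) {
    o <- order(introns$intron_start)
    ist <- introns$intron_start[o]; ien <- introns$intron_end[o]
    for (i in seq_len(n)) {
      is_ <- max(ist[i], span[1])
      ie_ <- min(ien[i], span[2])
      if (ie_ <= is_) next
      if (is_ > s) { out_s <- c(out_s, s); out_e <- c(out_e, is_) }
      s <- max(s, ie_)
    }
  }
  if (span[2] > s) { out_s <- c(out_s, s); out_e <- c(out_e, span[2]) }
  list(s = as.integer(out_s), e = as.integer(out_e))
}

#' Scan an open reading frame for its first stop codon
#'
#' Translates codon by codon from `cds_start_tx` and reports where the first
#' in-frame stop (TAA/TAG/TGA) falls relative to the mapped canonical stop.
#'
#' @param seq Transcript sequence (character scalar, transcript
#'   orientation).
#' @param cds_start_tx 1-based transcript position of the first CDS base.
#' @param canonical_stop_tx 1-based transcript position of the first base of
#'   the canonical stop codon (possibly `NA` when the canonical stop has
#'   been excised).
#' @return A list: `first_stop_pos` (transcript position of the first base
#'   of the first in-frame stop, `NA` if none), `canonical_stop_used`,
#'   `ptc_status` (`"none"`, `"premature"`, `"posterior_to_canonical"`, or
#'   `"canonical"`), `non_stop` flag.
#' @export
scan_orf <- function(seq, cds_start_tx, canonical_stop_tx) {
  L <- nchar(seq)
  if (is.na(cds_start_tx) || cds_start_tx < 1 || cds_start_tx > L) {
    return(list(first_stop_pos = NA_integer_, canonical_stop_used = FALSE,
                ptc_status = "none", non_stop = TRUE))
  }
  n_codons <- (L - cds_start_tx + 1L) %/% 3L
  first_stop <- NA_integer_
  if (n_codons > 0) {
    starts <- cds_start_tx + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit) > 0) first_stop <- starts[hit[1]]
  }
  if (is.na(first_stop)) {
    return(list(first_stop_pos = NA_integer_, canonical_stop_used = FALSE,
                ptc_status = "none", non_stop = TRUE))
  }
  used <- !is.na(canonical_stop_tx) && first_stop == canonical_stop_tx
  status <- if (used) {
    "canonical"
  } else if (is.na(canonical_stop_tx) || first_stop < canonical_stop_tx) {
    "premature"
  } else {
    "posterior_to_canonical"
  }
  list(first_stop_pos = first_stop, canonical_stop_used = used,
       ptc_status = status, non_stop = FALSE)
}
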