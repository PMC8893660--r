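# Independent brute-force oracles used across the test suite.
# These deliberately avoid the package's piece-table transcript machinery:
# the transcript is rebuilt with per-base character vectors and translated
# directly, so agreement with the fast callers is a genuine dual-route check.

# Mature transcript as per-base vectors: returns list(bases, gpos) in
# transcript orientation; inserted bases have gpos NA.
oracle_mature <- function(model, genome, chain, variant = NULL) {
  chrom <- model$chrom[1]
  span_s <- min(model$exon_start); span_e <- max(model$exon_end)
  gpos <- seq.int(span_s, span_e - 1L)
  bases <- strsplit(genome_seq(genome, chrom, span_s, span_e), "")[[1]]
  keep <- rep(TRUE, length(gpos))
  for (i in seq_len(nrow(chain))) {
    keep[gpos >= chain$intron_start[i] & gpos < chain$intron_end[i]] <- FALSE
  }
  ins_at <- NULL; ins_seq <- NULL
  if (!is.null(variant)) {
    rlen <- nchar(variant$ref)
    if (rlen == 0) {
      # insertion before pos, applied only when interior to a kept run
      i_left <- which(gpos == variant$pos - 1L)
      i_right <- which(gpos == variant$pos)
      if (length(i_left) && length(i_right) && keep[i_left] &&
            keep[i_right]) {
        ins_at <- variant$pos
        ins_seq <- variant$alt
      }
    } else {
      ref_idx <- which(gpos >= variant$pos & gpos < variant$pos + rlen)
      retained <- sum(keep[ref_idx])
      if (retained == rlen) {
        keep[ref_idx] <- FALSE
        if (nchar(variant$alt) > 0) {
          ins_at <- variant$pos
          ins_seq <- variant$alt
        }
      } else if (retained > 0) {
        keep[ref_idx] <- FALSE  # partial: drop retained ref, no alt
      }
    }
  }
  out_bases <- character(0); out_gpos <- integer(0)
  if (!is.null(ins_at)) {
    pre <- keep & gpos < ins_at
    post <- keep & gpos >= ins_at
    out_bases <- c(bases[pre], strsplit(ins_seq, "")[[1]], bases[post])
    out_gpos <- c(gpos[pre], rep(NA_integer_, nchar(ins_seq)), gpos[post])
  } else {
    out_bases <- bases[keep]
    out_gpos <- gpos[keep]
  }
  if (model$strand[1] == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    out_bases <- rev(unname(comp[out_bases]))
    out_gpos <- rev(out_gpos)
  }
  list(bases = out_bases, gpos = out_gpos)
}

# Brute-force rescue verdict: translate the mutant mature transcript from
# the annotated start; rescue iff the first in-frame stop codon's first
# base sits exactly on the canonical stop codon's first base.
oracle_verdict <- function(model, genome, chain, variant) {
  if (variant$kind == "indel" && variant$delta_nt %% 3L == 0L) {
    return("not_applicable")
  }
  span_s <- min(model$exon_start); span_e <- max(model$exon_end)
  if (variant$pos < span_s || variant$pos >= span_e) {
    return("not_applicable")
  }
  minus <- model$strand[1] == "-"
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  start_g <- if (minus) ce - 1L else cs
  stop_g <- if (minus) cs + 2L else ce - 3L
  first_stop <- function(chain, variant) {
    m <- oracle_mature(model, genome, chain, variant)
    st <- which(m$gpos == start_g)
    if (length(st) != 1) return(list(idx = NA, gpos = NA, m = m))
    i <- st
    while (i + 2L <= length(m$bases)) {
      codon <- paste(m$bases[i:(i + 2L)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        return(list(idx = i, gpos = m$gpos[i], m = m))
      }
      i <- i + 3L
    }
    list(idx = NA, gpos = NA, m = m)
  }
  if (variant$kind == "snv") {
    canon <- make_isoform(model)
    fsc <- first_stop(canon, variant)
    canon_idx <- which(fsc$m$gpos == stop_g)
    premature <- !is.na(fsc$idx) &&
      (length(canon_idx) != 1 || fsc$idx < canon_idx)
    if (!premature) return("not_applicable")
  }
  fs <- first_stop(chain, variant)
  if (!is.na(fs$idx) && !is.na(fs$gpos) && fs$gpos == stop_g) {
    "rescue"
  } else {
    "no_rescue"
  }
}

# independent exhaustive ordered-pair oracle, character-matrix based
oracle_pi <- function(haps, ancestral = NULL, cls = NULL) {
  m <- do.call(rbind, strsplit(toupper(haps$seq), ""))
  x <- haps$frequency
  anc <- if (!is.null(ancestral)) strsplit(toupper(ancestral), "")[[1]]
  class_of <- function(a, d) {
    key <- paste0(a, ">", d)
    map <- c("C>A" = "C:G->A:T", "G>T" = "C:G->A:T",
             "C>T" = "C:G->T:A", "G>A" = "C:G->T:A",
             "C>G" = "C:G->G:C", "G>C" = "C:G->G:C",
             "A>C" = "A:T->C:G", "T>G" = "A:T->C:G",
             "A>G" = "A:T->G:C", "T>C" = "A:T->G:C",
             "A>T" = "A:T->T:A", "T>A" = "A:T->T:A")
    unname(map[key])
  }
  total <- 0
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- m[i, ]; b <- m[j, ]
    cov <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    d <- 0
    for (s in which(cov & a != b)) {
      if (is.null(cls)) {
        d <- d + 1
      } else {
        der <- if (a[s] == anc[s]) b[s] else if (b[s] == anc[s]) a[s]
               else NA
        if (!is.na(der) && identical(class_of(anc[s], der), cls)) d <- d + 1
      }
    }
    total <- total + x[i] * x[j] * d / sum(cov)
  }
  total
}
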