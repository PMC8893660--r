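# the six ancestral->derived substitution classes, keyed by "anc>der"
SUBSTITUTION_CLASSES <- c(
  "C>A" = "C:G->A:T", "G>T" = "C:G->A:T",
  "C>T" = "C:G->T:A", "G>A" = "C:G->T:A",
  "C>G" = "C:G->G:C", "G>C" = "C:G->G:C",
  "A>C" = "A:T->C:G", "T>G" = "A:T->C:G",
  "A>G" = "A:T->G:C", "T>C" = "A:T->G:C",
  "A>T" = "A:T->T:A", "T>A" = "A:T->T:A"
)

#' Substitution class labels
#' @return Character vector of the six class labels.
#' @export
substitution_classes <- function() unique(unname(SUBSTITUTION_CLASSES))

#' Frequency-weighted Nei-Li nucleotide diversity
#'
#' Computes `pi = sum_i sum_j x_i x_j pi_ij` over ordered pairs of aligned
#' haplotypes, where `pi_ij` is the per-site number of nucleotide
#' differences between haplotypes i and j (per covered site: alignment
#' columns holding a gap or N in either sequence are excluded from that
#' pair's comparison). With a `group` column holding exactly two groups,
#' the between-group mode uses ordered cross-group pairs only, with
#' frequencies normalised within each group. When `substitution_class` is
#' given, only differences of that ancestral-oriented class are counted; a
#' difference is classifiable when exactly one of the two bases equals the
#' ancestral base at that site.
#'
#' @param haplotypes Tibble with `seq` (equal-length aligned sequences) and
#'   `frequency`; optionally `group` (two levels for between-group mode).
#' @param ancestral Ancestral sequence (required for class-restricted
#'   diversity).
#' @param substitution_class One of [substitution_classes()], or `NULL`
#'   for unrestricted diversity.
#' @return Numeric per-site diversity.
#' @export
nei_li_pi <- function(haplotypes, ancestral = NULL,
                      substitution_class = NULL) {
  seqs <- toupper(haplotypes$seq)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) abort("haplotypes must be equal length")
  if (!is.null(ancestral) && nchar(ancestral) != lens[1]) {
    abort("ancestral sequence length mismatch")
  }
  if (!is.null(substitution_class) && is.null(ancestral)) {
    abort("class-restricted diversity requires an ancestral sequence")
  }
  x <- haplotypes$frequency
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  anc <- if (!is.null(ancestral)) strsplit(toupper(ancestral), "")[[1]]
  pij <- function(i, j) {
    a <- mat[i, ]; b <- mat[j, ]
    covered <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(covered)) return(0)
    diffs <- covered & a != b
    if (!is.null(substitution_class)) {
      der <- ifelse(a == anc, b, ifelse(b == anc, a, NA))
      key <- paste0(anc, ">", der)
      cls <- unname(SUBSTITUTION_CLASSES[key])
      diffs <- diffs & !is.na(der) & !is.na(cls) & cls == substitution_class
    }
    sum(diffs) / sum(covered)
  }
  if ("group" %in% names(haplotypes) &&
      dplyr::n_distinct(haplotypes$group) == 2) {
    gs <- unique(haplotypes$group)
    i1 <- which(haplotypes$group == gs[1])
    i2 <- which(haplotypes$group == gs[2])
    x1 <- x[i1] / sum(x[i1]); x2 <- x[i2] / sum(x[i2])
    total <- 0
    for (a in seq_along(i1)) for (b in seq_along(i2)) {
      total <- total + x1[a] * x2[b] * pij(i1[a], i2[b])
    }
    return(total)
  }
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) total <- total + x[i] * x[j] * pij(i, j)
  }
  total
}

#' Base-content-corrected diversity
#'
#' Divides a class-restricted diversity by the fraction of region bases
#' able to undergo that class of change: GC content for `C:G->*` classes,
#' AT content for `A:T->*` classes.
#'
#' @param pi Per-site diversity (from [nei_li_pi()]).
#' @param region_seq Nucleotide sequence of the region.
#' @param substitution_class One of [substitution_classes()].
#' @return List with `pi_corrected`, `content`; `content = 0` yields `NA`
#'   with a warning.
#' @export
corrected_pi <- function(pi, region_seq, substitution_class) {
  bases <- strsplit(toupper(region_seq), "")[[1]]
  acgt <- bases[bases %in% c("A", "C", "G", "T")]
  relevant <- if (startsWith(substitution_class, "C:G")) {
    c("C", "G")
  } else {
    c("A", "T")
  }
  content <- sum(acgt %in% relevant) / length(acgt)
  if (is.nan(content) || content == 0) {
    warn("region has no bases of the relevant content class")
    return(list(pi_corrected = NA_real_, content = content))
  }
  list(pi_corrected = pi / content, content = content)
}

#' Per-class corrected diversity of one region
#'
#' Convenience wrapper: class-restricted Nei-Li diversity for all six
#' substitution classes, each corrected by the matching base content of
#' the region.
#'
#' @inheritParams nei_li_pi
#' @param region_seq Region sequence used for the content correction
#'   (defaults to the ancestral sequence).
#' @return A tibble with one row per substitution class: `pi`, `content`,
#'   `pi_corrected`.
#' @export
diversity_by_class <- function(haplotypes, ancestral,
                               region_seq = ancestral) {
  purrr::map(substitution_classes(), function(cl) {
    pi <- nei_li_pi(haplotypes, ancestral, cl)
    cp <- suppressWarnings(corrected_pi(pi, region_seq, cl))
    tibble(substitution_class = cl, pi = pi, content = cp$content,
           pi_corrected = cp$pi_corrected)
  }) |>
    list_rbind()
}
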