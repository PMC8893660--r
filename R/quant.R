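#' Junction region depth
#'
#' The junction region of a junction is its intron interval; the region
#' depth is the summed read count of all junctions (itself included) whose
#' intron overlaps that interval, within one sample.
#'
#' @param junction One-row tibble with `intron_start`, `intron_end`.
#' @param evidence Junction evidence tibble restricted to one sample and
#'   gene, with `intron_start`, `intron_end`, `read_count`.
#' @return Integer total depth (0 propagates an undefined relative level).
#' @export
junction_region_depth <- function(junction, evidence) {
  ov <- evidence$intron_start < junction$intron_end &
    evidence$intron_end > junction$intron_start
  sum(evidence$read_count[ov])
}

#' Relative level of a junction within its region
#'
#' `reads / junction region depth`; `NA` when the region depth is zero.
#'
#' @inheritParams junction_region_depth
#' @return Fraction in `[0, 1]`, or `NA` for an empty region.
#' @export
relative_level <- function(junction, evidence) {
  depth <- junction_region_depth(junction, evidence)
  own <- evidence |>
    dplyr::filter(.data$intron_start == junction$intron_start,
                  .data$intron_end == junction$intron_end)
  reads <- sum(own$read_count)
  if (depth == 0) return(NA_real_)
  reads / depth
}

#' Relative levels for a whole evidence table
#'
#' Vectorised companion of [relative_level()]: computes region depth and
#' relative level for every junction, per sample and condition.
#'
#' @param evidence Junction evidence tibble (`chrom`, `intron_start`,
#'   `intron_end`, `strand`, `sample_id`, `condition`, `read_count`,
#'   optionally `gene_id`).
#' @return `evidence` with `region_depth` and `relative_level` columns.
#' @export
quantify_junctions <- function(evidence) {
  group_cols <- intersect(c("gene_id", "sample_id", "condition", "chrom"),
                          names(evidence))
  evidence |>
    group_by(across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(ev, key) {
      depth <- purrr::map2_dbl(ev$intron_start, ev$intron_end,
                               function(s, e) {
        sum(ev$read_count[ev$intron_start < e & ev$intron_end > s])
      })
      ev$region_depth <- as.integer(depth)
      ev$relative_level <- if_else(depth > 0, ev$read_count / depth,
                                   NA_real_)
      ev
    }) |>
    ungroup()
}

#' Mutant / wild-type relative-level ratio
#'
#' `R_mw = R_m / R_w`, the fold change in the relative level of a rescue
#' junction between mutant and wild type. `R_w = 0 < R_m` gives `Inf`
#' (junction absent in the wild type); `R_m = R_w = 0` is flagged
#' not-observed (`NA`).
#'
#' @param r_m,r_w Relative level(s) in mutant and wild type.
#' @return A tibble with `r_m`, `r_w`, `r_mw`, `increased`
#'   (`r_mw > 1`) and `observed`.
#' @export
compute_rmw <- function(r_m, r_w) {
  r_mw <- dplyr::case_when(
    r_m == 0 & r_w == 0 ~ NA_real_,
    r_w == 0 ~ Inf,
    TRUE ~ r_m / r_w
  )
  tibble(r_m = r_m, r_w = r_w, r_mw = r_mw,
         increased = !is.na(r_mw) & r_mw > 1,
         observed = !(r_m == 0 & r_w == 0))
}

#' Percent spliced-in of the exon node induced by a junction
#'
#' The differential exon node of a junction is the exonic region it
#' removes (skipped exon, shortened exon part) or the intronic region it
#' adds (exon extension). A local splice graph is built from all junctions
#' overlapping the junction's region; its splicing paths are the sets of
#' pairwise non-overlapping junctions whose introns jointly cover every
#' canonical intron of the region (intron retention is not modelled). Each
#' path is supported by the mean read count of its junctions, and PSI is
#' the proportional support of the paths whose mature transcript contains
#' the node. With no exclusion-path evidence PSI is 1, flagged
#' low-confidence.
#'
#' @param junction One-row junction tibble (`intron_start`, `intron_end`).
#' @param evidence Junction evidence for one sample/gene (with
#'   `read_count`).
#' @param model Gene-model tibble for the gene.
#' @return A one-row tibble with `node_start`, `node_end`, `psi`,
#'   `low_confidence`.
#' @export
compute_psi <- function(junction, evidence, model) {
  node <- junction_node(junction, model)
  if (is.na(node$start)) {
    return(tibble(node_start = NA_integer_, node_end = NA_integer_,
                  psi = NA_real_, low_confidence = TRUE))
  }
  ov <- evidence |>
    dplyr::filter(.data$intron_start < node$window_end,
                  .data$intron_end > node$window_start) |>
    group_by(.data$intron_start, .data$intron_end) |>
    summarise(read_count = sum(.data$read_count), .groups = "drop") |>
    arrange(.data$intron_start)
  ci <- intron_intervals(model)
  keep_ci <- ci$start < node$window_end & ci$end > node$window_start
  paths <- enumerate_paths(ov$intron_start, ov$intron_end,
                           ci$start[keep_ci], ci$end[keep_ci])
  if (length(paths) == 0) {
    return(tibble(node_start = node$start, node_end = node$end,
                  psi = NA_real_, low_confidence = TRUE))
  }
  support <- vapply(paths, function(p) mean(ov$read_count[p]), numeric(1))
  includes_node <- vapply(paths, function(p) {
    !any(ov$intron_start[p] < node$end & ov$intron_end[p] > node$start)
  }, logical(1))
  inc <- sum(support[includes_node]); tot <- sum(support)
  if (tot == 0) {
    return(tibble(node_start = node$start, node_end = node$end,
                  psi = NA_real_, low_confidence = TRUE))
  }
  tibble(node_start = node$start, node_end = node$end,
         psi = inc / tot,
         low_confidence = !any(!includes_node & support > 0))
}

# all sets of pairwise non-overlapping junctions whose introns cover every
# canonical intron base of the region; returned as index vectors
enumerate_paths <- function(js, je, cs, ce) {
  n <- length(js)
  if (n == 0) return(list())
  res <- list()
  covered <- function(idx) {
    if (length(cs) == 0) return(TRUE)
    all(vapply(seq_along(cs), function(k) {
      ov <- pmax(js[idx], cs[k]) < pmin(je[idx], ce[k])
      pos_cover <- 0L
      # canonical intron k must be fully inside the union of path introns
      left <- cs[k]
      for (i in idx[order(js[idx])]) {
        if (js[i] <= left && je[i] > left) left <- je[i]
      }
      left >= ce[k]
    }, logical(1)))
  }
  grow <- function(idx, next_i) {
    if (next_i > n) {
      if (length(idx) > 0 && covered(idx)) res[[length(res) + 1L]] <<- idx
      return(invisible())
    }
    # skip junction next_i
    grow(idx, next_i + 1L)
    # take it if non-overlapping with current chain
    if (length(idx) == 0 ||
        !any(js[idx] < je[next_i] & je[idx] > js[next_i])) {
      grow(c(idx, next_i), next_i + 1L)
    }
  }
  grow(integer(0), 1L)
  res
}

# differential exon node of a junction: the exonic bases its intron removes,
# or, for pure extensions, the intronic bases it converts to exon
junction_node <- function(junction, model) {
  s <- junction$intron_start; e <- junction$intron_end
  ci <- intron_intervals(model)
  ex <- exon_intervals(model)
  ovi <- ci$start < e & ci$end > s
  ws <- min(s, ci$start[ovi]); we <- max(e, ci$end[ovi])
  # exonic bases inside the junction's intron
  a <- pmax(ex$exon_start, s); b <- pmin(ex$exon_end, e)
  keep <- b > a
  if (any(keep)) {
    return(list(start = min(a[keep]), end = max(b[keep]),
                window_start = ws, window_end = we))
  }
  # extension: canonical-intronic bases outside the junction's intron
  if (any(ovi)) {
    left <- min(ci$start[ovi])
    right <- max(ci$end[ovi])
    if (s > left) return(list(start = left, end = s,
                              window_start = ws, window_end = we))
    if (e < right) return(list(start = e, end = right,
                               window_start = ws, window_end = we))
  }
  list(start = NA_integer_, end = NA_integer_,
       window_start = ws, window_end = we)
}

#' Proportion of genes with a rescue junction, by read threshold
#'
#' For ascending read thresholds, the proportion of genes having at least
#' one rescue junction supported by that many reads. The curve is
#' monotonically non-increasing; its value at the largest threshold is the
#' asymptote estimate.
#'
#' @param rescue_reads Tibble with `gene_id` and `reads` (one row per
#'   rescue junction; genes may have several rows or none).
#' @param thresholds Ascending integer vector of minimum read counts.
#' @param n_genes Denominator: total genes assayed (defaults to the number
#'   of distinct genes present in `rescue_reads`).
#' @return A tibble with `threshold`, `n_genes_passing`, `proportion`, and
#'   attribute `asymptote`.
#' @export
prevalence_vs_threshold <- function(rescue_reads, thresholds,
                                    n_genes = NULL) {
  if (is.null(n_genes)) n_genes <- dplyr::n_distinct(rescue_reads$gene_id)
  if (n_genes == 0) abort("empty gene set")
  if (is.unsorted(thresholds)) abort("thresholds must be ascending")
  best <- rescue_reads |>
    group_by(.data$gene_id) |>
    summarise(max_reads = max(.data$reads), .groups = "drop")
  out <- tibble(
    threshold = thresholds,
    n_genes_passing = vapply(thresholds,
                             function(t) sum(best$max_reads >= t),
                             integer(1))
  ) |>
    mutate(proportion = .data$n_genes_passing / n_genes)
  attr(out, "asymptote") <- out$proportion[nrow(out)]
  class(out) <- c("sr_prevalence", class(out))
  out
}

#' Non-canonical to canonical junction depth ratio per gene
#'
#' Per gene: maximum read depth among non-canonical junctions divided by
#' the maximum read depth among canonical junctions; 0 when the gene has no
#' non-canonical junction, `NA` when it has no canonical reads. When a
#' `rescue` logical column is present, a `rescue_ratio` (maximum rescue
#' junction depth / canonical depth) is also reported.
#'
#' @param evidence Classified junction evidence with `gene_id`,
#'   `canonical`, `read_count`, optionally `rescue`.
#' @return Tibble `gene_id`, `canonical_depth`, `noncanonical_depth`,
#'   `ratio` (and `rescue_ratio` when applicable).
#' @export
noncanonical_to_canonical_ratio <- function(evidence) {
  has_rescue <- "rescue" %in% names(evidence)
  evidence |>
    group_by(.data$gene_id) |>
    summarise(
      canonical_depth = max(c(.data$read_count[.data$canonical], 0L)),
      noncanonical_depth = max(c(.data$read_count[!.data$canonical], 0L)),
      rescue_depth = if (has_rescue) {
        max(c(.data$read_count[!.data$canonical & .data$rescue], 0L))
      } else NA_integer_,
      .groups = "drop"
    ) |>
    mutate(
      ratio = if_else(.data$canonical_depth > 0,
                      .data$noncanonical_depth / .data$canonical_depth,
                      NA_real_),
      rescue_ratio = if_else(.data$canonical_depth > 0,
                             .data$rescue_depth / .data$canonical_depth,
                             NA_real_)
    ) |>
    (\(d) if (has_rescue) d else select(d, -"rescue_depth",
                                        -"rescue_ratio"))()
}
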