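#' Read a per-cytosine methylation report
#'
#' Cytosine-report style TSV with columns `chrom`, `pos`, `strand`,
#' `context` (`CpG`/`CHG`/`CHH`), `count_methylated`,
#' `count_unmethylated`, optionally `sample_id`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of cytosine calls.
#' @export
read_cytosine_report <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("chrom", "pos", "strand", "context", "count_methylated",
              "count_unmethylated")
  missing <- setdiff(needed, names(calls))
  if (length(missing) > 0) {
    abort(paste0("cytosine report lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  calls
}

#' Mean methylation level per region and context
#'
#' Per-site levels are `methylated / (methylated + unmethylated)`. Sites
#' with depth below `min_depth` are dropped; a region/context is discarded
#' (`NA`) when fewer than `min_coverage` of its cytosines are covered. The
#' region level is the mean of covered site levels, averaged across
#' samples when a `sample_id` column is present.
#'
#' @param calls Cytosine call tibble (see [read_cytosine_report()]); all
#'   cytosines of each context must be listed, covered or not.
#' @param regions Tibble with `chrom`, `start`, `end`, `region_class`
#'   (0-based half-open).
#' @param min_depth Minimum site depth (default 4).
#' @param min_coverage Minimum fraction of cytosines covered (default
#'   0.7).
#' @return Tibble `chrom`, `start`, `end`, `region_class`, `context`,
#'   `level` (`NA` for discarded regions), `n_sites`, `covered_fraction`.
#' @export
methylation_by_region <- function(calls, regions, min_depth = 4,
                                  min_coverage = 0.7) {
  has_samples <- "sample_id" %in% names(calls)
  if (!has_samples) calls$sample_id <- "sample1"
  out <- purrr::map(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    site <- calls |>
      dplyr::filter(.data$chrom == rg$chrom, .data$pos >= rg$start,
                    .data$pos < rg$end)
    site |>
      group_by(.data$context, .data$sample_id) |>
      summarise(n_sites = n(),
                covered_fraction = mean(
                  .data$count_methylated + .data$count_unmethylated >=
                    min_depth),
                level = {
                  depth <- .data$count_methylated +
                    .data$count_unmethylated
                  ok <- depth >= min_depth
                  if (!any(ok)) NA_real_ else {
                    mean(.data$count_methylated[ok] / depth[ok])
                  }
                },
                .groups = "drop") |>
      mutate(level = if_else(.data$covered_fraction < min_coverage,
                             NA_real_, .data$level)) |>
      group_by(.data$context) |>
      summarise(level = if (all(is.na(.data$level))) NA_real_ else {
                  mean(.data$level, na.rm = TRUE)
                },
                n_sites = .data$n_sites[1],
                covered_fraction = mean(.data$covered_fraction),
                .groups = "drop") |>
      mutate(chrom = rg$chrom, start = rg$start, end = rg$end,
             region_class = rg$region_class, .before = 1)
  })
  list_rbind(out)
}
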