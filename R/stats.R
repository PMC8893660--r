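#' Goodness of fit against the two-thirds noisy-splicing null
#'
#' Under random noisy splicing, 2/3 of novel junctions are expected to
#' change the reading frame (non-3n). This Pearson goodness-of-fit test
#' compares observed non-3n / 3n counts with expectation `(2n/3, n/3)`,
#' with 1 degree of freedom and no continuity correction.
#'
#' @param k_non3n Number of non-3n junctions.
#' @param n Total number of junctions (> 0).
#' @return An object of class `sr_gof` with elements `chi2`, `df`, `p`.
#' @export
chi2_gof_two_thirds <- function(k_non3n, n) {
  if (n <= 0) abort("n must be positive")
  if (k_non3n < 0 || k_non3n > n) abort("k_non3n must lie in [0, n]")
  expected <- c(2, 1) * n / 3
  observed <- c(k_non3n, n - k_non3n)
  chi2 <- sum((observed - expected)^2 / expected)
  new_gof(chi2, 1L, "two-thirds goodness of fit",
          observed = observed, expected = expected)
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Cells are given row-wise (`a b / c d`); Yates' continuity correction is
#' applied by default.
#'
#' @param a,b,c,d Non-negative cell counts; both margins must be positive.
#' @param continuity Apply Yates' correction (default `TRUE`).
#' @return An object of class `sr_gof`.
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = TRUE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(m < 0)) abort("negative cell count")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero margin in 2x2 table")
  }
  ht <- stats::chisq.test(m, correct = continuity)
  new_gof(unname(ht$statistic), 1L,
          paste0("2x2 chi-squared",
                 if (continuity) " (Yates)" else ""),
          observed = as.vector(m), expected = as.vector(ht$expected))
}

new_gof <- function(chi2, df, method, observed = NULL, expected = NULL) {
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 method = method, observed = observed,
                 expected = expected),
            class = "sr_gof")
}

#' @export
print.sr_gof <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  Chi-squared = %s, df = %d, P %s\n",
              format(signif(x$chi2, 4)), x$df, format_p(x$p)))
  invisible(x)
}

format_p <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else paste0("= ", format(signif(p, 2)))
}

#' @exportS3Method generics::tidy
tidy.sr_gof <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p, method = x$method)
}

#' @exportS3Method generics::glance
glance.sr_gof <- function(x, ...) tidy(x)

#' Summarise a classified junction catalogue
#'
#' Genome-wide style summary: distinct junction counts, genes with
#' junctions, alternatively spliced genes (with a non-canonical junction),
#' non-3n junctions, junctions per gene, and fold over the annotated
#' junction count.
#'
#' @param catalog Classified junction catalogue (see
#'   [classify_junctions()]).
#' @param models Gene-model tibble of the annotation.
#' @return A one-row tibble of summary statistics.
#' @export
summarize_catalog <- function(catalog, models) {
  jx <- catalog |>
    distinct(.data$chrom, .data$intron_start, .data$intron_end,
             .data$strand, .keep_all = TRUE)
  ann <- canonical_junctions(models)
  n_genes <- dplyr::n_distinct(models$gene_id)
  in_gene <- jx |> dplyr::filter(!is.na(.data$gene_id))
  tibble(
    n_junctions = nrow(in_gene),
    n_annotated_junctions = nrow(ann),
    n_noncanonical = sum(!in_gene$canonical),
    n_non3n = sum(in_gene$frame_class == "non-3n", na.rm = TRUE),
    n_genes = n_genes,
    n_genes_with_junctions = dplyr::n_distinct(in_gene$gene_id),
    n_alt_spliced_genes = dplyr::n_distinct(
      in_gene$gene_id[!in_gene$canonical]),
    junctions_per_gene = nrow(in_gene) / n_genes,
    fold_over_annotation = if (nrow(ann) > 0) {
      nrow(in_gene) / nrow(ann)
    } else NA_real_
  )
}
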