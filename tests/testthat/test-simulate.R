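test_that("generators are byte-identical under the same seed", {
  cfg <- sim_config(seed = 7, n_genes = 5,
                    intron_length_range = c(67, 300))
  s1 <- simulate_gene_models(cfg)
  s2 <- simulate_gene_models(cfg)
  expect_identical(s1$models, s2$models)
  expect_identical(as.character(s1$genome), as.character(s2$genome))

  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(s1$models, f1)
  write_gene_models(s2$models, f2)
  expect_identical(readLines(f1), readLines(f2))

  j1 <- simulate_noisy_junctions(s1$models, cfg, n_total = 50)
  j2 <- simulate_noisy_junctions(s2$models, cfg, n_total = 50)
  expect_identical(j1, j2)
  v1 <- inject_variants(s1$models, s1$genome, cfg)
  v2 <- inject_variants(s2$models, s2$genome, cfg)
  expect_identical(v1, v2)
  p1 <- simulate_haplotype_panel(cfg)
  p2 <- simulate_haplotype_panel(cfg)
  expect_identical(p1, p2)
})

test_that("generated introns respect the configured bounds", {
  cfg <- sim_config(seed = 13, n_genes = 8)
  sim <- simulate_gene_models(cfg)
  for (g in unique(sim$models$gene_id)) {
    m <- dplyr::filter(sim$models, gene_id == g)
    ci <- splicerescue:::intron_intervals(m)
    if (length(ci$start) == 0) next
    lens <- ci$end - ci$start
    expect_true(all(lens >= 67 & lens <= 3608))
  }
  jx <- simulate_noisy_junctions(sim$models, cfg, n_total = 300)
  jl <- jx$intron_end - jx$intron_start
  expect_true(all(jl >= 67 & jl <= 3608))
  # junctions stay within their gene bodies
  spans <- gene_spans(sim$models)
  jsp <- dplyr::left_join(jx, spans, by = c("gene_id", "chrom", "strand"))
  expect_true(all(jsp$intron_start >= jsp$tx_start &
                    jsp$intron_end <= jsp$tx_end))
})

test_that("a zero noisy rate leaves the catalogue canonical only", {
  cfg <- sim_config(seed = 14, n_genes = 3, noisy_per_gene = 0)
  sim <- simulate_gene_models(cfg)
  jx <- simulate_noisy_junctions(sim$models, cfg)
  full <- dplyr::bind_rows(
    canonical_junctions(sim$models)[
      c("gene_id", "chrom", "strand", "intron_start", "intron_end")],
    jx)
  cls <- classify_junctions(full, sim$models)
  expect_true(all(cls$canonical))
})

test_that("injected variants carry the requested frame phases", {
  cfg <- sim_config(seed = 15, n_genes = 8)
  sim <- simulate_gene_models(cfg)
  vars <- inject_variants(sim$models, sim$genome, cfg)
  expect_gt(nrow(vars), 0)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$phase == "snv") {
      expect_equal(v$delta_nt, 0)
      model <- dplyr::filter(sim$models, gene_id == v$gene_id)
      cc <- call_rescue(model, sim$genome, v, make_isoform(model))
      expect_equal(cc$ptc_status, "premature")
    } else {
      expect_equal(-v$delta_nt %% 3L,
                   switch(v$phase, "3n+1" = 1L, "3n+2" = 2L, "3n" = 0L))
      if (v$phase == "3n") {
        expect_equal(v$frame_class, "3n")
      }
    }
  }
})

test_that("multinomial read simulation recovers isoform proportions", {
  jx <- tibble::tibble(intron_start = c(100L, 100L, 100L),
                       intron_end = c(200L, 250L, 300L))
  set.seed(1)
  ev <- simulate_junction_reads(jx, c(0.95, 0.04, 0.01), 10000,
                                sample_id = "wt", condition = "WT")
  expect_equal(sum(ev$read_count), 10000)
  expect_lt(abs(ev$read_count[1] / 10000 - 0.95),
            3 * sqrt(0.95 * 0.05 / 10000))
  # depth 1 and depth 0 degenerate cases
  ev1 <- simulate_junction_reads(jx, c(0.5, 0.3, 0.2), 1)
  expect_equal(sum(ev1$read_count), 1)
  ev0 <- simulate_junction_reads(jx, c(0.5, 0.3, 0.2), 0)
  expect_equal(sum(ev0$read_count), 0)
})

test_that("haplotype panels have the configured shape and zero-rate limit", {
  cfg <- sim_config(seed = 16, panel_groups = 3, panel_size = 20,
                    panel_region_length = 200, panel_mutations = 0)
  panel <- simulate_haplotype_panel(cfg)
  expect_equal(dplyr::n_distinct(panel$haplotypes$group), 3)
  sums <- panel$haplotypes |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = sum(count), f = sum(frequency))
  expect_true(all(sums$n == 20))
  expect_true(all(abs(sums$f - 1) < 1e-12))
  # no mutations: every class diversity is zero
  for (cl in substitution_classes()) {
    expect_equal(nei_li_pi(panel$haplotypes, panel$ancestral, cl), 0)
  }
  expect_equal(nei_li_pi(panel$haplotypes), 0)
})

test_that("plot helpers return ggplot objects", {
  curve <- prevalence_vs_threshold(
    tibble::tibble(gene_id = c("g1", "g2"), reads = c(5L, 100L)),
    c(0, 10, 100))
  expect_s3_class(plot_prevalence_curve(curve), "ggplot")
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")

  fx <- bc10_fixture()
  cat <- classify_junctions(fx$skip_junction, fx$models)
  expect_s3_class(plot_frame_spectrum(cat), "ggplot")

  div <- tibble::tibble(region_class = c("SE", "CE"),
                        substitution_class = "C:G->A:T",
                        pi_corrected = c(0.01, 0.002))
  expect_s3_class(plot_region_diversity(div), "ggplot")
})

test_that("junction tables and VCFs round-trip through the readers", {
  ev <- tibble::tibble(chrom = "chr1", intron_start = c(10L, 40L),
                       intron_end = c(30L, 90L), strand = "+",
                       sample_id = "s1", condition = "WT",
                       read_count = c(3L, 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ev, path)
  expect_equal(as.data.frame(read_junction_table(path)),
               as.data.frame(ev))

  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t101\t.\tACT\tA\t.\tPASS\t.",
           "chr1\t201\t.\tG\tT\t.\tPASS\t.")
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, vp)
  vars <- read_variants(vp)
  expect_equal(vars$pos, c(100L, 200L))
  expect_equal(vars$kind, c("indel", "snv"))
  expect_equal(vars$delta_nt, c(-2L, 0L))
  expect_equal(vars$frame_class, c("non-3n", "3n"))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_junction_bed(dplyr::mutate(ev, reads = read_count), bed)
  lines <- readLines(bed)
  expect_equal(length(lines), 2)
  expect_equal(strsplit(lines[1], "\t")[[1]][2], "10")
})
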