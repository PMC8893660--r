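test_that("a -20 nt donor-shift junction rescues 3n+1 but not 3n+2 indels", {
  fx <- wda1_fixture()
  chain <- make_isoform(fx$models, fx$shift_junction)
  calls <- dplyr::bind_rows(lapply(fx$variants$name, function(nm) {
    v <- dplyr::filter(fx$variants, name == nm)
    dplyr::mutate(call_rescue(fx$models, fx$genome, v, chain), name = nm)
  }))
  expect_equal(calls$junction_delta, rep(-20, 4))
  rescued <- dplyr::filter(calls, name %in% c("del1", "del4", "del22"))
  expect_true(all(rescued$verdict == "rescue"))
  expect_true(all(rescued$net_delta_mod3 == 0))
  expect_true(all(rescued$canonical_stop_used))
  expect_true(all(rescued$form_class == "A_non3n_other"))
  ins <- dplyr::filter(calls, name == "ins1")
  expect_equal(ins$verdict, "no_rescue")
  expect_equal(ins$net_delta_mod3, (-20 + 1) %% 3)

  # under canonical splicing the same deletion is not rescued
  v <- dplyr::filter(fx$variants, name == "del1")
  cc <- call_rescue(fx$models, fx$genome, v, make_isoform(fx$models))
  expect_equal(cc$verdict, "no_rescue")
})

test_that("whole-exon skipping rescues indels inside a 3n exon", {
  bx <- bc10_fixture()
  chain <- make_isoform(bx$models, bx$skip_junction)
  calls <- dplyr::bind_rows(lapply(bx$variants$name, function(nm) {
    v <- dplyr::filter(bx$variants, name == nm)
    dplyr::mutate(call_rescue(bx$models, bx$genome, v, chain), name = nm)
  }))
  expect_true(all(calls$verdict == "rescue"))
  expect_true(all(calls$form_class == "A1_3n_exon_skip"))
  # the indel is excised with the exon, so it contributes no frame delta
  expect_true(all(calls$variant_delta == 0))
  expect_equal(calls$junction_delta, rep(-45, 3))
})

test_that("indel distances to the nearest splice site match the exon geometry", {
  bx <- bc10_fixture()
  d <- vapply(c("del5", "del1", "del22"), function(nm) {
    indel_distance_to_splice_site(dplyr::filter(bx$variants, name == nm),
                                  bx$models)
  }, integer(1))
  expect_equal(unname(d), c(14L, 17L, 6L))

  # an indel abutting the exon start has distance 0
  g <- toy_model(n_exons = 3)
  genome <- toy_genome(g)
  v <- variant_spec("chrT", 200, genome_seq(genome, "chrT", 200, 205), "")
  expect_equal(indel_distance_to_splice_site(v, g), 0L)
  # intronic variants are flagged
  vi <- variant_spec("chrT", 150, "C", "")
  expect_warning(di <- indel_distance_to_splice_site(vi, g), "not exonic")
  expect_true(is.na(di))
})

test_that("3n indels are not applicable to rescue analysis", {
  g <- toy_model(n_exons = 3)
  genome <- toy_genome(g)
  v <- variant_spec("chrT", 40, genome_seq(genome, "chrT", 40, 43), "")
  call <- call_rescue(g, genome, v, make_isoform(g))
  expect_equal(call$verdict, "not_applicable")
  # and a variant outside the gene span is not applicable either
  vo <- variant_spec("chrT", 40, "C", "")
  g2 <- gene_model("far", "chrT", "+", c(1000, 1200), c(1100, 1300),
                   1010, 1291)
  callo <- call_rescue(g2, genome, vo, make_isoform(g2))
  expect_equal(callo$verdict, "not_applicable")
})

test_that("a nonsense SNV is rescued by skipping its 3n exon", {
  bx <- bc10_fixture()
  model <- bx$models
  ex <- splicerescue:::exon_intervals(model)
  minus <- model$strand[1] == "-"
  e7 <- if (minus) length(ex$exon_start) - 6L else 7L
  pick <- list(a = ex$exon_start[e7] + 3L, b = ex$exon_end[e7] - 3L)
  set.seed(1)
  v <- splicerescue:::nonsense_snv(model, bx$genome, pick)
  expect_false(is.null(v))
  # under canonical splicing the SNV creates a PTC (no rescue)
  cc <- call_rescue(model, bx$genome, v, make_isoform(model))
  expect_equal(cc$ptc_status, "premature")
  expect_equal(cc$verdict, "no_rescue")
  # the exon-7 skip removes the PTC and preserves frame
  chain <- make_isoform(model, bx$skip_junction)
  cs <- call_rescue(model, bx$genome, v, chain)
  expect_equal(cs$verdict, "rescue")
  expect_equal(cs$ptc_mode, "A")  # PTC in the skipped exon, same exon
})

test_that("PTC modes distinguish excision, compensation and upstream skips", {
  fx <- wda1_fixture()
  model <- fx$models
  del1 <- dplyr::filter(fx$variants, name == "del1")
  chain <- make_isoform(model, fx$shift_junction)

  # engineer a PTC in the -1-shifted frame inside exon 3 (the indel's
  # exon), downstream of the deletion: mode C (PTC retained, frame
  # compensated by an upstream junction, no exon skipped)
  ctx <- build_mature_transcript(model, fx$genome, variant = del1)
  minus <- model$strand[1] == "-"
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  start_tx <- ctx$genome2tx(if (minus) ce - 1L else cs)
  del_tx <- min(na.omit(vapply(0:2, function(k) {
    ctx$genome2tx(del1$pos + if (minus) -1L - k else 1L + k)
  }, integer(1))))
  t <- del_tx + 30L
  t <- t + (3L - (t - start_tx) %% 3L) %% 3L  # in-frame after the shift
  genome_c <- edit_tx_bases(fx$genome, model, ctx, t, "TAA")
  cc <- call_rescue(model, genome_c, del1, make_isoform(model))
  expect_equal(cc$ptc_status, "premature")
  call_c <- call_rescue(model, genome_c, del1, chain)
  expect_equal(call_c$verdict, "rescue")
  expect_equal(call_c$ptc_mode, "C")

  # same engineering but in exon 4 (different exon from the indel): mode G
  ex <- splicerescue:::exon_intervals(model)
  e4 <- if (minus) 2L else 4L
  e4_tx <- range(na.omit(vapply(
    seq(ex$exon_start[e4], ex$exon_end[e4] - 1L),
    ctx$genome2tx, integer(1))))
  t4 <- e4_tx[1] + 15L
  t4 <- t4 + (3L - (t4 - start_tx) %% 3L) %% 3L
  genome_g <- edit_tx_bases(fx$genome, model, ctx, t4, "TAA")
  call_g <- call_rescue(model, genome_g, del1, chain)
  expect_equal(call_g$verdict, "rescue")
  expect_equal(call_g$ptc_mode, "G")

  # excise that exon-4 PTC with an exitron-like -20 nt junction covering
  # it (frame compensating, not an exon skip): mode F
  ptc_g <- sort(vapply(0:2, function(k) ctx$tx2genome(t4 + k), integer(1)))
  exi_start <- ptc_g[1] - 6L
  exitron <- tibble::tibble(intron_start = exi_start,
                            intron_end = exi_start + 20L)
  call_f <- call_rescue(model, genome_g, del1,
                        make_isoform(model, exitron))
  expect_equal(call_f$verdict, "rescue")
  expect_equal(call_f$ptc_mode, "F")
})

test_that("posterior stops are reported, not counted as premature", {
  # engineer: canonical + non-3n indel where the shifted frame reaches
  # beyond the canonical stop (safe CDS has no internal stops and the
  # canonical TAA is out of frame after the shift)
  fx <- wda1_fixture()
  del1 <- dplyr::filter(fx$variants, name == "del1")
  cc <- call_rescue(fx$models, fx$genome, del1, make_isoform(fx$models))
  # the shifted frame finds either no stop at all or one behind the
  # canonical stop (inside the 3' UTR)
  expect_true(cc$ptc_status %in% c("none", "posterior_to_canonical"))
  expect_false(isTRUE(cc$canonical_stop_used))
})

test_that("modular-arithmetic verdicts equal brute-force translation verdicts", {
  n <- 0; mismatches <- 0
  for (rep in 1:4) {
    cfg <- sim_config(seed = 800 + rep, n_genes = 3,
                      intron_length_range = c(67, 200),
                      exon_count_range = c(3, 7))
    sim <- simulate_gene_models(cfg)
    jx <- simulate_noisy_junctions(sim$models, cfg, n_total = 24)
    vars <- inject_variants(sim$models, sim$genome, cfg)
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      model <- dplyr::filter(sim$models, gene_id == v$gene_id)
      jg <- dplyr::filter(jx, gene_id == v$gene_id)
      for (k in seq_len(nrow(jg))) {
        chain <- tryCatch(make_isoform(model, jg[k, ]),
                          error = function(e) NULL)
        if (is.null(chain)) next
        call <- call_rescue(model, sim$genome, v, chain)
        ov <- oracle_verdict(model, sim$genome, chain, v)
        n <- n + 1
        if (!identical(call$verdict, ov)) mismatches <- mismatches + 1
      }
    }
  }
  expect_gt(n, 50)
  expect_equal(mismatches, 0)
})

test_that("every rescue with a premature canonical stop gets one A-H mode", {
  modes <- character(0)
  for (rep in 1:6) {
    cfg <- sim_config(seed = 900 + rep, n_genes = 4,
                      intron_length_range = c(67, 200),
                      exon_count_range = c(4, 8))
    sim <- simulate_gene_models(cfg)
    jx <- simulate_noisy_junctions(sim$models, cfg, n_total = 40)
    vars <- inject_variants(sim$models, sim$genome, cfg,
                            phases = c("3n+1", "3n+2"))
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      model <- dplyr::filter(sim$models, gene_id == v$gene_id)
      jg <- dplyr::filter(jx, gene_id == v$gene_id)
      for (k in seq_len(nrow(jg))) {
        chain <- tryCatch(make_isoform(model, jg[k, ]),
                          error = function(e) NULL)
        if (is.null(chain)) next
        call <- call_rescue(model, sim$genome, v, chain)
        if (call$verdict == "rescue") modes <- c(modes, call$ptc_mode)
      }
    }
  }
  expect_gt(length(modes), 0)
  expect_true(all(modes %in% c(LETTERS[1:8], "posterior_stop",
                               "not_applicable")))
})

test_that("call_rescue_all pairs every variant with every novel junction", {
  bx <- bc10_fixture()
  catalog <- classify_junctions(bx$skip_junction, bx$models)
  calls <- call_rescue_all(bx$models, bx$genome, bx$variants, catalog)
  expect_equal(nrow(calls), 3)  # 3 variants x 1 novel junction
  expect_true(all(calls$verdict == "rescue"))
  expect_true(all(c("intron_start", "intron_end") %in% names(calls)))
})
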