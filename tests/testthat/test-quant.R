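mk_ev <- function(starts, ends, reads) {
  tibble::tibble(intron_start = starts, intron_end = ends,
                 read_count = reads)
}

test_that("junction region depth sums overlapping junction reads", {
  j <- tibble::tibble(intron_start = 100L, intron_end = 200L)
  ev <- mk_ev(c(100, 150), c(200, 400), c(10, 90))
  expect_equal(junction_region_depth(j, ev), 100)
  expect_equal(junction_region_depth(j, ev[1, ]), 10)

  # 5 junctions with known overlaps vs the quadratic all-pairs oracle
  set.seed(7)
  ev5 <- mk_ev(as.integer(c(0, 50, 120, 300, 290)),
               as.integer(c(100, 130, 200, 400, 310)),
               sample(1:50, 5))
  for (i in 1:5) {
    oracle <- sum(vapply(1:5, function(k) {
      if (ev5$intron_start[k] < ev5$intron_end[i] &&
            ev5$intron_end[k] > ev5$intron_start[i]) ev5$read_count[k]
      else 0L
    }, integer(1)))
    expect_equal(junction_region_depth(ev5[i, ], ev5), oracle)
  }
})

test_that("relative level is reads over region depth", {
  j <- tibble::tibble(intron_start = 100L, intron_end = 200L)
  # a rescue junction at 1.8% of its region
  ev <- mk_ev(c(100, 100), c(200, 250), c(18, 982))
  expect_equal(relative_level(j, ev), 0.018)
  # zero reads for j, nonzero region depth
  ev0 <- mk_ev(c(100, 100), c(200, 250), c(0, 50))
  expect_equal(relative_level(j, ev0), 0)
  # empty region flags undefined
  expect_true(is.na(relative_level(j, mk_ev(100L, 200L, 0L))))

  # multinomial recovery at depth 10,000
  g <- toy_model(n_exons = 3)
  jx <- tibble::tibble(intron_start = c(100L, 100L),
                       intron_end = c(200L, 209L))
  set.seed(11)
  ev <- simulate_junction_reads(jx, c(0.75, 0.25), 10000)
  hat <- relative_level(jx[2, ], ev)
  expect_lt(abs(hat - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("R_mw handles fold changes, infinity and not-observed", {
  r <- compute_rmw(0.377, 0.018)
  expect_equal(round(r$r_mw, 1), 20.9)
  expect_true(r$increased)
  r2 <- compute_rmw(0.021, 0)
  expect_true(is.infinite(r2$r_mw))
  r3 <- compute_rmw(0.1, 0.1)
  expect_equal(r3$r_mw, 1)
  expect_false(r3$increased)
  r4 <- compute_rmw(0, 0)
  expect_true(is.na(r4$r_mw))
  expect_false(r4$observed)
})

test_that("PSI equals the exhaustive path-enumeration oracle", {
  g <- toy_model(n_exons = 4)
  # inclusion 30 / exclusion 10 on the exon-2 node
  ev <- mk_ev(as.integer(c(100, 300, 100)), as.integer(c(200, 400, 400)),
              c(30L, 30L, 10L))
  skip <- tibble::tibble(intron_start = 100L, intron_end = 400L)
  expect_equal(compute_psi(skip, ev, g)$psi, 0.75)

  # exon never skipped
  psi1 <- compute_psi(skip, ev[1:2, ], g)
  expect_equal(psi1$psi, 1)
  expect_true(psi1$low_confidence)

  # richer graph: canonical J12/J23/J34, skip2, skip23 — compare with an
  # independent powerset-based path enumeration
  ev3 <- mk_ev(as.integer(c(100, 300, 500, 100, 100)),
               as.integer(c(200, 400, 600, 400, 600)),
               c(40L, 25L, 50L, 10L, 5L))
  got <- compute_psi(skip, ev3, g)
  node <- c(200, 300)
  # the region of the skip junction is its intron plus the overlapped
  # canonical introns: [100, 400); the local graph holds the junctions
  # and canonical introns overlapping it
  window <- c(100, 400)
  ci_all <- splicerescue:::intron_intervals(g)
  in_w <- ci_all$start < window[2] & ci_all$end > window[1]
  ci <- list(start = ci_all$start[in_w], end = ci_all$end[in_w])
  keep_j <- which(ev3$intron_start < window[2] &
                    ev3$intron_end > window[1])
  ev3 <- ev3[keep_j, ]
  idx_sets <- unlist(lapply(seq_len(nrow(ev3)), function(k) {
    utils::combn(nrow(ev3), k, simplify = FALSE)
  }), recursive = FALSE)
  valid <- Filter(function(s) {
    ok_nonov <- all(vapply(s, function(i) {
      sum(ev3$intron_start[s] < ev3$intron_end[i] &
            ev3$intron_end[s] > ev3$intron_start[i]) == 1
    }, logical(1)))
    if (!ok_nonov) return(FALSE)
    all(vapply(seq_along(ci$start), function(k) {
      pos <- seq(ci$start[k], ci$end[k] - 1)
      all(vapply(pos, function(p) {
        any(ev3$intron_start[s] <= p & p < ev3$intron_end[s])
      }, logical(1)))
    }, logical(1)))
  }, idx_sets)
  w <- vapply(valid, function(s) mean(ev3$read_count[s]), numeric(1))
  inc <- vapply(valid, function(s) {
    !any(ev3$intron_start[s] < node[2] & ev3$intron_end[s] > node[1])
  }, logical(1))
  expect_equal(got$psi, sum(w[inc]) / sum(w))
})

test_that("prevalence curves are monotone and match direct filtering", {
  # 33 of 73 genes have a rescue junction with >= 10 reads
  set.seed(21)
  reads <- c(sample(10:5000, 33, replace = TRUE),
             sample(0:9, 40, replace = TRUE))
  rr <- tibble::tibble(gene_id = paste0("g", 1:73), reads = reads)
  curve <- prevalence_vs_threshold(rr, c(0, 1, 10, 500), n_genes = 73)
  expect_equal(curve$proportion[curve$threshold == 10], 33 / 73)
  # threshold 0: every gene listed with a rescue junction counts
  expect_equal(curve$proportion[curve$threshold == 0], 1)
  expect_equal(curve$proportion[curve$threshold == 1], mean(reads > 0))

  # monotone non-increasing, and equal to the brute-force filter
  set.seed(22)
  rr2 <- tibble::tibble(
    gene_id = sample(paste0("g", 1:40), 120, replace = TRUE),
    reads = as.integer(rexp(120, 1 / 300)))
  th <- c(0, 1, 10, 50, 100, 500, 1000)
  curve2 <- prevalence_vs_threshold(rr2, th, n_genes = 40)
  expect_true(all(diff(curve2$proportion) <= 0))
  oracle <- vapply(th, function(t) {
    length(unique(rr2$gene_id[rr2$reads >= t])) / 40
  }, numeric(1))
  expect_equal(curve2$proportion, oracle)
  expect_equal(attr(curve2, "asymptote"),
               curve2$proportion[length(th)])
  expect_error(prevalence_vs_threshold(rr2, rev(th)), "ascending")
})

test_that("non-canonical to canonical depth ratios use maxima per gene", {
  ev <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2"),
    canonical = c(TRUE, FALSE, FALSE, TRUE),
    read_count = c(100L, 50L, 20L, 30L))
  r <- noncanonical_to_canonical_ratio(ev)
  expect_equal(r$ratio[r$gene_id == "g1"], 0.5)
  expect_equal(r$ratio[r$gene_id == "g2"], 0)

  # threshold counts match a brute-force scan on a synthetic gene set
  set.seed(31)
  evs <- tibble::tibble(
    gene_id = rep(paste0("g", 1:50), each = 4),
    canonical = rep(c(TRUE, FALSE, FALSE, FALSE), 50),
    read_count = as.integer(c(rbind(sample(50:200, 50, TRUE),
                                    sample(0:150, 50, TRUE),
                                    sample(0:150, 50, TRUE),
                                    sample(0:150, 50, TRUE)))))
  rs <- noncanonical_to_canonical_ratio(evs)
  oracle <- vapply(paste0("g", 1:50), function(g) {
    e <- evs[evs$gene_id == g, ]
    max(e$read_count[!e$canonical]) / max(e$read_count[e$canonical])
  }, numeric(1))
  expect_equal(sum(rs$ratio > 0.1), sum(oracle > 0.1))
  expect_equal(sum(rs$ratio > 0.5), sum(oracle > 0.5))
})

test_that("overlapping relative levels stay within [0, 1] and sum sanely", {
  set.seed(41)
  ev <- mk_ev(as.integer(c(100, 100, 150, 100)),
              as.integer(c(200, 250, 260, 209)),
              sample(0:100, 4)) |>
    dplyr::mutate(gene_id = "g1", sample_id = "s1", condition = "WT",
                  chrom = "chr1")
  q <- quantify_junctions(ev)
  expect_true(all(q$relative_level >= 0 & q$relative_level <= 1,
                  na.rm = TRUE))
  # mutually overlapping members' levels sum to >= any single level
  expect_true(sum(q$relative_level, na.rm = TRUE) >=
                max(q$relative_level, na.rm = TRUE))
})
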