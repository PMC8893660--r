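#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions the package is designed around:
#' multi-exon genes with lognormal exon lengths (median about 150 nt, as
#' typical of compact plant genes), intron lengths uniform on
#' `[67, 3608]` bp, noisy novel junctions drawn uniformly within gene
#' bodies (so about two thirds are frame-breaking under the null),
#' multinomial junction read counts at a configurable region depth, and
#' haplotype panels of 3 groups x 20 varieties.
#'
#' @param seed Integer seed; the same seed reproduces every generator
#'   byte-for-byte.
#' @param n_genes Number of genes to simulate.
#' @param exon_count_range Inclusive range of exons per gene.
#' @param exon_length_meanlog,exon_length_sdlog Lognormal exon-length
#'   parameters (median `exp(meanlog)` = 150 nt by default).
#' @param intron_length_range Inclusive intron-length bounds in bp.
#' @param noisy_per_gene Expected novel junctions per gene.
#' @param read_depth Junction-region read depth for read simulation.
#' @param panel_groups,panel_size Haplotype panel shape (3 groups of 20).
#' @param panel_region_length Length of each simulated haplotype region.
#' @param panel_mutations Mutations per haplotype lineage.
#' @return A list of class `sr_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       exon_count_range = c(2L, 11L),
                       exon_length_meanlog = log(150),
                       exon_length_sdlog = 0.4,
                       intron_length_range = c(67L, 3608L),
                       noisy_per_gene = 8L,
                       read_depth = 10000L,
                       panel_groups = 3L, panel_size = 20L,
                       panel_region_length = 500L,
                       panel_mutations = 3L) {
  stopifnot(n_genes >= 1, exon_count_range[1] >= 1,
            diff(exon_count_range) >= 0,
            intron_length_range[1] > 0,
            intron_length_range[2] >= intron_length_range[1])
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_length_meanlog = exon_length_meanlog,
    exon_length_sdlog = exon_length_sdlog,
    intron_length_range = as.integer(intron_length_range),
    noisy_per_gene = noisy_per_gene,
    read_depth = as.integer(read_depth),
    panel_groups = as.integer(panel_groups),
    panel_size = as.integer(panel_size),
    panel_region_length = as.integer(panel_region_length),
    panel_mutations = as.integer(panel_mutations)
  ), class = "sr_config")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codons that can never create a stop in any local frame (no T at all)
NONSTOP_SAFE_CODONS <- apply(
  expand.grid(c("A", "C", "G"), c("A", "C", "G"), c("A", "C", "G")),
  1, paste, collapse = "")

random_cds <- function(n_codons, safe = FALSE) {
  if (safe) {
    body <- sample(NONSTOP_SAFE_CODONS, n_codons - 2L, replace = TRUE)
  } else {
    all_codons <- apply(expand.grid(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")),
                        1, paste, collapse = "")
    body <- sample(setdiff(all_codons, STOP_CODONS), n_codons - 2L,
                   replace = TRUE)
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Simulate multi-exon gene models and their genome
#'
#' Each gene lives on its own chromosome with flanking pads, has an
#' in-frame CDS (single terminal stop) split across lognormal-length exons
#' separated by introns with GT..AG ends, and may lie on either strand.
#'
#' @param cfg An [sim_config()] object.
#' @param exon_counts Optional integer vector (length `n_genes`) forcing
#'   exon counts per gene.
#' @param forced_exon_lengths Optional named list: per gene index, an
#'   integer vector of forced exon lengths (`NA` entries are drawn).
#' @param safe_cds Use codons that cannot form a stop in any frame
#'   (handy for constructing frame-shift fixtures without incidental
#'   PTCs).
#' @return A list with `models` (gene-model tibble) and `genome`
#'   (`DNAStringSet`).
#' @export
simulate_gene_models <- function(cfg = sim_config(), exon_counts = NULL,
                                 forced_exon_lengths = list(),
                                 safe_cds = FALSE) {
  set.seed(cfg$seed)
  models <- list()
  seqs <- character(cfg$n_genes)
  chroms <- paste0("chr", seq_len(cfg$n_genes))
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- if (!is.null(exon_counts)) {
      exon_counts[g]
    } else {
      rng <- seq(cfg$exon_count_range[1], cfg$exon_count_range[2])
      if (length(rng) == 1) rng else sample(rng, 1)
    }
    lens <- pmax(30L, pmin(1200L, as.integer(round(
      rlnorm(n_ex, cfg$exon_length_meanlog, cfg$exon_length_sdlog)))))
    forced <- forced_exon_lengths[[as.character(g)]]
    if (!is.null(forced)) {
      ii <- which(!is.na(forced))
      lens[ii] <- as.integer(forced[ii])
    }
    E <- sum(lens)
    u5 <- min(30L, lens[1] %/% 2L)
    u3 <- min(30L, lens[n_ex] %/% 2L)
    cds_len <- E - u5 - u3
    u3 <- u3 + cds_len %% 3L
    cds_len <- E - u5 - u3
    stopifnot(cds_len >= 6L)
    transcript <- paste0(random_bases(u5),
                         random_cds(cds_len %/% 3L, safe = safe_cds),
                         random_bases(u3))
    intron_lens <- if (n_ex > 1) {
      as.integer(round(runif(n_ex - 1, cfg$intron_length_range[1],
                             cfg$intron_length_range[2])))
    } else integer(0)
    introns <- vapply(intron_lens, function(l) {
      paste0("GT", random_bases(l - 4L), "AG")
    }, character(1))
    # interleave exons and introns into the pre-mRNA
    tx_off <- cumsum(c(0L, lens))
    prem_parts <- character(0)
    for (i in seq_len(n_ex)) {
      prem_parts <- c(prem_parts,
                      str_sub(transcript, tx_off[i] + 1L, tx_off[i + 1L]))
      if (i < n_ex) prem_parts <- c(prem_parts, introns[i])
    }
    prem <- paste(prem_parts, collapse = "")
    P <- nchar(prem)
    pad <- 100L
    strand <- sample(c("+", "-"), 1)
    chrom_seq <- paste0(random_bases(pad),
                        if (strand == "+") prem else revcomp(prem),
                        random_bases(pad))
    # pre-mRNA coordinates of exons and CDS
    ioff <- cumsum(c(0L, intron_lens))
    ex_s_prem <- tx_off[seq_len(n_ex)] + ioff
    ex_e_prem <- tx_off[-1] + ioff
    prem_of_tx <- function(t) {
      i <- findInterval(t, tx_off, rightmost.closed = FALSE,
                        left.open = TRUE)
      t + ioff[max(i, 1L)]
    }
    cds_s_prem <- prem_of_tx(u5 + 1L) - 1L
    cds_e_prem <- prem_of_tx(u5 + cds_len)
    to_genomic <- function(a, b) {
      if (strand == "+") c(pad + a, pad + b) else c(pad + P - b, pad + P - a)
    }
    gex <- purrr::map2(ex_s_prem, ex_e_prem, to_genomic)
    gcds <- to_genomic(cds_s_prem, cds_e_prem)
    models[[g]] <- gene_model(
      gene_id = sprintf("gene%03d", g), chrom = chroms[g], strand = strand,
      exon_starts = purrr::map_int(gex, function(x) as.integer(x[1])),
      exon_ends = purrr::map_int(gex, function(x) as.integer(x[2])),
      cds_start = gcds[1], cds_end = gcds[2]
    )
    seqs[g] <- chrom_seq
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
  list(models = list_rbind(models), genome = genome)
}

#' Simulate noisy novel junctions under the uniform-boundary null
#'
#' Novel donors and acceptors are drawn uniformly within each gene body,
#' subject to the configured intron-length bounds. Under this null about
#' two thirds of the resulting junctions change the reading frame.
#'
#' @param models Gene-model tibble.
#' @param cfg An [sim_config()] object (supplies bounds and seed).
#' @param n_total Optional total number of junctions (spread across
#'   genes); default draws `noisy_per_gene` per gene.
#' @return Junction tibble (`gene_id`, `chrom`, `intron_start`,
#'   `intron_end`, `strand`).
#' @export
simulate_noisy_junctions <- function(models, cfg = sim_config(),
                                     n_total = NULL) {
  set.seed(cfg$seed + 1L)
  spans <- gene_spans(models)
  counts <- if (is.null(n_total)) {
    rep(cfg$noisy_per_gene, nrow(spans))
  } else {
    as.vector(rmultinom(1, n_total, rep(1, nrow(spans))))
  }
  out <- purrr::map(seq_len(nrow(spans)), function(i) {
    sp <- spans[i, ]
    n <- counts[i]
    if (n == 0) return(NULL)
    lo <- cfg$intron_length_range[1]
    hi <- cfg$intron_length_range[2]
    width <- sp$tx_end - sp$tx_start
    if (width <= lo + 2) return(NULL)
    s <- sp$tx_start + floor(runif(n, 0, width - lo))
    max_len <- pmin(hi, sp$tx_end - s)
    len <- floor(runif(n, lo, max_len + 1))
    tibble(gene_id = sp$gene_id, chrom = sp$chrom,
           intron_start = as.integer(s),
           intron_end = as.integer(s + len),
           strand = sp$strand)
  })
  list_rbind(purrr::compact(out))
}

#' Inject CRISPR-style variants into gene models
#'
#' Places deletions/insertions of the requested phases inside CDS exons
#' (away from exon boundaries when possible) and nonsense SNVs that create
#' an in-frame premature stop under canonical splicing. Returns the
#' variant table plus an answer key (target exon, phase).
#'
#' @param models Gene-model tibble.
#' @param genome Named `DNAStringSet`.
#' @param cfg An [sim_config()] object (seed).
#' @param phases Character vector drawn from `"3n+1"`, `"3n+2"`, `"3n"`,
#'   `"snv"`; one variant per gene cycles through these.
#' @return Variant tibble with answer-key columns `gene_id`,
#'   `target_exon`, `phase`.
#' @export
inject_variants <- function(models, genome, cfg = sim_config(),
                            phases = c("3n+1", "3n+2", "3n", "snv")) {
  set.seed(cfg$seed + 2L)
  out <- list()
  gids <- unique(models$gene_id)
  for (i in seq_along(gids)) {
    model <- models |> dplyr::filter(.data$gene_id == gids[i])
    phase <- phases[(i - 1L) %% length(phases) + 1L]
    v <- inject_one_variant(model, genome, phase)
    if (!is.null(v)) out[[length(out) + 1L]] <- v
  }
  list_rbind(out)
}

inject_one_variant <- function(model, genome, phase) {
  cs <- model$cds_start[1]; ce <- model$cds_end[1]
  ex <- exon_intervals(model)
  # CDS-interior candidate exons with some margin
  a <- pmax(ex$exon_start, cs + 6L)
  b <- pmin(ex$exon_end, ce - 6L)
  ok <- which(b - a >= 30L)
  if (length(ok) == 0) return(NULL)
  exon_idx <- ok[sample(length(ok), 1)]
  pick <- list(exon_start = ex$exon_start[exon_idx],
               exon_end = ex$exon_end[exon_idx],
               a = a[exon_idx], b = b[exon_idx])
  if (phase == "snv") {
    v <- nonsense_snv(model, genome, pick)
    if (is.null(v)) return(NULL)
    v$target_exon <- exon_idx
    v$phase <- "snv"
    return(v)
  }
  len <- switch(phase,
                "3n+1" = sample(c(1L, 4L, 22L), 1),
                "3n+2" = sample(c(2L, 5L), 1),
                "3n" = sample(c(3L, 6L), 1))
  pos <- as.integer(floor(runif(1, pick$a, pick$b - len)))
  ref <- genome_seq(genome, model$chrom[1], pos, pos + len)
  v <- variant_spec(model$chrom[1], pos, ref, "")
  v$gene_id <- model$gene_id[1]
  v$target_exon <- exon_idx
  v$phase <- phase
  v
}

# single-base substitution creating an in-frame stop under canonical
# splicing, within the chosen exon
nonsense_snv <- function(model, genome, pick) {
  cs <- model$cds_start[1]
  minus <- model$strand[1] == "-"
  tx <- build_mature_transcript(model, genome)
  ce <- model$cds_end[1]
  start_g <- if (minus) ce - 1L else cs
  start_tx <- tx$genome2tx(start_g)
  for (g in sample(seq(pick$a, pick$b - 1L))) {
    t <- tx$genome2tx(g)
    if (is.na(t) || t < start_tx) next
    frame <- (t - start_tx) %% 3L
    codon_start <- t - frame
    codon <- str_sub(tx$seq, codon_start, codon_start + 2L)
    for (stop in STOP_CODONS) {
      d <- which(strsplit(codon, "")[[1]] != strsplit(stop, "")[[1]])
      if (length(d) == 1 && (codon_start + d - 1L) == t) {
        new_base_tx <- str_sub(stop, d, d)
        ref <- genome_seq(genome, model$chrom[1], g, g + 1L)
        alt <- if (minus) revcomp(new_base_tx) else new_base_tx
        if (alt == ref) next
        v <- variant_spec(model$chrom[1], g, ref, alt)
        v$gene_id <- model$gene_id[1]
        return(v)
      }
    }
  }
  NULL
}

#' Apply variants to a genome (mutated FASTA substrate)
#'
#' @param genome Named `DNAStringSet`.
#' @param variants Variant tibble (one variant per chromosome at most, as
#'   produced by [inject_variants()]).
#' @return A mutated `DNAStringSet`.
#' @export
apply_variants_to_genome <- function(genome, variants) {
  seqs <- as.character(genome)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    s <- seqs[[v$chrom]]
    seqs[[v$chrom]] <- paste0(str_sub(s, 1L, v$pos),
                              v$alt,
                              str_sub(s, v$pos + nchar(v$ref) + 1L))
  }
  Biostrings::DNAStringSet(seqs)
}

#' Simulate multinomial junction read counts
#'
#' Draws read counts for the junctions of one junction region from a
#' multinomial at the given isoform proportions and depth.
#'
#' @param junctions Junction tibble (rows are the competing junctions of
#'   one region).
#' @param proportions Numeric vector (same length, summing to 1).
#' @param depth Total region read depth.
#' @param sample_id,condition Labels attached to the evidence.
#' @return Junction evidence tibble with `read_count`.
#' @export
simulate_junction_reads <- function(junctions, proportions, depth,
                                    sample_id = "s1", condition = "WT") {
  stopifnot(length(proportions) == nrow(junctions),
            abs(sum(proportions) - 1) < 1e-8)
  counts <- if (depth > 0) {
    as.vector(rmultinom(1, depth, proportions))
  } else {
    rep(0L, nrow(junctions))
  }
  junctions |>
    mutate(sample_id = sample_id, condition = condition,
           read_count = as.integer(counts))
}

#' Simulate an aligned haplotype panel with known per-class diversity
#'
#' Builds an ancestral sequence and, per group, a small set of haplotype
#' lineages each carrying substitutions at distinct sites (class chosen by
#' `class_weights`); group members are distributed over lineages to give
#' the haplotype frequencies. The answer key records each lineage's
#' mutated sites so the true pairwise differences are computable by set
#' arithmetic, independently of sequence comparison.
#'
#' @param cfg An [sim_config()] object.
#' @param n_lineages Haplotype lineages per group.
#' @param class_weights Named weights over [substitution_classes()] used
#'   when drawing substitutions (default uniform).
#' @return A list: `haplotypes` (tibble `haplotype_id`, `group`, `seq`,
#'   `frequency`, `count`), `ancestral` (character), `key` (tibble
#'   `haplotype_id`, `site`, `from`, `to`).
#' @export
simulate_haplotype_panel <- function(cfg = sim_config(), n_lineages = 4L,
                                     class_weights = NULL) {
  set.seed(cfg$seed + 3L)
  L <- cfg$panel_region_length
  ancestral <- random_bases(L)
  anc <- strsplit(ancestral, "")[[1]]
  classes <- substitution_classes()
  if (is.null(class_weights)) {
    class_weights <- setNames(rep(1, length(classes)), classes)
  }
  pairs <- tibble(key = names(SUBSTITUTION_CLASSES),
                  class = unname(SUBSTITUTION_CLASSES)) |>
    tidyr::separate("key", c("from", "to"), sep = ">")
  haps <- list(); keys <- list()
  # mutation sites are distinct across all lineages so that every
  # polymorphic site has a single derived allele (each pairwise difference
  # is then attributable to exactly one substitution class)
  n_mut <- cfg$panel_mutations
  all_sites <- sample(L, n_mut * n_lineages * cfg$panel_groups)
  site_i <- 0L
  for (g in seq_len(cfg$panel_groups)) {
    counts <- as.vector(rmultinom(1, cfg$panel_size,
                                  rep(1, n_lineages)))
    for (h in seq_len(n_lineages)) {
      hid <- sprintf("g%d_h%d", g, h)
      seq_h <- anc
      sites <- all_sites[site_i + seq_len(n_mut)]
      site_i <- site_i + n_mut
      for (s in sites) {
        cl <- sample(classes, 1, prob = class_weights[classes])
        opts <- pairs |> dplyr::filter(.data$class == cl,
                                       .data$from == anc[s])
        if (nrow(opts) == 0) next
        to <- opts$to[sample(nrow(opts), 1)]
        keys[[length(keys) + 1L]] <- tibble(haplotype_id = hid, site = s,
                                            from = anc[s], to = to)
        seq_h[s] <- to
      }
      haps[[length(haps) + 1L]] <- tibble(
        haplotype_id = hid, group = paste0("group", g),
        seq = paste(seq_h, collapse = ""),
        count = counts[h], frequency = counts[h] / cfg$panel_size)
    }
  }
  list(haplotypes = list_rbind(haps), ancestral = ancestral,
       key = list_rbind(keys))
}
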