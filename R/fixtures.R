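#' Deterministic exon-skip rescue fixture (brittle-culm-like)
#'
#' An 11-exon gene whose 7th exon is 45 bp (a multiple of three), carrying
#' three deletions in exon 7: -5 bp at 14 bp from the exon's 5' end,
#' -1 bp at 17 bp, and -22 bp at 17 bp (6 bp from the 3' end). The
#' exon-7-skip junction (fusing the flanking introns) removes 45 nt —
#' frame preserving — and excises the -22 bp deletion entirely, modelling
#' rescue by whole-exon skipping.
#'
#' @param seed Seed for the random sequence content.
#' @return List: `models`, `genome`, `variants` (three deletions, named
#'   `del5`, `del1`, `del22`), `skip_junction` (one-row junction tibble).
#' @export
bc10_fixture <- function(seed = 101L) {
  lens <- rep(NA_integer_, 11L)
  lens[7] <- 45L
  sim <- simulate_gene_models(
    sim_config(seed = seed, n_genes = 1L, exon_count_range = c(11L, 11L),
               exon_length_meanlog = log(151), exon_length_sdlog = 0.3,
               intron_length_range = c(80L, 400L)),
    forced_exon_lengths = list("1" = lens))
  model <- sim$models
  genome <- sim$genome
  ex <- exon_intervals(model)
  minus <- model$strand[1] == "-"
  e7 <- if (minus) length(ex$exon_start) - 7L + 1L else 7L  # genomic index
  exon7 <- list(exon_start = ex$exon_start[e7], exon_end = ex$exon_end[e7])
  stopifnot(exon7$exon_end - exon7$exon_start == 45L)
  # offsets measured from the transcript 5' end of exon 7
  del_at <- function(offset5, len) {
    pos <- if (minus) {
      exon7$exon_end - offset5 - len
    } else {
      exon7$exon_start + offset5
    }
    ref <- genome_seq(genome, model$chrom[1], pos, pos + len)
    v <- variant_spec(model$chrom[1], pos, ref, "")
    v$gene_id <- model$gene_id[1]
    v
  }
  variants <- bind_rows(
    del_at(14L, 5L) |> mutate(name = "del5"),
    del_at(17L, 1L) |> mutate(name = "del1"),
    del_at(17L, 22L) |> mutate(name = "del22")
  )
  ci <- intron_intervals(model)
  skip <- tibble(gene_id = model$gene_id[1], chrom = model$chrom[1],
                 strand = model$strand[1],
                 intron_start = ci$start[e7 - 1L],
                 intron_end = ci$end[e7])
  list(models = model, genome = genome, variants = variants,
       skip_junction = skip)
}

#' Deterministic splice-shift rescue fixture (wax-deficient-anther-like)
#'
#' A multi-exon gene with a non-canonical 5' splice site that removes the
#' last 20 nt of exon 2 (a non-3n junction), and CRISPR-style variants in
#' exon 3: deletions of 1, 4 and 22 bp (all 3n+1) and a 1 bp insertion
#' (3n+2). Combined with the -20 nt junction, the 3n+1 deletions give a
#' net change of 0 mod 3 (rescue); the insertion does not. The CDS is
#' built from stop-free-in-any-frame codons so that frame restoration is
#' decided purely by the arithmetic, mirroring how a real rescue form
#' reaches the canonical stop.
#'
#' @param seed Seed for the random sequence content.
#' @return List: `models`, `genome`, `variants` (named `del1`, `del4`,
#'   `del22`, `ins1`), `shift_junction` (the -20 nt donor-shift
#'   junction).
#' @export
wda1_fixture <- function(seed = 202L) {
  sim <- simulate_gene_models(
    sim_config(seed = seed, n_genes = 1L, exon_count_range = c(5L, 5L),
               exon_length_meanlog = log(220), exon_length_sdlog = 0.2,
               intron_length_range = c(80L, 400L)),
    safe_cds = TRUE)
  model <- sim$models
  genome <- sim$genome
  ex <- exon_intervals(model)
  ci <- intron_intervals(model)
  minus <- model$strand[1] == "-"
  n_ex <- length(ex$exon_start)
  # transcript-order exon/intron i at genomic index:
  gidx <- function(i) if (minus) n_ex - i + 1L else i
  giidx <- function(i) if (minus) (n_ex - 1L) - i + 1L else i
  e2 <- gidx(2L); i2 <- giidx(2L)
  shift <- if (minus) {
    tibble(intron_start = ci$start[i2], intron_end = ci$end[i2] + 20L)
  } else {
    tibble(intron_start = ci$start[i2] - 20L, intron_end = ci$end[i2])
  }
  shift <- shift |>
    mutate(gene_id = model$gene_id[1], chrom = model$chrom[1],
           strand = model$strand[1])
  e3 <- list(exon_start = ex$exon_start[gidx(3L)],
             exon_end = ex$exon_end[gidx(3L)])
  site5 <- 40L  # offset of the edit site from the 5' end of exon 3
  vat <- function(len, alt, name) {
    pos <- if (minus) e3$exon_end - site5 - len else e3$exon_start + site5
    ref <- if (len > 0) {
      genome_seq(genome, model$chrom[1], pos, pos + len)
    } else ""
    v <- variant_spec(model$chrom[1], pos, ref, alt)
    v$gene_id <- model$gene_id[1]
    v$name <- name
    v
  }
  variants <- bind_rows(
    vat(1L, "", "del1"), vat(4L, "", "del4"), vat(22L, "", "del22"),
    vat(0L, "G", "ins1")
  )
  list(models = model, genome = genome, variants = variants,
       shift_junction = shift)
}
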