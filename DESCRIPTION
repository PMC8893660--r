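Package: splicerescue
Title: Frame-Restoring Splice Junctions After Frameshift Indels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether non-canonical splice junctions can restore
    the annotated reading frame of a gene carrying a frameshifting (non-3n)
    indel or a nonsense point mutation. Provides junction cataloguing and
    classification against a reference annotation (canonical vs non-canonical,
    3n vs non-3n, exon skipping and alternative 5'/3' splice-site events),
    a rescue caller that decides whether an isoform re-enables use of the
    canonical stop codon and classifies the rescue mode, junction-level
    abundance statistics (relative level, mutant/wild-type ratio, PSI,
    prevalence-versus-depth curves), protein-consequence scoring with a
    domain-preservation rule, splice-region typing with base-content-corrected
    Nei-Li nucleotide diversity and methylation summaries, goodness-of-fit
    tests against the two-thirds noisy-splicing null, and a deterministic
    synthetic-data generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
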