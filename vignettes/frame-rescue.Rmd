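---
title: "Calling frame-restoring splice junctions after frameshift indels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling frame-restoring splice junctions after frameshift indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicerescue)
library(dplyr)
```

## The problem

A deletion or insertion whose length is not a multiple of three (a
*non-3n* indel) shifts the reading frame of everything downstream,
normally producing a premature termination codon (PTC) and a truncated,
usually non-functional protein. Transcriptomes, however, contain many
non-canonical splice junctions, and a junction that changes the mature
transcript's coding length by `d` nucleotides combines with an indel of
retained length change `v`: when `(d + v) mod 3 = 0` the original frame —
and with it the canonical stop codon — is recovered downstream of the
disturbance. `splicerescue` decides, for any (gene, variant, isoform)
triple, whether this recovery actually happens, and quantifies how
abundant and how protein-preserving such rescue isoforms are.

## Coordinate conventions and the gene model

All internal coordinates are 0-based and half-open; GFF3 input (1-based,
closed) is converted on loading and written back identically. A gene
model is a tibble with one row per exon of a single representative
transcript — when an annotation carries several transcripts per gene the
first is kept with a warning, since a single canonical exon–intron
structure is what "canonical junction" is defined against. Genes without
CDS features cannot enter frame analysis and are excluded with a
warning. All frame arithmetic is performed in transcript orientation;
genomic coordinates are retained for reporting, and every classifier is
invariant under translating a gene's coordinates by a constant (this is
asserted by a test).

## Junction classification

A junction is **canonical** iff its intron interval exactly matches an
annotated intron. Its **frame delta** is computed structurally, not by
string alignment: the affected window is the union of the junction's
intron with every annotated intron it overlaps, and

```
delta = (window bases kept under the junction) − (window bases kept under the annotation)
```

This one formula covers donor/acceptor shifts (±k), whole-exon skips
(−exon length), exitron-like junctions lying inside one exon (−intron
length) and combinations, and it is exactly checkable against per-base
set arithmetic. Event labels follow the standard taxonomy: `SE` when the
intron wholly contains annotated exon(s) with both ends at annotated
sites; `A5E`/`A5S` when only the donor deviates (into the intron =
extension, into the exon = shortening); `A3E`/`A3S` for the acceptor;
`MXE` only when a partner skip junction with an overlapping intron and a
disjoint skipped exon exists — a single junction is never `MXE`. Anything
else, including junctions with both ends inside canonical introns, is
`other` and excluded from frame arithmetic unless supplied as part of an
explicit isoform chain. Junctions overlapping two genes are assigned to
the gene with the larger CDS overlap, ties flagged; junctions overlapping
no gene are flagged intergenic.

## The rescue caller

An isoform is an ordered chain of non-overlapping introns; helpers build
the canonical chain and single-novel-junction chains (all canonical
introns not overlapping the novel one, plus the novel one). How
multi-junction isoforms are assembled from short-read evidence is not
resolvable from junction tables alone, so chains are accepted as explicit
inputs and single-novel-junction chains are generated automatically.

The verdict combines modular arithmetic with an ORF scan:

1. `Δj` — the chain's frame delta restricted to bases inside the
   annotated CDS span (UTR-only changes cannot shift the coding frame).
2. `Δv` — the variant's retained contribution: a fully retained variant
   contributes `len(alt) − len(ref)`; a variant whose reference interval
   is partially excised contributes minus its retained coding bases and
   is flagged boundary-spanning (the alternative allele is then not
   inserted); a fully excised variant contributes 0.
3. The mutant mature transcript is built, the annotated start and stop
   codons are mapped through a transcript↔genome coordinate map, and the
   ORF is scanned codon-by-codon for the first in-frame stop
   (TAA/TAG/TGA).

`verdict = rescue` iff `(Δj + Δv) mod 3 = 0`, the first stop is the
mapped canonical stop, and its status is not premature. 3n indels are
reported `not_applicable` (they never break frame); so are SNVs that do
not create a PTC under canonical splicing and variants outside the gene
span. Frame-restoring chains that terminate at a downstream stop instead
of the canonical one are reported `posterior_to_canonical`, not rescue.
No NMD rule (such as the 50-nt last-junction heuristic) is applied in
calling; PTC is defined operationally as any in-frame stop strictly
upstream of the mapped canonical stop.

For nonsense SNVs the typical rescue route is excision of the mutated
base, but the caller deliberately lets the ORF scan decide: a junction
boundary can split the mutated codon so that the stop never forms even
though the base itself is retained. This keeps the fast verdict exactly
equivalent to brute-force transcript translation, which the test suite
verifies on over a thousand randomized (gene, variant, isoform) triples
against an independently implemented per-base oracle.

Rescues are classified two ways:

* **Form**: 3n chain skipping the whole indel-bearing exon
  (`A1_3n_exon_skip`), other 3n rescues (`A_3n_other`), non-3n chain
  containing a whole-exon skip (`A6_non3n_exon_skip`), other non-3n
  rescues (`A_non3n_other`). Finer subtypes of the "other" buckets are
  not distinguished, matching how such events are usually reported.
* **PTC mode** (A–H): the cross of *indel and PTC in the same annotated
  exon vs different exons* with *PTC excised by whole-exon skipping / PTC
  excised by a non-exon-skip junction / PTC retained but compensated with
  no upstream skip / PTC retained and rescued by skipping an exon before
  it*. The PTC used here is the first in-frame stop of the
  canonical-splicing-plus-variant transcript; when that stop falls behind
  the canonical stop the mode is `posterior_stop`.

Distances from an indel to the nearest annotated splice site are the
minimum over both indel boundaries of the distance to the nearest intron
boundary; ties take the 5' boundary, intronic variants are flagged.

## Quantification

The **junction region** of a junction is its intron interval; the
**region depth** is the summed reads of all junctions overlapping that
interval, and the **relative level** is the junction's reads over region
depth. Exon-body reads are not part of the depth — quantification is
junction-only, and output metadata should be read with that in mind.
`R_mw` is the relative level in mutant over wild type, `Inf` when the
junction is absent from the wild type (`R_w = 0 < R_m`), `NA` when
unobserved in both; infinity is serialized as the literal string `"Inf"`
in text reports.

**PSI** is defined on the differential exon node the junction induces
(the exonic bases it removes, or the intronic bases an extension adds).
A local splice graph is built from the junctions overlapping the node's
region; a splicing path is a set of non-overlapping junctions covering
every canonical intron of the region (intron retention is deliberately
not modelled — it cannot be resolved unambiguously from junction
evidence); each path is supported by the mean read count of its
junctions, and PSI is the proportional support of node-containing paths.
With no exclusion evidence PSI is 1 with a low-confidence flag. The
implementation enumerates paths depth-first and is tested against an
independent powerset enumeration.

Prevalence-versus-threshold curves report, for ascending minimum read
counts, the fraction of genes with at least one rescue junction at that
support; the curve is monotone non-increasing by construction, and its
value at the largest threshold serves as the asymptote estimate.
Non-canonical/canonical depth ratios use the per-gene *maximum*
non-canonical junction depth over the maximum canonical depth, with a
separate rescue-junction variant of the numerator.

## Protein impact

Isoform translation runs from the annotated start codon (no
re-initiation or start scanning) to the first stop; non-stop transcripts
are translated to the end and flagged. Similarity between wild-type and
isoform proteins is global alignment identity — matching columns over
alignment length — under fixed scoring (match 1, mismatch 0, gap −1, end
gaps penalised); "overall similarity" has no single standard definition,
so the simplest reproducible choice is used and the 90% competence
threshold is exposed as `min_identity`. A domain (an input
interval on the wild-type protein; domain scanning is out of scope) is
preserved when its aligned span contains no gap or mismatch columns
(tolerance configurable, default 0). Rescue competence = all domains
preserved and identity above threshold; genes without domains pass
vacuously with a flag.

## Splice regions, diversity, methylation

Region typing partitions every exonic base of a gene into CE (exon with
no non-canonical end), UE (unaffected part of an affected exon), SE,
A5S or A3S, and labels intronic bases of affected introns A5E, A3E or UI.
When events overlap, the more specific label wins (SE > A5S/A3S > UE for
exonic bases; A5E/A3E > UI for intronic bases) and conflicts are logged.
The partition is implemented per-base and collapsed to intervals, so
disjointness and coverage are exact and asserted by tests.

Nei–Li diversity is the frequency-weighted mean per-site pairwise
difference over ordered haplotype pairs, `π = Σᵢⱼ xᵢxⱼ πᵢⱼ`; `πᵢⱼ` is
computed per covered site (columns with gaps or Ns in either sequence are
excluded for that pair — sites not covered in all varieties simply drop
out). With a two-level `group` column the between-group mode uses ordered
cross-group pairs with frequencies normalised within groups. Substitution
classes are oriented by a supplied ancestral sequence (ancestral
inference itself is out of scope): a difference is classifiable when
exactly one of the two bases is ancestral, and the six class-restricted
diversities then sum exactly to the unrestricted value. Corrected
diversity divides by the regional GC content for `C:G→*` classes and AT
content for `A:T→*` classes; zero content flags the result undefined.

Methylation summaries drop cytosines below depth 4 and discard a
region/context when under 70% of its cytosines are covered (both
thresholds configurable); the region level is the mean of covered site
levels, averaged across samples.

## Null-model statistics

A random splice boundary lands in each reading-frame phase with equal
probability, so two thirds of noisy novel junctions should be frame
breaking. `chi2_gof_two_thirds()` tests observed non-3n/3n counts
against (2n/3, n/3) with df 1 and *no* continuity correction;
`chi2_2x2()` compares two such proportions with Yates' correction by
default. These conventions are the ones that reproduce the standard
printed values for these tests, and both are cross-checked against
`stats::chisq.test()` and the closed-form 2×2 statistic in the test
suite.

## The synthetic generators

The generators define the study conditions under which the pipeline is
exercised:

* gene models with 2–11 exons, lognormal exon lengths with median 150 nt
  (a typical compact-plant-gene scale; the `bc10_fixture()` exemplar
  uses 151 nt to match its 11-exon, 45-bp-exon geometry), intron lengths
  uniform on [67, 3608] bp, in-frame CDS with a single terminal stop,
  GT..AG intron ends, either strand;
* noisy junctions drawn uniformly within gene bodies subject to the
  intron-length bounds — the uniform-boundary null under which about two
  thirds of junctions are non-3n;
* CRISPR-style deletions/insertions of phases 3n+1, 3n+2 and 3n placed
  inside CDS exons, and nonsense SNVs engineered to create an in-frame
  stop under canonical splicing;
* multinomial junction read counts at configurable isoform proportions
  and depth (default 10,000), with WT and mutant conditions free to
  differ;
* haplotype panels of 3 groups × 20 varieties, each lineage carrying
  substitutions at globally distinct sites so that every pairwise
  difference is attributable to exactly one substitution class and true
  diversities are computable from the answer key by set arithmetic.

Everything is byte-deterministic under a seed. The `safe_cds` option
builds coding sequences from T-free codons, in which no stop can arise in
any frame: frame-restoration fixtures can then be constructed whose
verdicts depend only on the arithmetic, and PTCs are introduced
explicitly where a test needs them.

What the generators do *not* emulate: sequencing error and alignment
artefacts, splice-site motif strength, expression-level variation and
NMD kinetics (condition differences are modelled directly as different
isoform proportions), recombination within haplotype panels, and linkage
between regions. Passing tests therefore demonstrate the correctness of
the algorithms under the stated statistical structure, not the
error profile of any particular sequencing pipeline.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately compact problem sizes
chosen to exercise every code path: oracle-equivalence over ≥1,000
randomized triples on 3–7-exon genes with 67–200 bp introns; the
two-thirds null at 30,000 junctions (binomial 3-SE band); Nei–Li
agreement to 1e-12 on panels of up to 10 haplotypes; quantification
recovery at depth 10,000 within 3 binomial standard errors. Integer
coordinates make all interval arithmetic exact; the only floating-point
tolerances in the package are those stated in the tests. Degenerate
inputs have defined behaviour throughout: zero region depth, empty
haplotype differences, zero-content regions, depth-0 read simulation and
single-read evidence are all flagged rather than erroring.

## Limitations

Intron retention is out of scope by design. The caller evaluates
isoforms it is given (or single-novel-junction chains); it does not
predict which isoforms an indel will induce, nor model NMD efficiency or
dosage. One representative transcript per gene defines the canonical
structure; multi-isoform reference sets are not treated as first-class
canonical sets. The A2–A5/A7–A10 fine subtypes of the rescue-form
taxonomy are not distinguished. Protein similarity uses one fixed
alignment scoring; domain preservation is interval-based, not
HMM-based.
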