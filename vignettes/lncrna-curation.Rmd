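---
title: "Curating and annotating lncRNAs: models, rules and design choices"
author: "lncCurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and annotating lncRNAs: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncCurate)
```

## The problem

A long non-coding RNA (lncRNA) is operationally a transcript longer than
200 bp with no protein-coding potential. Catalogues of lncRNAs for a genome
are assembled from several kinds of evidence that disagree with each other:
database annotations, published screens with different library chemistries,
and fresh RNA-seq assemblies. `lncCurate` turns the reconciliation of those
sources — and the downstream annotation of the reconciled set — into
explicit, deterministic, testable rules. This vignette documents the models
and the choices behind them; it is the package's account of its own science,
in the spirit of the methods vignettes of the established Bioconductor
analysis packages.

Everything below operates on one record type: a stranded, exon-structured
transcript model (`transcript_set()`), with 0-based half-open coordinates
internally. GTF's 1-based closed convention is converted exactly once, at
the I/O boundary (`read_gtf()`/`write_gtf()`), which removes a whole class
of off-by-one errors; BED and all internal arithmetic are native. Strand
`"*"` (unknown) is a first-class value that is carried, never coerced:
direction-unknown transcripts flow through every table as their own
category.

## Curation: redundancy and contamination rules

Merging starts from a primary set (database annotations) and screens each
candidate source against it. Only alignments with E-value below `1e-10` are
evidence. Three rules reflect how different sources relate:

* **Database-vs-database** (`rule = "flybase_ucsc"`): a candidate is
  redundant when it has the *same locus* as a primary transcript, or when
  the alignment covers at least 50 % of the candidate's own length.
* **Broad literature set** (`rule = "brown"`): besides an id-level check
  (candidates annotated with an already-included database id), overlap
  covering more than 50 % of *either* transcript's length removes the
  candidate — unless it has two or more exons and its exon count differs
  from the matched transcript's, in which case it is plausibly a different
  isoform and is kept.
* **Intergenic-only screen vs broad set** (`rule = "young_vs_brown"`): only
  locus identity or 90 % coverage of the candidate removes it.

Two points the sources leave open, decided here: *same locus* is read
strictly as identical chromosome, strand, span and exon boundary chain; and
the denominator of the 90 % rule is the candidate's own length (the sources
do not say; the candidate is the thing being judged). Overlapping-but-kept
transcripts from different sources are reported, not merged — collapsing
them into gene models needs manual review and is out of scope.

When no alignments are available, a coordinate fallback computes overlap
fractions from genomic exon-union intersections at the same thresholds, and
marks its decisions (`coord:` evidence prefix) so provenance is never
ambiguous. rRNA contamination is removed on a conjunction: E-value below
`1e-10` *and* identity above 99 %. A status filter drops transcripts
re-annotated as coding, pseudogene, rRNA/snRNA/snoRNA/scaRNA, out-of-date,
TE-region or dropped sequences; transcripts absent from the status table
are kept, because absence of evidence is not evidence for removal.

Every operation returns the kept set *and* a decision per input transcript;
kept plus removed always partitions the input, and deduplication is
idempotent (re-running the kept set against the same primary removes
nothing). Both properties are enforced by tests.

## Discovery: the filter funnel

Novel-lncRNA discovery screens assembled transcripts in six ordered stages,
each with in/removed/out accounting validated by `funnel_check()`:

1. **Intergenicity** — the union of assembled transcripts across libraries
   (exact same-locus duplicates collapsed first, so the union is counted
   once) keeps transcripts whose exons overlap no reference transcript's
   span on *either* strand. Strand-blind intergenicity is deliberate: at
   this stage any contact with annotation disqualifies.
2. **Length** — at least 200 bp (the boundary itself is kept; "shorter
   than" removes). The length filter precedes the coding filter, matching
   the stage order of the funnel this reproduces.
3. **Coding potential** — probability-based scores remove at ≥ 0.39 (the
   boundary is removed); label-based scores keep only `noncoding`. A
   missing score is an error naming the transcripts, not a silent keep.
4. **rRNA exclusion** — same rule as curation.
5. **Read support** — zero remapped reads removes; a transcript absent
   from the count table counts as unsupported.
6. **Sense overlap** — exon–exon overlap with an updated coding annotation
   on the same strand removes. This is exon-level, not span-level: a sense
   transcript inside a coding intron is an intronic-sense lncRNA, a class
   the catalogue retains. Unknown-strand candidates cannot be assessed and
   are kept with a warning.

## Classification

Relative to a set of coding genes (gene span = min start/max end over
isoforms; gene exons = isoform exon union — the gene-span reading is the
package's choice where the alternatives were open):

* **exonic** (sense/antisense): any lncRNA exon overlaps a coding exon;
* **intronic** (sense/antisense): no exon contact, but the lncRNA span
  overlaps a gene span by ≥ 1 bp. Full containment is the motivating
  geometry; partial span overlap without exon contact is undefined in the
  sources and is resolved *toward* intronic here, anchored to the
  maximum-overlap gene;
* **intergenic**: no overlap at all;
* **unknown**: the lncRNA's strand is unknown, regardless of location —
  sense/antisense would be meaningless, so direction-unknown transcripts
  form one class everywhere.

Exon contact outranks intronic containment when a transcript touches
several genes, because exon overlap is the stronger, explicitly listed
condition. Anchor ties break by overlap then lexicographic gene id, for
determinism. The implementation is verified against an independent
per-base oracle (label every base, aggregate) on 1000 random transcripts,
and against planted labels on synthetic data, both exactly.

## Expression

Reads are trimmed 10 bp from the 5′ end (random-primer effects), then 3′
bases are removed until a base with Phred quality strictly above 20 is
reached; reads shorter than 36 bp are discarded. Quality encoding is
phred+33 throughout.

RPKM is computed deterministically as `count × 10⁹ / (total_mapped × L)`
with `L` the full exon-union length and `total_mapped` the *library-wide*
mapped total supplied in the counts-table header — never re-derived from
the transcript subset. This replaces an effective-length-aware EM
quantifier by design: the package trades exact numeric parity with
EM-based estimates for desk-scale, deterministic reproducibility, and no
parity with such estimates is claimed.

A transcript is *expressed* at RPKM strictly above 1 (RPKM = 1 is not
expressed). The poly(A)-minus call is deliberately stringent: ribo-zero
RPKM > 1 *and* poly(A) RPKM exactly 0 — no epsilon, because ribo-zero
libraries also contain polyadenylated RNA, so any poly(A) signal at all
disqualifies.

## Chromatin signatures and validation groups

The promoter window spans 500 bp upstream to 100 bp downstream of the TSS
along the direction of transcription (601 bp when unclipped; clipped at
the chromosome start). It therefore requires a known strand: for
direction-unknown genes H3K4me3 is *not assessable* (`NA`), which is
distinct from absent. Datasets of one mark are pooled before assignment —
any-stage presence counts, because peak tracks and expression libraries
are not stage-matched and a per-stage join would manufacture precision
the data do not have.

H3K4me3 is present on ≥ 1 bp overlap with the promoter window. H3K36me3
coverage is computed over the transcribed region — the genomic span TSS to
TES including introns, following the mark's biology of covering the whole
transcribed region. Pol II presence is assessed over promoter ∪ transcribed
region, but its coverage is reported over the transcribed region only, so
the two numbers answer different questions (is the polymerase there at
all; how much of the body does it cover). K4–K36 is the conjunction of the
two mark presences. CAGE 5′-completeness asks for a peak within an
inclusive ±50 bp window around the 5′ base.

Validation groups combine signatures with expression extremes among
expressed genes (RPKM > 1 is a precondition, violated input is an error):
all three signatures with RPKM above the 3rd quartile (12.92) is G1, below
the 1st quartile (2.78) G2; none of the three with high/low expression is
G3/G4; mixed signatures or mid-range expression is `none`.

## RT-qPCR calls

−ΔCt = Ct(reference) − mean(Ct of technical replicates); detected at
−ΔCt ≥ cutoff (1 for brain assays, 2 for whole-body assays). The reference
assay is an explicit input: the sources show a positive control but never
name the normalizer, so guessing one would be invention. Detection rates
are printed as percentages rounded half-up to two decimals (base R rounds
half-even, which would mis-print the published style).

## The synthetic-data generator

`sim_config()` fixes the study conditions the fixtures emulate: mean lncRNA
length 1008 bp versus mRNA 2869 bp, 94 % of lncRNAs with 1–3 exons, an
8-fold mRNA:lncRNA mean-expression ratio, 30 developmental-stage libraries
plus poly(A) and ribo-zero brain libraries (25 and 50 million mapped reads),
a brain-expressed fraction of one third with 13 % of those poly(A)-minus,
and a 55 % CAGE-complete fraction. Counts are negative-binomial
(dispersion 0.3) — the standard overdispersion model for RNA-seq counts;
the sources state no noise model, so this is the package's choice. The toy
chromosome (2 Mb, 40 coding genes, 62 lncRNAs) is sized so the default test
suite and the acceptance script finish in well under a minute.

Placement enforces separability of planted truth: one lncRNA per host gene
and per intergenic gap, with 2 kb margins so that promoter windows, CAGE
windows and the overhang of exonic lncRNAs can never touch a neighbouring
gene's planted peaks. Decoy peaks of every mark are placed in lncRNA-free
gaps, so "absent" flags are tested against nearby signal, not against an
empty genome. Brain-library counts are constructed to realize the planted
flags exactly (ceiling to guarantee RPKM > 1; zero for poly(A)-minus
plants); stage-library counts are free NB draws, so the expression-ratio
recovery is a genuinely stochastic test, checked within three standard
errors.

Determinism: every generator draws from a substream seeded by (master
seed, fixture name), so one seed fixes every emitted byte and adding a
fixture never perturbs the others.

What the fixtures do *not* emulate: sequence-level realism (no codon
structure or GC bias), multi-isoform genes, overlapping gene models,
aligner-ready reads, or stage-matched chromatin. Passing the
plant-then-recover suites therefore shows that the *rules* are implemented
correctly and invert the generator's geometry exactly; it does not show
robustness to assembly artefacts or mapping noise in real data.

## Numerical and degenerate-input conventions

Empty transcript sets flow through every filter (empty in, empty out);
empty regions for coverage, empty replicate sets and empty call sets are
errors, because their values are undefined rather than zero. Parsers are
strict by default — malformed records are errors naming the line — with an
opt-in lenient mode that warns and skips; silent skipping is never the
default. Overlap thresholds are applied exactly as written: ≥ 0.5 and
≥ 0.9 where coverage "of" a fraction removes, > 0.5 where "more than"
does, ≥ 0.39 removes on coding probability, > 1 for expressed, > 20 for
trim quality, ≥ cutoff for qPCR detection. Where a boundary mattered, a
fixture pins it (a 46 bp read trimming to exactly 36 bp is kept; 45 bp is
discarded; coding probability exactly 0.39 is removed).

## Known limitations

* The curation module reports overlap groups across sources but does not
  merge them into gene models; boundary resolution needs manual review.
* RPKM values are not comparable to effective-length-aware EM estimates;
  only the deterministic formula above is implemented.
* Chromatin assignment is binary presence/coverage over pooled datasets;
  signal intensities and stage-matched joins are out of scope.
* The discovery funnel counts transcripts at every stage; where a source
  switches between gene and transcript units mid-funnel, transcripts are
  used throughout.
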