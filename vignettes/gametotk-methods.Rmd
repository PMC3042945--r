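---
title: "Methods: simulating and characterizing a normalized long-read cDNA library"
author: "gametotk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing a normalized long-read cDNA library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametotk)
library(dplyr)
```

`gametotk` re-implements, as a tested and reusable toolkit, the classic
workflow for characterizing a de novo EST transcriptome sequenced from a
normalized cDNA library with long single-end reads: read cleaning, a
two-step overlap-layout-consensus (OLC) assembly with retained singletons,
saturation statistics, taxonomic contamination screening, microsatellite
and repeat discovery, and GO-slim enrichment. The motivating application is
a fern (*Pteridium*) gametophyte transcriptome — a free-living haploid
plant generation whose gene complement is poorly represented in reference
databases — but every stage is generic. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## The synthetic library generator

Real projects of this kind start from hundreds of thousands of
pyrosequencing reads; at package scale everything must instead be generated
with known ground truth. `sim_config()` fixes the reference study
conditions:

* **Transcriptome.** `n_genes = 2000` transcripts with log-normal lengths
  (arithmetic mean 1500 bp, sd 900 bp, truncated at 200 bp) and log-normal
  true abundances (`abundance_sdlog = 1.5`), normalized to sum to one. The
  heavy-tailed abundance law reflects unnormalized mRNA populations; no
  published abundance table exists for this kind of library, so any
  heavy-tailed law reproducing the steep left-skewed coverage histogram of
  a normalized library is adequate, and the log-normal is the conventional
  choice.
* **Reads.** `n_reads = 50000` single-end reads. Fragment lengths are
  normal with mean 372.6 bp and sd 96.36 bp — the published summary
  statistics of the cleaned read set this workflow targets — hard-clamped
  to [40, 624] bp. Fragments are placed uniformly along their transcript
  ("fragmented by sonication": no positional bias) and sequenced from a
  uniformly random strand.
* **Normalization.** Reads are allocated to transcripts by a multinomial
  law with probabilities proportional to
  `true_abundance^normalization_exponent`. Exponent 0 is perfect
  normalization (uniform allocation); 1 leaves the skew untouched. The
  default 0.25 models effective-but-imperfect normalization; reducing the
  exponent provably reduces the variance of reads per transcript, which the
  test suite checks across seeds.
* **Errors.** Substitutions at 0.002 per base, plus the dominant
  pyrosequencing error mode: ±1 bp indels inside homopolymer runs of at
  least 3 bp, at 0.002 per run base. No published error model accompanies
  the original data, so these are field-typical magnitudes (~0.3–0.5%
  total error), fixed once.
* **Decorations.** A 5' library adapter on every read, a 3' adapter on
  25%, and a polyA (forward strand) or polyT (reverse strand) tail on 30%
  of reads with Poisson length (mean 18 bp). Errors are applied to the
  fragment before decoration, so the truth table's decoration widths
  exactly delimit the (possibly erroneous) core.
* **Contaminants.** `spike_contaminants()` adds `round(0.018 × n_reads)`
  reads drawn by the same process from a non-target library, flagged in the
  truth table — matching the observed best-hit contamination fraction this
  kind of screen reports.

Every generator is a pure function of its seed: identical configurations
produce byte-identical FASTA/FASTQ output. Coordinates are 0-based
half-open everywhere internally; 1-based conventions appear only in GFF3
and tabular-hit interchange.

What the simulation does *not* emulate: flowgram-level signal, realistic
per-base qualities, chimeric library artefacts, alternative splicing, and
sequence composition biases. Tests that pass on this synthetic library
therefore demonstrate algorithmic correctness against a known truth, not
robustness to every artefact of real instrument data.

## Read cleaning

`clean_reads()` applies adapter trimming, aggressive polyA/T trimming and
a length filter. Adapter matching scans every alignment offset; a hit needs
at least `min_match = 8` overlapping bases at a mismatch rate of at most
0.1. End-touching hits trim the matched prefix/suffix; an internal
full-length adapter truncates the read at the match start, discarding the
downstream bases (they are ligation artefacts). PolyA/T trimming combines
two rules per end and base: a *window rule* — cut at the outermost
target-base position from which every full 10-bp window is at least 80%
target base — and a *run rule* removing terminal pure runs of at least
5 bp. Adapter and tail trimming are iterated to a fixed point so trimming
one decoration cannot shelter another; this also makes `clean_reads()`
idempotent by construction. Defaults (window 10, fraction 0.8, run 5,
`min_len = 78`) follow the "aggressive" behaviour of the cleaning tools
this stage stands in for; the 78-bp floor is the observed minimum of the
published cleaned read set, since no explicit threshold was reported.
Aggressive tail trimming deliberately sacrifices genuine terminal A/T
runs of the transcript — the cleaned read is always a substring of its
decorated core, but may be a proper one.

## Two-step OLC assembly

`assemble_primary()` (the MIRA-like pass, ≥94% identity) and
`assemble_secondary()` (the CAP3-like redundancy-reduction pass, ≥95%
identity and ≥25 bp overlap) share one engine, written in C++:

1. **Candidate detection.** Reads sharing a k-mer (default k = 16 primary,
   12 secondary; k-mers occurring more than `max_occ = 100` times are
   treated as repeats and skipped) on either strand are candidate pairs.
   The index is a flat sorted array with a direct-indexed bucket table —
   a deliberate cache-friendly choice over hashing, which dominated run
   time in early profiling.
2. **Verification.** Each candidate pair is verified at its modal k-mer
   diagonal: a gapless identity check first, then a banded
   alignment (band 8 + L/50) only when indels are in play. Identity is
   always matches ÷ alignment columns, gap columns included — the single
   definition behind every identity threshold in the package.
3. **Greedy layout.** Accepted overlaps are processed in order of
   descending identity, then length, then a deterministic pair order, and
   merged with a union-find whose node transforms carry strand and offset;
   inconsistent late edges are ignored. This deterministic greedy layout
   replaces the multi-pass heuristics of the original assemblers, which
   are out of scope.
4. **Consensus.** Within each component, reads are laid left to right and
   aligned progressively against the growing consensus, casting per-column
   votes (A/C/G/T/gap). The consensus base is the majority, ties resolved
   in favour of the earliest vote; columns whose gap votes outnumber all
   base votes are dropped at finalization. A member whose alignment
   identity against the consensus falls below the pass threshold is
   *released* — returned to the pool as a singleton — and the component is
   re-polished without it. With `discard_low_identity = TRUE` releases are
   discarded instead, mimicking assemblers that drop unalignable reads;
   the default keeps the primary pass's discard count at zero, because the
   criteria by which the original tool discarded reads are not documented
   and cannot be reproduced.

The secondary pass runs the same engine over unigene consensus sequences;
merged products become `secondary_contig`s, member reads are unioned with
placements lifted (and clamped) onto the merged consensus, and no reads are
ever discarded. On error-free staggered reads the consensus equals the
source transcript exactly, which the suite asserts across seeds; with the
default error model, consensus accuracy against truth is ≥ 99% at the 1st
percentile in the reference-scale recovery run.

One property worth knowing: because layout is single-linkage and the
release threshold equals the overlap threshold, the unigene *count* is not
strictly monotone in `min_identity` when two transcripts diverge by almost
exactly the threshold — a borderline merge plus releases can yield a
contig-plus-singletons count exceeding the clean two-contig split. The
monotonicity test therefore exercises divergences far from the thresholds.

## Saturation statistics

`accumulation_curve()` is the bootstrapped rarefaction of the assembly:
the pooled reads, labelled by unigene, are shuffled (default 1,000
replicate sample orders) and scanned, tracking distinct unigenes after
each draw. The confidence band is the per-draw 2.5/97.5 percentile across
replicates — the published method names a 95% interval without specifying
its construction, and the percentile form is assumption-free. Milestones
(reads to tag 90/95/99% of unigenes) are read off the *mean* curve; the
last-ten statistic (reads per detection among the final ten unigenes) is
computed per replicate and averaged, the more defensible reading of an
ambiguous verbal definition. For the uniform case the bootstrap mean is
validated against the exact without-replacement expectation
$\sum_i \left(1 - \binom{T-m_i}{t}\big/\binom{T}{t}\right)$; note that on
the integer lattice (very small or near-final $t$) the percentile band
collapses to a point that the closed form need not hit, so the validation
falls back to the bootstrap mean being within 0.05 of the closed form
there. The replicate matrix is held in memory; at very large read counts
reduce `n_boot` accordingly.

## Taxonomic screening

`assign_lca()` reproduces the MEGAN-style assignment natively: the
best-hit taxon is that of the single highest-bitscore hit, and the LCA is
taken over hits with bitscore strictly greater than 75 *and* within 10% of
the query's top bitscore (read multiplicatively: ≥ 0.9 × top), requiring
at least three qualifying hits. "Greater than 75" is treated as strict —
the boundary convention is not documented in the method this follows.
`plastid_screen()` merges a query's hit intervals on the plastid genome
and flags genomic contamination when the merged span exceeds 3.5 kb
(strictly) or more than five distinct annotated genes are overlapped;
"adjacent genes" is interpreted as distinct genes overlapped by the merged
region. The homology search itself is never run here — the module consumes
standard 13-column tabular hits from any engine.

## Repeats and SSRs

`find_ssrs()` reports maximal perfect tandem repeats of 2–5 bp motifs at
minimum repeat counts 10/9/7/6 — reading the published "longer than 9, 8,
6, and 5 repeats" strictly. Motifs are canonicalized (lexicographic
minimum over rotations and reverse-complement rotations), motifs that are
repetitions of shorter motifs are excluded (this also removes
homopolymers), and overlapping calls at different motif lengths resolve to
the longest interval with ties to the shorter motif. `flank_check()`
replaces thermodynamic primer design with a flank-length proxy
(≥ 20 bp each side, inclusive). `screen_repeat_library()` aligns
class-labelled library elements locally on both strands (match +1,
mismatch −2, gap −3) and reports per-class match counts, merged masked
lengths and masked percentages; per-class intervals are merged before
summarizing, so nested or overlapping hits are not double-counted. One
best local alignment is taken per sequence–element–strand pair, so
multiple dispersed copies of the same element on one sequence are
summarized by their strongest occurrence.

## Functional annotation statistics

`longest_orf()` performs uncorrected six-frame translation and returns the
longest stop-to-stop (or edge-bounded) segment without requiring a start
codon. Segments are ranked by their stop-to-stop span in codons, with a
terminating stop counting toward the span; ties go to frame order
(+1, +2, +3, −1, −2, −3), then leftmost. The stop-inclusive span is what
makes a stop-terminated reading of a sequence rank at least as high as the
mirror-frame reading of the same nucleotides, giving deterministic,
convention-stable calls. `map_to_slim()` applies the true-path rule over
`is_a` and (by default) `part_of` edges — the behaviour of the annotation
suite this replaces; an `is_a`-only mode is available. `enrichment()`
counts *annotated sequences* (not term occurrences) per slim term, applies
the two-tailed Fisher exact test and Benjamini–Hochberg FDR across terms.
`detection_rate()` calls a reference gene detected on any hit with an
alignment strictly longer than 30 residues, and `set_overlap()` computes
exclusive Venn regions for two or three id sets.

## Pipeline and fixtures

`run_pipeline()` wires the stages clean → assemble → curve → tax → ssr →
repeats → annotate over a fixture directory, with per-stage input/parameter
hashing so a completed stage is a no-op on re-run. `make_fixture()` writes
complete synthetic bundles: `"tiny"` (40 genes, 400 reads; seconds end to
end, used by the test suite) and `"paper-like-mini"` (the reference
conditions above: 2,000 genes, 50,000 reads, normalized skew on). The
pipeline's homology hits are synthesized from the truth table
(`simulate_hits()`), mapping target-derived unigenes to plant tips and
contaminant-derived unigenes to bacterial tips of a small fixed taxonomy —
sufficient to exercise best-hit/LCA logic, not a model of real database
hits. At the reference scale the full simulate → clean → assemble →
screen cycle runs in a few minutes on one CPU; the problem sizes used in
the tests (tiny fixtures for the pipeline, the reference scale for the
recovery check, 500 sequences for the SSR oracle, 1,000 bootstrap
replicates for the curve law) were chosen so the whole suite completes
comfortably on a laptop.

## Known limitations

* The assembler is a faithful but deliberately simple OLC stand-in:
  single-linkage greedy layout, no flowgram-aware error correction, no
  quality-weighted consensus, no scaffolding, no splice-graph resolution.
* Consensus insertions relative to the running consensus are not added as
  new columns mid-contig (deletions vote gap columns); at the error rates
  simulated this costs well under 1% consensus identity, but it would bias
  against indel-dense data.
* Percentile confidence bands degenerate on the integer lattice at the
  extremes of the accumulation curve.
* The repeat screen reports one best local alignment per
  sequence–element–strand; dispersed multi-copy elements are undercounted
  relative to a full masking tool.
* Published dataset-scale figures that depend on external databases and
  the original binaries (raw-read archives, nr searches, the original
  assembler versions) are reproduced only as arithmetic identities through
  the report operations, not recomputed from raw data.
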