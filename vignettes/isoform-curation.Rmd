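---
title: "Curating transcript isoforms from spliced long-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating transcript isoforms from spliced long-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocurate)
```

## The problem

Long cDNA sequencing reads can span entire transcripts, which makes them the
most direct evidence available for transcript isoform structure. But two
systematic defects stand between a pile of spliced long-read alignments and
a trustworthy isoform catalogue:

1. **Truncation.** RNA degradation, shearing, incomplete amplification and
   sequencer loading bias all shorten reads, so most alignments cover only
   part of their source transcript. Reads from one isoform therefore
   disagree wildly about transcription start and end sites even when their
   internal splice structure is identical.
2. **Splice-boundary misalignment.** Spliced aligners occasionally place a
   splice donor at a nearby downstream GT dinucleotide instead of the true
   donor, particularly for reads with elevated indel rates near a site that
   offers several plausible donors. The resulting junction looks canonical
   but is wrong.

`isocurate` deals with both: junction-level validation removes misaligned
reads, and intron-chain collapse absorbs end variability.

## The procedure

### Junction validation

Every junction (the gap between consecutive exon blocks, in 0-based
half-open coordinates) of every alignment is subjected to two independent
checks:

* **Motif check.** The first two intronic bases must read `GT` and the last
  two `AG` on the plus strand, or `CT`...`AC` on the genomic forward strand
  for minus-strand introns. Unstranded alignments (typical for unoriented
  cDNA) are tested in both orientations and the orientation that passes is
  recorded; retained reads inherit the strand their motifs agree on. Only
  the major GT–AG spliceosomal class validates. The minor GC–AG and AT–AC
  classes fail by design: they are rare enough that admitting them costs
  more in rescued artifacts than it gains in genuine introns, and the check
  is a filter, not an annotator. (With this motif set a junction can never
  validate on both strands simultaneously — `GT` and `CT` are distinct — so
  the ambiguous-orientation branch in the code is a guard for wider motif
  sets rather than a reachable state.)
* **Evidence check.** The junction's exact coordinates must appear in a
  database of junctions observed in orthogonal short-read RNA-seq
  alignments. Matching is exact (0 bp tolerance): any coordinate offset is
  evidence of disagreement, not an invitation to rescue. Lookup ignores
  strand by default because short-read aligners themselves orient junctions
  from the motif, so coordinates alone identify an intron; a strand-aware
  mode exists.

A read is **retained** only if it is multi-exon and every junction passes
both checks. Single-exon alignments are never retained: with no junction to
validate there is nothing to distinguish a transcript from genomic
background or DNA contamination.

The donor-shift artifact is eliminated jointly: a shifted donor still sits
at a genuine GT (so the motif check passes) but its coordinates match no
short-read junction (so the evidence check fails). This division of labour
is why the evidence database must come from an independent platform.

### Collapse by junction code

Each retained read's identity is its **junction code** — chromosome, strand
and the ordered list of its intron coordinates, e.g.
`chr1:+:200-300,400-500`. Reads with identical codes are merged into one
isoform model whose extent is the furthest observed start and furthest
observed end over its members, and whose support is the member count.
Matching is exact: a single base of difference in any intron founds a
separate model. Output order is fixed (chromosome, start, code text) so
repeated runs are byte-identical.

A 5'- or 3'-truncated read that lost whole terminal exons has a code that
is a contiguous *sub-chain* of its source isoform's code and will found its
own model. Whether such fragments should be absorbed into the longer model
is genuinely ambiguous — a shorter chain can also be a real alternative
transcript with its own promoter or terminator. We therefore default to
exact-code identity (the conservative reading of duplicate removal) and
offer `subset_collapse()` as an explicit opt-in: it absorbs a model whose
chain is a contiguous window of a longer model's chain on the same
chromosome and strand *and* whose extent stays inside the longer model's
exon structure at that window (a fragment whose end runs past the next
intron of the longer model is structurally incompatible and is kept).
Fragments are processed shortest-chain-first and absorbed into the longest
compatible target, ties broken by code order, so support totals are
conserved and flow transitively up nested chains.

### Classification against a reference

A model is **annotated** if its code equals the code of some multi-exon
reference transcript. Otherwise it is a **novel isoform of a known gene**
if its span overlaps a genic region by at least one base, and a **novel
gene** model if it overlaps none. Genic regions are per-gene span unions
(introns included), and the overlap is strand-agnostic by default, the
plain bedtools-style reading of "intersect with genic regions"; both
choices have stricter alternatives behind flags (`strict_strand`, and an
exon-union region mode was deliberately not implemented — spans are the
defensible default for deciding gene membership, since a novel isoform of
a known gene frequently lives entirely inside introns).

Novel-gene models are clustered into **new gene regions** by
single-linkage any-overlap of their spans. Book-ended spans (one ends
exactly where the next starts) do **not** merge: with half-open
coordinates they share zero bases. Distinct exons are counted by exact
coordinates — alternative 5'/3' ends of "the same" internal exon count
separately, because any merging rule would need an arbitrary equivalence
threshold, and exact counting is reproducible.

Single-exon transcripts never enter any of this: the validation step
excludes them from reads and the code set excludes them from the
annotation side.

### Descriptive metrics

* `overlap_matrix()` — for each ordered pair of feature sets, the
  percentage of row elements whose *span* is overlapped (≥ 1 bp,
  strand-agnostic) by some column element. Spans, not exon chains, because
  the question it answers is gene-level agreement between datasets.
* `coverage_profile()` — per reference transcript, the fraction of its
  *exonic* bases covered by the union of read exons, plus length-binned
  histograms of all transcripts, any-overlap transcripts, and transcripts
  covered by **more than** 90%. The 90% rule is strict: exactly 0.90 does
  not qualify. Transcript length means exonic length, since read coverage
  is measured in exonic space.
* `splice_distance_profile()` — for each observed splice donor (intron
  start on `+`, intron end on `-`) and acceptor (the converse), the signed
  distance to the nearest annotated site of the same kind on the same
  chromosome and strand, within a window of ±W (default W = 50, 1-bp bins;
  sites farther than W from everything land in an overflow bucket).
  Positive means downstream in transcript orientation, so donor-shift
  artifacts produce a positive-side peak. Junctions whose strand is still
  unknown after motif inference are dropped with a warning, since donor
  and acceptor cannot be told apart without an orientation.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `min_support` | 1 | short-read count needed for a junction to count as evidence. 1 — any observation validates — is the weakest faithful reading; raising it can only shrink the retained set (tested as a monotonicity property). |
| junction match tolerance | 0 bp (fixed) | offsets are signal, not noise. |
| motif set | GT–AG only | see above. |
| `subset_collapse` | off | sub-chain absorption is interpretation, not observation. |
| `strict_strand` | off | genic overlap strandedness. |
| `window` (W) | 50 bp | distance-profile half-width; wide enough to capture near-miss peaks (which concentrate within 10 bp) with room to spare. |
| coverage bins | 0–6000 by 250 bp | transcript-length histogram granularity. |

## The simulator

`sim_config()` / `simulate_dataset()` generate a complete desk-scale study:
genome, true and deliberately incomplete ("emitted") annotations, long
reads, short-read junction evidence, and machine-readable ground truth.

What it emulates, and how:

* **Gene models.** 20 genes (default) on two 100 kb chromosomes, each with
  a backbone of 4–8 exons (80–300 bp) separated by introns of 60–400 bp,
  on a random strand. Alternative isoforms (2–4 per gene) skip one
  distinct internal exon each; skip junctions reuse the backbone's donor
  and acceptor, so they are canonical without extra construction — just as
  real cassette-exon events are.
* **Splice motifs.** Every intron is planted with the donor consensus
  `GTAAGT` and an acceptor ending `TTTCAG` in gene orientation (reverse
  complemented on the genomic strand for minus genes). The consensus
  carries a second GT at offset +4 — the natural decoy for the donor-shift
  artifact, mirroring the real failure mode of misalignment near sites
  with several plausible donors.
* **Truncation.** Independently at each end (P(5') = 0.3, P(3') = 0.2 by
  default — degradation hits 5' ends harder), a read loses up to 2 whole
  terminal exons and/or a uniform slice of its new terminal exon, leaving
  at least 20 bp. Internal junction coordinates are never perturbed, so a
  truncated read is an exact sub-chain of its isoform — matching the
  observation that truncated long reads still align accurately.
* **Donor shift.** Each junction observation is independently shifted with
  probability 0.10 (the default rate; the artifact affects roughly one
  read in ten in the data this emulates) to the nearest downstream GT
  within 10 bp — deterministic offset +4 given the planted consensus. If
  no GT existed in the window the junction would be left alone and the
  failed attempt recorded.
* **Short-read evidence.** Emitted per junction (not per read), covering
  every true junction of every gene — hidden ones included, since
  expression does not care about annotation — with counts uniform in
  3–30, each junction independently omitted with probability
  `p_junction_unsupported` (default 0). Artifact junctions are never
  emitted: short reads are the clean oracle by construction.
* **Hidden truth.** `n_hidden_genes` genes and `n_hidden_isoforms`
  non-primary isoforms of visible genes are withheld from the emitted
  annotation, giving the classifier genuine novel genes and novel isoforms
  with known answers.

What it does **not** emulate — and what passing tests therefore do not
show about real data: base-level sequencing errors and indels (the
artifact is injected at the coordinate level, not caused by alignment of
noisy sequence), non-canonical introns, overlapping or nested genes,
antisense transcription, expression-level variation across isoforms,
acceptor-side misalignment, and short-read false-positive junctions. The
simulator demonstrates that the *logic* of the pipeline is correct under
its stated assumptions; it cannot certify aligner behaviour on real reads.

## Numerical and design choices

* **Coordinates** are uniformly 0-based half-open internally; GTF's
  1-based closed convention is converted exactly once, at the I/O
  boundary. One convention internally prevents off-by-one drift between
  modules (and the GTF round-trip is tested as an identity).
* **Determinism.** Every output table is sorted by explicit keys; model
  ids are assigned after sorting; the run manifest contains no timestamps.
  Two runs on identical inputs are byte-identical, and the simulator is a
  pure function of its seed.
* **Degenerate inputs.** Empty read sets, empty junction databases, empty
  model sets and annotation-free chromosomes all flow through and produce
  empty (not missing) outputs; an empty feature set's row in the overlap
  matrix is `NA` rather than a fabricated percentage.
* **IUPAC codes** in genome FASTA are collapsed to `N` with a warning. `N`
  can never satisfy a motif check, so the treatment is conservative rather
  than permissive.
* **Problem sizes.** The test-suite and acceptance runs use 5–20 genes,
  up to ~750 reads and 100 kb toy genomes — large enough that every code
  path and both strands are exercised hundreds of times per run, small
  enough that the whole suite completes in a couple of minutes. The
  per-base brute-force oracles that cross-check the interval arithmetic
  run on ≤ 10 kb toys, where exhaustive computation is trivially
  affordable.

## Known limitations

* BED12 is the alignment contract; SAM/BAM input would need prior
  conversion.
* One extent per code: the collapse keeps a single furthest start/end per
  intron chain, so genuinely distinct promoters of the same splice
  structure are not separated.
* Novel single-exon transcripts are invisible to the whole pipeline by
  design.
* The short-read junction database is trusted as clean; a false junction
  in the evidence validates any read that carries it.
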