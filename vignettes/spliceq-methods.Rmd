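---
title: "Counting and testing RNA processing changes with spliceq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and testing RNA processing changes with spliceq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceq)
```

`spliceq` detects changes in gene expression and RNA processing between
RNA-Seq samples. This vignette explains the models and procedures it
implements, the parameters that matter, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## Coordinates and gene models

All internal coordinates are 0-based half-open; SAM input (1-based) is
converted at the parser boundary and every emitted table carries a header
comment stating the convention. Transcripts are grouped into genes
strictly by the annotation's `gene_id` — no overlap-based re-clustering is
attempted, so the gene space is exactly what the input annotation defines.
A gene model is the union of all exons of all of its transcripts; its
length (the RPKM denominator) is the summed length of the merged union
blocks. Known splice sites are taken only from *internal* exon boundaries:
the terminal boundary of a transcript is a transcript end, not evidence of
splicing.

## The junction alignment space

Short ungapped aligners cannot place reads across introns, so the package
materializes a junction library: every known intron-start site of a gene
paired with every known intron-end site downstream of it in transcription
direction. Using whole-gene half-junction sets (rather than per-transcript
adjacency) yields all forward combinations, including skips never
annotated as transcripts. Each contig consists of `overhang` exonic bases
on both sides of the splice point:

* `overhang` (nt), default `read_len − 1`. A full-length read aligned
  anywhere on such a contig must cross the splice point with at least one
  base on each side, so every junction hit is informative. Flanks are
  truncated, never padded, when the exon-union block or chromosome is
  shorter, and the actual flank lengths are recorded in the contig name so
  liftover is exact.

Contig alignments are lifted to genome blocks abutting the intron. A hit
entirely inside one flank is re-classified as a plain genomic alignment.
After liftover, a genome hit and a junction hit with identical blocks are
de-duplicated *before* uniqueness is assessed — otherwise every junction
read near a flank boundary would spuriously look multi-mapped.

**Unique-best selection.** Candidates of one read end are ranked by
mismatch count only; gaps and base qualities are not scored, matching the
ungapped short-read regime this selection models. Exactly one best
candidate gives a placement; none, a non-match; several, a multi-match.
Duplicate-position reads are deliberately not collapsed (no PCR
de-duplication step is modeled). For paired data, a pair with one uniquely
placed end keeps that end as a single-end rescue; rescued ends are
re-screened from existing candidates rather than re-aligned with different
parameters.

## Counting rules

A read counts toward any gene whose exon union contains *all* of its
aligned positions, on either strand; a single intronic or intergenic base
disqualifies it for that gene, and overlapping genes can each count the
same read. The containment rule keeps the count interpretable as "reads
consistent with the mature transcript" at the cost of losing boundary
reads; because the downstream statistic compares the *same* gene across
samples, that loss cancels.

Two-isoform events hold disjoint evidence sets for isoforms A and B:

* **Cassette exons** — one candidate per internal exon-union block,
  whether or not skipping is annotated. Inclusion evidence is junctions
  landing on either block boundary; skip evidence is junctions from a
  known site strictly 5' of the block to a known site strictly 3' of it,
  anchored in known splice sites of the host gene. Both sides are
  junction-only: exon-body reads are excluded so that neither side of the
  contingency table scales with exon length. (Whether body reads should
  augment inclusion counts was left open by the design; junction-only was
  chosen for length-unbiasedness, and is the variant validated by the
  generator's analytic expectation.)
* **Retained introns** — one candidate per exon-union gap whose flanks are
  *locally constitutive*: every transcript spanning the gap has exons
  ending and beginning exactly at its boundaries, and at least one
  transcript must span it. Intron-interval reads support retention; reads
  contained in either flanking block support splicing.
* **Alternative terminal exons** — for every distinct TSS but the 5'-most
  (and symmetrically every PACS but the 3'-most, in transcription
  direction), candidate-terminal-exon intervals (minus exonic regions of
  more-extreme transcripts) are compared against exon-union regions more
  distal than the candidate site. Overlaps are resolved by subtracting the
  distal side; events with an empty side are dropped.

Junction evidence requires the placement to cross exactly that junction
with both anchors at least `min_anchor` nt (default 1 — the library's
`read_len − 1` overhang already guarantees 1-nt anchors; raise it for
imported spliced BAMs with very short anchors). Interval evidence requires
full containment by a gap-free read; reads crossing unannotated gaps
support no event evidence but still count for genes if exon-contained.
Counts for lane groups are sums of member-lane counts.

## The change statistics

**Effective totals by minimize significant changes (MSC).** Comparing raw
totals assumes the library-size ratio is the null ratio for unchanged
genes, which fails when a few very highly expressed genes change. MSC
estimates the fraction `q2` of reads belonging to sample 2 so as to
approximately minimize the resulting number of significantly changed
genes: each gene with `g ≥ 1` reads contributes a Wilson score interval
for `q2` (the range over which that gene is not significantly changed),
the unit interval is cut into windows of width `1e-4`, each interval votes
for every window it overlaps, and the estimate is the midpoint of the
most-voted window — the arithmetic mean of midpoints under ties. Genes
with zero reads are excluded: their interval is [0, 1], which adds a
constant to every window and cannot move the argmax. The Wilson interval
was chosen for its coverage at extreme proportions, where the optimizer
often operates. The window width trades resolution against vote
granularity; `1e-4` makes the discretization error negligible relative to
any downstream effect. In seeded simulations (2000 genes, log-normal
depths with median 200 reads per gene, 5% of genes changed 8-fold) the
estimate recovers the true fraction within ±0.005; varying the confidence
level across 0.90/0.95/0.99 moves it by a few windows times `1e-4` — far
below any practical consequence, though not literally within one window.

**Binomial change test.** With effective totals `n1`, `n2` and per-gene
counts `g1`, `g2`, the count `g2` is Binomial(`g`, `q2`)-distributed under
no change. The two-tailed P-value sums all outcomes whose probability does
not exceed the observed outcome's, with relative tolerance `1 + 1e-7` so
that floating-point noise does not exclude ties — the same convention as
R's `binom.test`, against which the implementation is verified to 1e-12.
This models *sampling* noise only; it is the right tool for technical
comparisons (lanes, pooled lane groups) and will overstate significance
across biological replicates (see Limitations).

**Event tests.** Each event yields the 2×2 table of isoform A/B evidence
counts in the two samples. When all four expected values exceed 5 the
chi-squared test with a capped continuity correction
(`min(0.5, |O − E|)`, keeping the balanced-table statistic at zero) is
used; otherwise the two-sided Fisher exact test with the same
no-more-probable-than-observed convention. Fisher is conservative in this
regime: on seeded null tables its type-I error at nominal 0.05 stays below
nominal (measured by the acceptance suite).

**Calls, folds and multiplicity.** Fold changes are computed on effective
totals, `(g2/n2)/(g1/n1)`; empty denominators yield explicit `0`/`Inf`
markers rather than pseudo-counts, so one-sided extremes (e.g. cassette
exons with zero skip reads) remain visibly extreme. A gene or event is
called up (down) when `p ≤ p_cutoff` and the fold is at least
`fold_cutoff` (at most its reciprocal). P-values are not adjusted by
default; `n_tests × p_cutoff` bounds the expected false positives under
the global null (27,389 genes at 1e-4 gives 2.74), and Benjamini–Hochberg
adjustment is available behind a flag.

**Microarray path.** Probe intensities (background-subtracted upstream)
are summarized per gene as the median over *detected* probes — probes
positive in every array — and optionally compared with Welch's t-test.
Degenerate zero-variance input returns 1 for equal means and 0 otherwise.

## QC computations

Read-type tallies count every read end into non-match / multi-match /
unique categories (paired-unique and single-rescued for paired data), and
matching types classify placements as junction, exon, intron or
intergenic with junction taking priority. Paired ends are classified in
fixed priority order — different chromosomes, same strand, minus end
wholly upstream, an annotated intron entirely inside the open interval
between the inner ends, else canonical. The canonical distance is the
signed genomic distance between the last sequenced bases of the two ends
("last" meaning the rightmost aligned base of the plus end and the
leftmost of the minus end, i.e. the sequencing-direction end of each
read); it is negative for overlapping alignments. The complete library
size adds both read lengths and both adaptor lengths to the median
distance (172 nt for 36-nt reads and 50-nt adaptors).

Expression correlations between samples are Pearson correlations of
`log2(RPKM + 1)` profiles with average-linkage ordering on `1 − r` — a
concrete choice among reasonable transforms, made for its robustness to
the dynamic range of RPKM. Background sets match changed genes to
unchanged genes greedily (descending count, nearest `log((c+1)/(t+1))`,
without replacement, lexicographic tie-break); matching on raw counts
rather than RPKM is recommended to avoid transcript-length bias.

## The synthetic-data generator

The generator emulates the data regimes the toolkit targets: a compact
multi-chromosome genome; genes with 1–5 exons and isoform structures for
cassette skipping, intron retention (simulated in reads but deliberately
*not* annotated — retention is an observation, not an annotation, and an
annotated retention transcript would dissolve the candidate event),
alternative TSS and alternative PACS (strand-aware, so the novel terminal
exon is placed at the transcription-appropriate end); log-normal expression
levels; per-sample depth factors (the true `q2`); per-gene fold changes;
per-event isoform fractions; and paired-end fragment geometry
(Normal outer distance, FR orientation). Reads are emitted pre-aligned as
genome-space SAM with N gaps — the aligner itself is out of scope — and a
FASTQ emitter exists for integration with external aligners. Each sample's
stream is seeded from `(seed, sample index)`, so adding a sample never
perturbs another's reads, and identical configurations are byte-identical.

Defaults: 36-nt reads, 50-nt adaptors, 200±30-nt inserts, exons 150–250
nt, introns 80–200 nt, 5% changed genes at fold 8, isoform fraction 0.5.
These mirror the early-generation short-read regime the statistics were
designed for.

Not emulated: sequencing errors and base qualities (placements carry
`NM:i:0`), PCR duplicates, multi-mapping reads (each simulated read has
one true placement), overlapping genes, and biological replicate variance.
Passing tests on this generator therefore validate the counting and
testing machinery — coordinate arithmetic, evidence assignment, estimator
recovery, error control under sampling noise — not robustness to alignment
artifacts or biological overdispersion.

For cassette genes the expected junction-evidence fraction is *not* the
isoform fraction: the inclusion isoform offers two crossable junctions and
a longer transcript, the skip isoform one junction and a shorter
transcript. `expected_cassette_fraction()` computes the analytic
expectation under uniform read starts, and recovery is asserted within
three binomial standard errors.

## Problem sizes and numerical choices

The test and acceptance runs use: exhaustive binomial-oracle comparison
for all outcomes with `g ≤ 30` across `q2 ∈ {0.1, …, 0.9}` (tolerance
1e-12); exhaustive Fisher comparison against direct hypergeometric
enumeration for every table with total ≤ 40; 10,000 null tables for the
conservativeness check; 2000-gene count simulations for MSC recovery; and
a 2000-gene read-level simulation (median 100 expected reads per gene,
~0.9M placements) for end-to-end recovery of planted fold changes (FDR at
P ≤ 1e-4) and a planted cassette inclusion fraction. These sizes were
chosen so each property is measured with comfortable statistical margin on
a single CPU.

Tie-breaks and degenerate inputs are fixed deliberately: empty tables test
to P = 1; `g = 0` genes give P = 1 and an undefined fold (`NA`), called
unchanged; trials-zero Wilson intervals are [0, 1]; zero canonical pairs
give a missing library size; zero-variance samples give missing
correlations.

## Limitations

* The binomial model captures sampling noise only; for biological
  replicates an overdispersed model (negative binomial, moderated
  variance) should be layered on the same counts — deliberately out of
  scope here.
* Junction evidence relies on annotated splice sites; novel splice sites,
  alternative donors/acceptors within exons, and sequence variants are not
  modeled.
* The cassette inclusion:skip ratio loses precision when one side
  approaches zero even though its P-value remains valid; infinite ratio
  markers make these regimes visible rather than smoothing them away.
* MSC assumes most genes are unchanged; with a majority of changed genes
  the voted window no longer tracks the technical depth ratio.
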