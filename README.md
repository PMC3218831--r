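# spliceq

RNA-Seq gene expression and RNA processing change detection, built around a
splice-junction alignment space and a binomial sampling model with
robustly estimated effective library sizes.

`spliceq` is a back-end toolkit for bulk RNA-Seq (and, for its
summarization path, Affymetrix-style probe intensities). It is aimed at
analysts who have alignments (SAM/BAM) and a transcript annotation and want
per-gene and per-splicing-event change calls between two samples or lane
groups, together with the standard QC summaries — without fitting a
biological-variance model. Its statistics target *technical* comparisons
between sequencing lanes or pooled lane groups.

## What it computes

**Junction library.** From each gene's annotated splice sites the package
enumerates every forward splicing combination (exon *n* to exon *m*, *m* >
*n*, in transcription direction) and emits junction contigs: `L` exonic
bases on each side of the splice point (default `L = read_len − 1`, so any
full-length read aligned to a contig crosses the junction). Reads aligned
to these contigs are lifted back to genome coordinates, and a read is used
only if it has a **unique best** (minimal-mismatch) placement across the
genome and junction spaces; paired-end reads falling back to single ends
when only one end places uniquely.

**Counting.** A read counts toward every gene whose exon union contains all
of its aligned positions (possibly split by a junction, either strand).
Expression is reported as RPKM: reads per kilobase of gene model (exon
union) per million uniquely aligned reads. Two-isoform RNA processing
events — cassette exons (inclusion vs. skip junction reads), retained
introns (intron reads vs. locally constitutive flanking exon reads) and
alternative terminal exons (candidate terminal exon vs. more distal
exons) — are counted into 2×2 contingency tables.

**Statistics.** For gene-level changes between samples with counts g₁, g₂
(g = g₁ + g₂), the count g₂ is modeled as Binomial(g, q₂) with
q₂ = n₂/(n₁ + n₂), where n₁, n₂ are *effective* totals estimated by
**minimize significant changes (MSC)**: every gene's Wilson 95% confidence
interval for q₂ votes for the windows of width 10⁻⁴ it overlaps in [0, 1],
and q₂ is the midpoint of the most-voted window (ties averaged). This
(approximately) minimizes the number of significantly changed genes, so
normalization is not dominated by a few highly expressed or changed genes.
Event tables are tested with the two-sided Fisher exact test, switching to
the chi-squared test when all four expected values exceed 5. P-values are
unadjusted by default (a Benjamini–Hochberg option exists); at the usual
cutoff of P ≤ 10⁻⁴, testing all 27,389 mm9 genes is expected to yield no
more than 3 false positives under the global null.

**QC and comparison.** Read-type and matching-type tallies, paired-end
distance classification (different chromosome / same strand / minus end
upstream / intron between / canonical) with the complete-library-size
arithmetic (median distance + 2·read length + 2·adaptor length),
expression-profile correlation matrices, ECDF curves, expression-matched
background sets, 4way cross-experiment matching with quadrant
classification, and comparison similarity matrices.

**Synthetic data.** A deterministic generator (`sim_gene_plan`,
`sim_config`, `simulate_experiment`) builds a toy genome, multi-isoform
annotation (cassette, retained-intron, multi-TSS/PACS structures) and
pre-aligned reads with known levels, fold changes, isoform fractions, depth
ratios and paired-end geometry. The whole test suite runs off this
generator; no external data is needed.

## Worked example

Simulate a two-sample experiment (200 genes, 5% changed 8-fold, depth
ratio 1.5:1 so the true q₂ is 0.4), then run the full chain:

```r
library(spliceq)

plan <- sim_gene_plan(200, seed = 42, prop_changed = 0.05, fold = 8)
cfg  <- sim_config(plan, samples = data.frame(
          sample_id = c("ctl", "trt"), depth = c(1.5, 1),
          apply_fold = c(FALSE, TRUE)), seed = 42)
dir  <- file.path(tempdir(), "demo")
simulate_experiment(cfg, dir)

models <- load_gene_models(read_annotation(file.path(dir, "annotation.gtf")),
                           genome_ref(file.path(dir, "genome.fa")))
psets  <- import_project(file.path(dir, "sample_sheet.tsv"), models)
gct    <- count_genes(psets, models)
tt     <- compare_groups(gct, "ctl", "trt")
attr(tt, "norm")
#> <msc_norm> q2 = 0.397591 (182 votes, 46 tied window(s) of width 1e-04)
#>   N = 25892, n1 = 15597.566, n2 = 10294.434

sig <- tt[tt$call != "unchanged", ]
head(sig[order(sig$p), c("gene_id","g1","g2","fold_change","p","call")], 5)
#>     gene_id  g1   g2 fold_change         p call
#> 184  G00184 191 1009      8.0041 6.88e-220   up
#> 62   G00062 127  622      7.4206 5.55e-131   up
#> 98   G00098 119  556      7.0792 2.79e-114   up
#> 170  G00170  47  331     10.6705  4.13e-83   up
#> 12   G00012 340   19      0.0847  9.67e-52 down
```

The MSC estimate (0.3976) recovers the planted read fraction 0.4 from the
unchanged majority of genes, and the recovered fold changes sit at the
planted value of 8 (the binomial P-values are extreme because these are
pure technical replicates by construction). Event tables work the same
way:

```r
ev  <- find_events(models)
ect <- count_events(psets, ev)
et  <- event_change_test(ect, "ctl", "trt", p_cutoff = 0.01, ratio_cutoff = 2)
head(et[order(et$p), c("event_id","a1","b1","a2","b2","ratio_change","p","method")], 3)
#>                        event_id a1 b1 a2 b2 ratio_change      p method
#> 161  G00044:alt_tss:29814:29892 13 20  1 19        0.081 0.0150  chisq
#> 223 G00062:cassette:42497:42565 15  1 50 25        0.133 0.0335 fisher
#> 176  G00046:alt_tss:30805:30871  6 44  7 12        4.278 0.0346 fisher
```

A command-line front door covers the same pipeline
(`inst/scripts/spliceq`): `simulate`, `build-junctions`, `find-events`,
`import`, `count`, `test`, `qc`, `compare`, each writing provenance-stamped
TSV tables.

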