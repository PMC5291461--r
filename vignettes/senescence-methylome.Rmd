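---
title: "Methods: methylome-transcriptome analysis of replicative senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-transcriptome analysis of replicative senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senemeth)
```

## The analysis model

Replicative senescence of cultured fibroblasts is reached after tens of
population doublings, and DNA methylation drifts along the way. The
analysis implemented here works on single BeadChip arrays per passage and
single expression arrays per condition — the design of the study this
pipeline reproduces — so no variance model is fitted anywhere; every
quantity is a deterministic function of the measured values and the
published thresholds. That is a real limitation (no per-probe standard
errors, no moderated statistics as in limma-style modelling), and it is
deliberate: the pipeline's job is to reproduce and stress-test this
specific thresholding analysis, not to improve on it.

### Methylation calling

Methylation per CpG probe is summarised as
$\beta = M / (U + M + 100)$, with $M$ and $U$ the methylated and
unmethylated allele intensities; the offset of 100 (intensity units)
regularises low-signal probes and keeps $\beta < 1$. Probes are
eliminated from *all* analyses when any used sample has a detection
p-value strictly above 0.05 or a blank β — the analysis-set-wide rule
keeps every contrast on one probe universe. Differential methylation is
called from $\Delta\beta = \beta_{test} - \beta_{control}$ with
inclusive boundaries: hyper at $\Delta\beta \ge 0.2$, hypo at
$\Delta\beta \le -0.2$. The boundaries are implemented with a $10^{-9}$
tolerance so that decimal β values landing exactly on the threshold are
treated inclusively despite binary floating-point representation; this
is far below the resolution of array data.

A probe called at the final passage is flagged *sequential* when its β
is monotone across every consecutive passage pair, within a tolerance
ε (default 0). Monotonicity is non-strict: equal consecutive β values
count as drift, since "stepwise" change does not require every step to
be positive. ε is exposed because small inter-array noise can interrupt
an otherwise clear drift; with the default the flag is the strict
pairwise rule.

### Expression calling

One-colour intensities are floored at the low-signal cutoff (1.0,
replace-with-cutoff), log2-transformed, and shifted per sample so the
75th percentile is zero. Percentiles use linear interpolation between
order statistics (`stats::quantile` type 7); published descriptions of
percentile normalization typically name only the percentile, so one
interpolation convention has to be fixed — type 7 is R's default and is
documented here as the package's convention. miRNA arrays use the same
chain with a 90-percentile shift and no cutoff.

Fold change per gene is $2^{\overline{\log_2 x_{test}} -
\overline{\log_2 x_{control}}}$ — the ratio of geometric means, the
natural choice given log-space normalization. Calls are inclusive at
2-fold (up) and 0.5-fold (down); a separate 3-fold selector exists
because downstream functional-annotation tools want shorter lists.
Probes sharing a RefSeq ID are aggregated by the per-sample mean before
fold changes. Sample clustering uses the uncentered correlation
$r_u = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ as distance
$1 - r_u$; linkage is not specified by the original description, so
average linkage is the default and is configurable.

Note one boundary of the rescale-invariance property: per-sample
rescaling of raw intensities is absorbed exactly by the percentile
shift only while intensities stay above the low-signal floor — the
floor clamp is intentionally not scale-invariant.

### Promoter classification

Promoters are classified from sequence alone: GC fraction
$\ge 0.5$ and Gardiner–Garden observed/expected CpG ratio
$(\#CpG \cdot L)/(\#C \cdot \#G) \ge 0.6$ (both inclusive) define a CGI
promoter. Choices the criteria leave open, fixed here and configurable:

* **Window extent.** The source analysis states the criteria but not
  the promoter extent; the default window is [TSS − 1000, TSS + 500) in
  transcription direction, a conventional promoter span. Results such
  as the CGI/non-CGI split of distance distributions can be sensitive
  to this choice on real genomes.
* **N handling.** Ns are excluded from the effective length $L$ and
  from all counts; windows above a configurable N fraction (default
  0.5) are errors, all-N windows always.
* **Whole-window statistics.** No sliding sub-windows — the simplest
  consistent reading of the criteria.
* **Case and strand.** Soft-masked lowercase bases count as their
  uppercase base. Statistics are computed on the plus strand; because
  CpG is its own reverse complement and GC content is
  strand-symmetric, classification is strand-invariant (tested for
  every planted window).

### Integration

Each probe maps to the minimum-distance TSS on its chromosome, kept
only within 8 kb (inclusive). Distance is unsigned ($|pos - tss|$);
probe strand is irrelevant for a strand-symmetric CpG. Every isoform
row competes independently; ties — equidistant TSSs, or several
accessions sharing one TSS — resolve to the lexicographically smallest
accession, making the mapping deterministic and row-order-invariant.
Joint calls flag concordant pairs (hyper + down, hypo + up at the
methylation and expression thresholds above). Counts are per CpG site,
not per gene: several probes may legitimately map to one gene, and
deduplicated gene-level views are derived summaries.

### The miRNA axis

Manifest probes whose gene annotation matches an anchored miRNA
host-gene pattern (`MIR` followed by a digit or `LET`, so `MIRROR1`
never matches) and lies in a promoter feature (TSS1500 or TSS200 by
default; the restriction is configurable because "promoter region" is
not formally defined in the source analysis) are the miRNA promoter
probes. A miRNA is concordant when a promoter probe is hypermethylated
and its expression falls at least 1.5-fold — or the mirror, which is
always evaluated even though the motivating dataset had no mirror hits.
Host-gene symbols and mature miRNA names are harmonized through a
user-supplied alias table; no nomenclature logic is hard-coded. The
final filter keeps genes targeted (per an input target table — target
prediction is out of scope) by at least two same-direction concordant
miRNAs with their own expression change opposite past 2-fold.
"At least two" rather than "more than two": the published result table
this reproduces contains many genes with exactly two supporting
miRNAs, so the inclusive reading is the one consistent with the
published output. The bundled reference table
(`reference_triad_table()`: 27 genes, 7 miRNAs) is reconstructed
exactly by the filter in the test suite.

## The synthetic-data generator

The generator exists so every pipeline stage can be validated against
planted truth without downloads. Its defaults are the study conditions
the tests run under:

* **Passage series**: four passages (PDL 36/49/69/85 labels), 1,000
  probes, 10% hyper- and 10% hypo-drifting at 0.1 β per step, noise
  σ = 0.01. Drifting probes start in [0.05, 0.25] (hyper) or
  [0.75, 0.95] (hypo) so three steps of drift stay clear of the β
  bounds; the final-passage Δβ of 0.3 sits well above the 0.2
  threshold, which is why recall ≈ 1 at this noise level is expected,
  not tuned. Noise is truncated Gaussian (clipped to [0, 1]) — simple
  and sufficient for threshold-calling tests; the source study reports
  no β variance estimates, so σ is a free parameter chosen small
  relative to the call threshold.
* **Detection p-values**: good entries from Uniform(0, 0.04), planted
  failures from Uniform(0.06, 1) — no mass on the 0.05 boundary, so
  the strict-inequality rule is never exercised by luck.
* **Toy genome**: promoter windows are built compositionally from
  10-bp tiles (all tiles end in A and start with C or G, so shuffled
  tile junctions never create a CpG), giving *guaranteed* GC 0.60 /
  O/E 1.0 for CGI and GC 0.40 / O/E 0.2 for non-CGI promoters rather
  than sampling until criteria are met. Each TSS is placed so its
  default promoter window coincides exactly with the planted window;
  strands alternate; windows never overlap by construction (checked).
* **Expression**: planted up/down genes differ by 2 on the log2 scale
  (4-fold, comfortably past the 2-fold call) with 0.1 log2 noise; a
  fifth of genes carry two probes to exercise aggregation. Concordant
  miRNAs are planted with Δβ +0.3 promoter probes and 2.5-fold
  expression loss; triad genes are up-regulated targets of 2–3
  concordant miRNAs, decoys of exactly one, and one flat-expression
  gene is targeted by two concordant miRNAs to exercise the gene-level
  cutoff.

What the generator does **not** emulate: array image processing, dye
bias, batch effects, replicate structure, the correlation of
methylation drift with genomic context, or realistic β distributions
(real arrays are bimodal with heteroscedastic noise). Passing tests
therefore demonstrate the correctness of the implemented rules, not
performance on real arrays.

## Problem sizes and determinism

The validation suite runs the generator at 1,000 probes, 100 genes, 10
oracle seeds — sizes chosen so every brute-force oracle (all-pairs
nearest-TSS scan, exhaustive Venn membership enumeration, direct
formula evaluation) stays exact and fast while still exercising ties,
boundaries and empty categories. All randomness flows from a single
integer seed per generator call; a fixed seed reproduces every output
bit-identically, and the acceptance script derives all its seeds from
its `--seed` flag.

## Known limitations

* Single-array contrasts: no replicate variance, no p-values on calls.
* The promoter window extent and the miRNA "promoter region" are
  configurable conventions, not published constants; genome-scale
  results can be sensitive to both.
* Gene-level deduplication of probe-level integrated calls is reported
  as a summary but no specific published gene count is calibrated.
* 27K/450K cross-platform harmonization beyond probe-ID intersection is
  out of scope, as are BeadChip intensity normalizations (BMIQ/SWAN),
  functional-term enrichment itself (an external gene-to-group map is
  consumed), and miRNA target prediction (a target table is consumed).
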