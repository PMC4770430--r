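---
title: "Calling DMRs and collaborative methylation patterns from binned MBD-seq coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DMRs and collaborative methylation patterns from binned MBD-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrpatterns)
```

## The analysis in one paragraph

MBD-seq (methyl-CpG-binding-domain capture sequencing) yields read coverage
proportional to DNA methylation. `dmrpatterns` takes per-sample read counts
in fixed 100-bp genomic bins, normalizes them to reads per million (rpm),
and compares tumor sample groups against non-tumor controls bin by bin with
the Wilcoxon rank-sum test. Runs of consecutive significant bins inside four
gene-anchored regions are called differential methylation regions (DMRs).
Each gene's TSS methylation state is then paired with the state of its
distal promoter, gene body, and TES regions to yield twelve TSS-anchored
collaborative differential methylation patterns (CDMPs), whose gene sets are
compared with hypergeometric overlap tests and cross-tabulated against
differential-expression calls.

## Gene-anchored regions

Each gene contributes four strand-aware, half-open intervals:

| region | plus strand | width |
|---|---|---|
| Distal  | `[TSS − 100 kb, TSS − 2 kb)` | ≤ 98 kb |
| TSS     | `[TSS − 2 kb, TSS + 2 kb)`   | 4 kb |
| Genic   | `[TSS + 2 kb, TES − 1 kb)`   | span − 3 kb |
| TES     | `[TES − 1 kb, TES + 1 kb)`   | 2 kb |

The layout is mirrored on the minus strand, and all intervals are clipped to
the chromosome. The four intervals tile `[TSS − 100 kb, TES + 1 kb)` exactly
— no overlap, no gap — which the test suite asserts on random genes. Genes
spanning ≤ 3 kb have an empty Genic interval; they are kept (their other
regions are still analyzed) but can never receive a Genic DMR.

Coordinates are 0-based half-open throughout, matching BED/bedGraph
conventions; GTF input is converted on load. A bin belongs to a region iff
its *start* lies inside the region interval. The convention for partial bins
is not forced by anything upstream; the bin-start rule was chosen because it
makes membership unambiguous and keeps the four bin lists disjoint.

Transcript selection: transcripts whose TSS or TES coordinate collides with
a transcript of a *different* gene are dropped (both parties), then the
longest isoform per gene is kept. The alternative — treating any shared
coordinate as disqualifying, including between isoforms of one gene — is
available via `collision_scope = "any"`. The default was chosen because the
gene-level pattern classification needs exactly one record per gene, and
discarding a whole gene because two of its own isoforms share a promoter
would be self-defeating.

## The DMR caller

For a comparison of tumor group A against control group B, every bin of
every region is tested with the two-sided Wilcoxon rank-sum test on the
samples' rpm values. The exact null distribution is used when both groups
have ≤ 10 samples and the bin has no tied values; otherwise the normal
approximation with tie correction and continuity correction (the same
formulas as `stats::wilcox.test`, reimplemented in C++ for genome-scale
throughput and cross-checked against both `wilcox.test` and full
permutation enumeration in the tests).

A bin *qualifies* when

* `p < 0.05`,
* `|log2 FC| ≥ 1`, where the fold change compares group-mean rpm with a
  pseudocount, and
* the group means actually differ (direction hyper or hypo).

A DMR is a maximal run of consecutive qualifying bins of uniform direction
spanning at least **3 bins** (Distal, TSS, TES) or **5 bins** (Genic), whose
run-averaged rpm in the higher-methylated group is at least **0.2 rpm**.
Runs are never merged across a non-qualifying bin, and a direction flip
breaks a run.

Numerical and procedural choices worth stating explicitly:

* **Which thresholds apply per bin vs per run.** The p-value and fold-change
  thresholds define bin qualification; the 0.2 rpm floor is averaged over
  the run (it is the only threshold phrased as an average). All three are
  parameters of `dmr_params()` if a different reading is wanted.
* **Pseudocount.** Group-mean rpm can be zero; the fold change is computed
  as `log2((mean_a + c) / (mean_b + c))` with `c = 0.1` rpm by default
  (`fc_pseudocount`). At typical methylated-region coverage the pseudocount
  is negligible; its only job is to keep zero-coverage bins finite.
* **No multiple-testing correction** is applied to bin p-values: the
  consecutive-run requirement is the error control. The null-calibration
  test (below) measures what that control actually buys.
* **Ties and constant bins.** A bin whose values are identical in both
  groups has zero rank variance and is assigned p = 1 (never significant).
* **Comparisons.** Any tumor group (L, H, VH, or ALL = all tumors pooled)
  can be compared against N, ADJ, or N+ADJ (samples pooled before testing —
  pooling, not meta-analysis, is the natural reading of a "combined"
  control). A gene-region is marked differential for a tumor group if it is
  differential against N *or* ADJ; when the two controls disagree in
  direction the status is "both" and the gene is excluded from
  single-direction pattern classes (exclusions are counted, not silently
  dropped).

## CDMP classification

For each comparison, a gene's TSS status (`S1` hyper / `S0` hypo) is paired
with each partner region's status (Distal `D`, Genic `G`, TES `E`; `1`
hyper / `0` hypo), giving up to three labels per gene from the twelve
possible (S1D1 … S0E0). Genes whose TSS status is "none" or "both" receive
no label — the patterns are TSS-anchored by design. Classification happens
per (tumor, control) comparison first; the N-or-ADJ union is applied at the
gene-set level afterwards. The opposite order (unite statuses, then
classify) is also reachable by passing united statuses to
`classify_cdmp()`; the default order is reported with the outputs.

Pattern gene sets are compared with the upper-tail hypergeometric test,
`P(X ≥ overlap)`, computed in log space so that extreme significance does
not underflow. The universe is the set of genes with testable bins in both
regions of the pairing — the smallest defensible universe; it is reported
alongside every test.

## What the synthetic data emulate — and what they do not

`sim_config()` defines a seeded study: a toy genome whose genes sit ≥ 204 kb
apart (so neighbouring distal windows cannot be forced to overlap), grouped
binned coverage, and per-group DE tables. Defaults mirror the study design
the package targets: five groups of 8 N / 12 ADJ / 13 L / 12 H / 7 VH
samples.

* **Count noise** is negative binomial with dispersion 0.1. The caller
  tests ranks, so any overdispersed family would do; NB is the standard
  choice for sequencing counts and has a single dispersion knob.
* **Baseline coverage** is 10 expected reads per 100-bp bin. At the ~50M
  reads per sample typical of MBD-seq libraries, a bin at the 0.2-rpm DMR
  floor carries ~10 reads; methylated-region coverage sits at tens of reads
  per bin, so 10 is a realistic enriched-region baseline rather than a
  genome-wide average.
* **Plants** multiply (hyper) or divide (hypo) the expected count by a
  4-fold shift across a contiguous stretch of bins of one region, for the
  affected tumor groups only; N and ADJ stay at baseline. ADJ can
  optionally leak a fraction of the shift (`adj_attenuation`), default 0,
  emulating adjacent tissue that behaves like normal.
* **DE tables** plant DEGs with `|log2FC| > 0.5` and `p < 0.05` and give
  unplanted genes either a null p-value or a sub-threshold fold change, so
  the standard thresholds recover exactly the planted sets; a configurable
  fraction of unplanted genes is marked lowly expressed to exercise the
  "< 0 log2-cpm in more than 150 samples" filter.

The simulation does **not** model CpG density, mappability structure
(optional zero-coverage gaps aside), fragment-size effects, GC bias, or
inter-sample library-quality variation. Passing the planted-recovery tests
therefore demonstrates that the caller implements its rules correctly and
has the expected power under clean overdispersed noise — not that those
rules are optimal for any particular real tissue panel.

## Verification and problem sizes

The test suite verifies each stage against an independent oracle: run
calling against exhaustive window enumeration (1,000 random bin-statistic
sequences), exact rank-sum p-values against full permutation enumeration
(all group sizes ≤ 6), hypergeometric tails against subset enumeration
(universes ≤ 12), and region partitioning against interval arithmetic on
1,000 random genes. End-to-end checks use 500 simulated genes at the
default group sizes for planted-DMR recovery, 2,000 genes for null
calibration (8 vs 8 samples from one distribution; well under 2 % of genes
may show any DMR), and full-pipeline byte-identity across reruns of one
seed. These sizes were chosen so the whole suite completes in a few minutes
on one core while keeping every estimate comfortably away from its
acceptance bound.

## Expression integration

DE tables (gene, log2 fold change, p-value, low-expression count) are
consumed, not computed — the table schema is the contract, and any caller
(edgeR, DESeq2, limma) can stand behind it. Genes with below-zero log2-cpm
in more than 150 samples are excluded (strictly more than: 150 exactly is
kept); a gene is a DEG when `p < 0.05` and `|log2FC| > 0.5`, the sign
giving the direction. The fold-change rule is applied two-sidedly — the
only reading that can produce down-regulated calls. Methylation and
expression gene identifiers are matched by exact case-insensitive string
equality; genes absent from either side are dropped from the
cross-tabulation, which is how "only the overlap genes" is meant.

## Known limitations

* The caller is exactly the threshold/run rule: no smoothing, no HMM
  segmentation, no beta-binomial shrinkage. That is a feature (it is the
  method under study), but it means single-bin signals and sub-threshold
  wide signals are invisible by construction.
* Distal windows of neighbouring real genes overlap freely; a bin may serve
  as Distal evidence for several genes, and no masking is applied.
* rpm normalization is relative; no CpG-density or absolute-methylation
  calibration is attempted.
* The five-group design is fixed in vocabulary (N, ADJ, L, H, VH) though
  any subset of groups may be present in a given sample sheet.
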