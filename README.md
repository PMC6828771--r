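# WoundChrom

Wounding reprograms plant cells: within hours of cutting, thousands of
genes switch on, and which genes respond — and how fast — is written in
their chromatin before the wound ever happens. WoundChrom is an R package
for the integrative analysis behind that statement. It takes
histone-modification ChIP-seq time courses (H3K9/14ac, H3K27ac, H3K4me3,
H3K36me3, H3K27me3, plus a histone H3 control) and matched RNA-seq time
courses around wounding, and quantifies how pre-existing and wound-induced
histone-mark states relate to the level and *timing* of transcriptional
induction. It is aimed at epigenomics groups who have gene-level peak
calls and coverage tables and want the full downstream statistical
pipeline, reproducibly and with testable parts.

## What it computes

* **Marking calls.** Peaks (ENCODE narrowPeak/broadPeak, filtered at
  Q < 0.001) are assigned to the closest gene over a strand-aware
  analysis window — 1 kb promoter plus gene body — with BEDTools-`closest`
  tie semantics; a gene is *marked* only when it has a qualifying peak in
  **both** replicates.
* **Enrichment levels.** Per gene, mark and time: mean mark read depth
  over the window divided by the histone H3 depth in the same region
  (pseudo-depth 0.5 on both), so levels are comparable across loci.
* **Differential marking.** For each mark and time *t* vs 0 h the level
  ratio is taken to MA coordinates, `M = log2(x_t / x_0)`,
  `A = (log2 x_t + log2 x_0) / 2`; a robust line fitted on *anchor* genes
  (marked at both time points) rescales M, and genes with |M′| > 0.15 are
  called gained/lost — the MAnorm idea applied to gene-level summaries.
* **Wound-responsive genes.** A re-implemented TMM normalization and a
  conditional negative-binomial exact test (each time vs 0 h; dispersion
  by pooled method of moments with empirical-Bayes moderation) define
  induced/repressed genes at FC > 1.5 and BH FDR < 0.001 at any time.
* **Induction timing.** K-means (k = 8) on mean-centred log profiles,
  clusters relabelled 1→8 from most rapidly to most slowly induced using a
  half-maximum timing score.
* **Integration statistics.** Representation factors
  `RF = (k/n)/(K/N)` with exact hypergeometric tails for marks, co-marks
  (bivalent H3K27me3+active states), and epigenetic categories within
  timing clusters; rank-LOESS curves of timing over pre-wound mark level;
  PCA of mark-level ranks vs timing; H3K9/14ac-vs-H3K4me3 gain precedence
  counts; Pearson correlation of marking and expression changes; Wilcoxon
  level comparisons.
* **Treatment contrasts.** The same DE and marking machinery applied
  treated-vs-control (e.g. a histone-acetyltransferase inhibitor arm),
  with the triple-overlap report induced × down-regulated × ac-decreased.
* **Synthetic data.** `woundSimConfig()` + `simulateWoundDataset()`
  generate a complete file-backed dataset (genes.bed, narrowPeak files,
  coverage.tsv, counts.tsv) with planted ground truth — six gene classes
  covering pre-acetylated rapid responders, slow gainers where
  acetylation precedes H3K4me3, bivalent PRC2 targets, silent PRC2
  targets, repressed ac-losers and stable genes — so every stage of the
  pipeline can be validated against known truth.

## Worked example

```r
library(WoundChrom)

cfg <- woundSimConfig(nGenes = 500, seed = 42)
dir <- file.path(tempdir(), "demo"); out <- file.path(tempdir(), "demo-out")
simulateWoundDataset(cfg, dir)
res <- runPipeline(pipelineConfig(dir, out, seed = 42))

length(res$responsive$induced)   # 131 wound-induced genes
res$dynamics$prec$counts
#     ac_first    me3_first simultaneous      only_ac     only_me3      neither
#           65            0            3           35            1           27
sapply(res$dynamics$loess, `[[`, "rho")
#  H3K27ac  H3K27me3  H3K36me3   H3K4me3 H3K9K14ac
#    -0.71      0.29      0.12     -0.40     -0.71
```

Reading the output: of the 131 induced genes, 65 gain H3K9/14ac strictly
before H3K4me3 and none the other way around — acetylation precedes
H3K4me3 deposition. The rank-LOESS Spearman correlations say that genes
with high pre-wound acetylation are induced *early* (ρ ≈ −0.71 for
H3K9/14ac and H3K27ac, labels run 1 = earliest), while H3K36me3 carries
almost no timing information (ρ ≈ 0.12). Per-mark enrichment is a
one-liner, e.g. H3K27me3-marked genes among the induced set:

```r
subset(res$enrichment$marks, set == "induced" & category == "H3K27me3")
#    k   n  K   N representation_factor p_over p_under stars pct_of_marked
#   13 131 86 500                  0.58   1.00  0.0058    **          15.1
reportFraction(13, 86)   # "15%" of H3K27me3 targets are wound-induced
```

Every output also lands as a TSV bundle plus a `manifest.json` (config,
per-stage counts, checksums) under the output directory, and re-running
with the same config and seed reproduces the bundle byte for byte.

A command-line front end is installed with the package
(`system.file("scripts", "woundchrom.R", package = "WoundChrom")`) with
`simulate`, `run` and `contrast` subcommands.

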