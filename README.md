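# tsMultiome

Calling tissue-specific genes and tissue-specific open chromatin regions
(TS OCRs) from multi-tissue single-cell RNA-seq plus bulk ATAC-seq, and
integrating the two modalities — the analysis style used to characterize
tissue adaptation of immune cell populations (e.g. group 2 innate lymphoid
cells, ILC2s) profiled across bone marrow, large intestine, small
intestine, lung and pancreas.

## What it computes

**Tissue specificity by exhaustive pairwise intersection.** A feature is
tissue-specific when it is significantly higher in one tissue than in
*every* other tissue under one-vs-one comparison:

```
TS(t) = ∩_{u ≠ t} { f : p_{t,u}(f) < α  and  log2FC_{t,u}(f) > fcMin }
```

For genes the per-comparison test is a tie-corrected Wilcoxon rank-sum on
log-normalized counts (`value = ln(1 + 10^4 · c / total)`), gated on
BH-adjusted q < 0.05 and log2FC > 0.25; for ATAC peaks it is a simplified
negative-binomial Wald test (median-of-ratios size factors, binned
method-of-moments dispersion trend) gated on raw p < 0.05. Peaks enter the
analysis only if reproducible in all biological replicates ("genuine
peaks") and are merged across tissues into a combined atlas.

**ATAC–RNA integration.** For a tissue contrast, each gene's one-vs-all
mRNA log2FC is paired with the mean log2FC of accessibility over all of
its peaks in each region class — promoter (TSS −1000/+100), intragenic
(5'UTR + 3'UTR + exon + intron) or intergenic — restricted to genes with
significant >1.2-fold expression change. Quadrant concordance and Pearson
correlation are reported per class. The LI/SI shared-feature fold is
`((Σ LI-vs-other)/3 + (Σ SI-vs-other)/3) / 2`.

**Single-cell correlation screen.** Cells with zero raw counts of a target
gene (e.g. *Ikzf3*, encoding Aiolos) are dropped; every other gene is
Pearson-correlated with the target across the remaining cells and
sign-partitioned at p < 0.05.

**Synthetic data with planted truth.** `simulateMultiome()` generates the
whole five-tissue dataset — negative-binomial UMI and peak counts, planted
tissue-specific genes and shared intestinal genes, mitochondrial genes,
contaminant cell clusters bearing ILC3/B-cell markers, a latent-factor
correlation block around the target gene, and replicate peak sets whose
planted accessibility effects are coupled to planted genes through
non-promoter peaks — together with a `TruthManifest` for scoring.

## Worked example

```r
library(tsMultiome)
library(SummarizedExperiment)

sim <- simulateMultiome(simParams(seed = 11))
qc  <- runCellQC(sim$cells, rounds = 2, seed = 11)
ts  <- runTSGenes(qc$cells)
gt  <- geneTruth(sim$truth)
for (t in names(ts$sets)) {
  truth <- gt$gene_id[!is.na(gt$tissue) & gt$tissue == t]
  cat(t, scoreFeatureSet(ts$sets[[t]], truth)[c("recall", "precision")], "\n")
}
```

prints (recall, precision of the planted 20 tissue-specific genes per
tissue, after QC, contaminant removal and downsampling):

```
BM 1 1
LI 1 0.952381
SI 1 1
Lung 1 1
Pancreas 1 1
```

i.e. every planted gene is recovered and at most one extra gene slips into
a tissue's set. The ATAC side and the integration follow the same pattern:

```r
ocr  <- runTSOCRs(sim$peaks, sim$peaksets)
rows <- do.call(rbind, lapply(unique(tissues(qc$cells)), function(t)
  runIntegration(qc$cells, ocr, sim$annotation, t)$rows))
concordanceSummary(rows)
```

which shows strong positive accessibility–expression correlation for
intragenic and intergenic peaks (r ≈ 0.93, concordance ≈ 0.89 on the
default simulation) and none at promoters (|r| < 0.1) — the planted
coupling is routed through non-promoter peaks, mirroring the biology the
pipeline is designed to expose.

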