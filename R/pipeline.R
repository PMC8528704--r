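# End-to-end wrappers: pairwise rank-sum DE + tissue-specific gene calling,
# genuine-peak/atlas construction + pairwise NB Wald DA + TS-OCR calling,
# and the per-tissue ATAC-RNA integration.

#' Call tissue-specific genes from a QC'ed cell matrix
#'
#' Runs [wilcoxonDE()] for every unordered tissue pair and intersects the
#' per-comparison up-calls per tissue ([callTissueSpecific()]). Defaults
#' follow the single-cell convention: BH-adjusted q < 0.05 and
#' log2fc > 0.25 per comparison.
#'
#' @param cells a [CellCounts-class] with a `"logcounts"` assay.
#' @param alpha,fcMin,useAdjusted gates per comparison.
#' @param ... passed to [wilcoxonDE()].
#' @return `list(results = pairwise DifferentialResult map, sets = named
#'   list of tissue-specific gene id vectors)`.
#' @export
runTSGenes <- function(cells, alpha = 0.05, fcMin = 0.25,
                       useAdjusted = TRUE, ...) {
  norm <- assay(cells, "logcounts")
  tl <- unique(tissues(cells))
  groupIdx <- split(seq_len(ncol(cells)), factor(tissues(cells), levels = tl))
  results <- pairwiseComparisons(groupIdx, function(a, b)
    wilcoxonDE(norm, a, b, ...))
  sets <- lapply(stats::setNames(tl, tl), function(t)
    callTissueSpecific(results, t, setdiff(tl, t), "up", alpha, fcMin,
                       useAdjusted))
  list(results = results, sets = sets)
}

#' Call tissue-specific OCRs from replicate peak sets and counts
#'
#' Builds per-tissue genuine peaks (reproducible across replicates), merges
#' them into the combined atlas, aggregates the peak counts onto atlas
#' intervals, computes median-of-ratios size factors, runs the NB Wald test
#' for every tissue pair, and intersects per-tissue up-calls. Defaults
#' mirror the peak convention: raw p < 0.05, no fold gate.
#'
#' @param peaks a [PeakExperiment-class] of raw peak counts.
#' @param peaksets named list (tissue -> list of replicate `GRanges`).
#' @param alpha,fcMin,useAdjusted gates per comparison.
#' @param minOverlap merge overlap (bases).
#' @return list: `atlas` (GRanges, with per-tissue presence flags),
#'   `counts` (atlas x sample matrix), `sf`, `results` (pairwise map),
#'   `sets` (named list of TS-OCR atlas ids per tissue).
#' @export
runTSOCRs <- function(peaks, peaksets, alpha = 0.05, fcMin = 0,
                      useAdjusted = FALSE, minOverlap = 1) {
  genuine <- lapply(peaksets, genuinePeaks, minOverlap = minOverlap)
  atlas <- combinedAtlas(genuine, minOverlap = minOverlap)
  counts <- assay(peaks, "counts")
  hits <- GenomicRanges::findOverlaps(atlas, rowRanges(peaks),
                                      ignore.strand = TRUE)
  agg <- rowsum(counts[S4Vectors::subjectHits(hits), , drop = FALSE],
                group = S4Vectors::queryHits(hits))
  atlasCounts <- matrix(0, length(atlas), ncol(counts),
                        dimnames = list(names(atlas), colnames(counts)))
  atlasCounts[as.integer(rownames(agg)), ] <- agg
  sf <- sizeFactorsMedianRatio(atlasCounts)
  tl <- unique(tissues(peaks))
  groupIdx <- split(seq_len(ncol(counts)),
                    factor(tissues(peaks), levels = tl))
  results <- pairwiseComparisons(groupIdx, function(a, b)
    nbWaldDA(atlasCounts, a, b, sf = sf))
  sets <- lapply(stats::setNames(tl, tl), function(t)
    callTissueSpecific(results, t, setdiff(tl, t), "up", alpha, fcMin,
                       useAdjusted))
  list(atlas = atlas, counts = atlasCounts, sf = sf, results = results,
       sets = sets)
}

#' Per-peak one-vs-all accessibility log2 fold change
#'
#' The DA test is pairwise, so the one-vs-all accessibility fold matching a
#' one-vs-all expression contrast is the mean of the tissue's pairwise
#' log2 fold changes against each other tissue.
#'
#' @param results pairwise DA result map (from [runTSOCRs()]).
#' @param tissue target tissue.
#' @param otherTissues remaining tissue labels.
#' @return named per-peak numeric vector.
#' @export
oneVsAllAccessibility <- function(results, tissue, otherTissues) {
  folds <- vapply(otherTissues, function(o) {
    r <- .pairResult(results, tissue, o)
    stats::setNames(r$log2fc, r$feature_id)
  }, numeric(nrow(results[[1]])))
  rowMeans(folds)
}

#' ATAC-RNA integration for one tissue contrast
#'
#' One-vs-all expression folds (rank-sum), one-vs-all accessibility folds
#' (pairwise mean), nearest-gene assignment and region classification of
#' atlas peaks, the `> fcThreshold`-fold significant-gene gate, and the
#' per-region-class concordance/correlation summary.
#'
#' @param cells a [CellCounts-class] with `"logcounts"`.
#' @param ocr output of [runTSOCRs()].
#' @param ann a [GeneAnnotation-class].
#' @param tissue target tissue.
#' @param fcThreshold,alpha gene-gate parameters (defaults 1.2, 0.05).
#' @param ... passed to [oneVsAllLog2FC()].
#' @return list: `rows` (integration table), `summary`
#'   ([concordanceSummary()]), `expr` (the one-vs-all DifferentialResult).
#' @export
runIntegration <- function(cells, ocr, ann, tissue, fcThreshold = 1.2,
                           alpha = 0.05, ...) {
  norm <- assay(cells, "logcounts")
  labels <- tissues(cells)
  expr <- oneVsAllLog2FC(norm, labels, tissue, ...)
  others <- setdiff(unique(labels), tissue)
  accLfc <- oneVsAllAccessibility(ocr$results, tissue, others)
  assign <- nearestGenes(ocr$atlas, ann)
  classes <- classifyRegions(ocr$atlas, ann)
  accTable <- avgAccessibilityLog2FC(accLfc, assign$gene_id, classes)
  rows <- buildIntegrationTable(expr, accTable, fcThreshold, alpha)
  list(rows = rows, summary = concordanceSummary(rows), expr = expr)
}

#' Normalized peak coverage (log2 of size-factor-scaled counts)
#'
#' @param counts peaks x samples matrix.
#' @param sf size factors.
#' @return log2(1 + count/sf) matrix.
#' @export
normalizePeakCounts <- function(counts, sf = sizeFactorsMedianRatio(counts)) {
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Recall and precision of a called feature set against planted truth
#'
#' @param called character vector of called feature ids.
#' @param truth character vector of planted truth ids.
#' @return named numeric: `recall`, `precision`, `n_called`, `n_truth`.
#' @export
scoreFeatureSet <- function(called, truth) {
  called <- unique(as.character(called)); truth <- unique(as.character(truth))
  tp <- length(intersect(called, truth))
  c(recall = if (length(truth)) tp / length(truth) else NA_real_,
    precision = if (length(called)) tp / length(called) else NA_real_,
    n_called = length(called), n_truth = length(truth))
}

#' Score called atlas peaks against planted truth peaks by overlap
#'
#' Called atlas ids are resolved to intervals and compared with the truth
#' peak intervals by >= 1 bp overlap.
#'
#' @param atlas atlas `GRanges` (named).
#' @param calledIds called atlas peak ids.
#' @param truthPeaks `GRanges` of planted truth peaks.
#' @return named numeric: `recall`, `precision`, `n_called`, `n_truth`.
#' @export
scorePeakSet <- function(atlas, calledIds, truthPeaks) {
  called <- atlas[names(atlas) %in% calledIds]
  tp_r <- sum(IRanges::overlapsAny(truthPeaks, called, ignore.strand = TRUE))
  tp_p <- sum(IRanges::overlapsAny(called, truthPeaks, ignore.strand = TRUE))
  c(recall = if (length(truthPeaks)) tp_r / length(truthPeaks) else NA_real_,
    precision = if (length(called)) tp_p / length(called) else NA_real_,
    n_called = length(called), n_truth = length(truthPeaks))
}
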