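#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowRanges rowRanges<-
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand width
#' @importFrom BiocGenerics start<- end<-
#' @importFrom IRanges IRanges
NULL

#' CellCounts: a SingleCellExperiment of raw UMI counts with tissue labels
#'
#' Thin subclass of [SingleCellExperiment::SingleCellExperiment] used as the
#' container for cell x gene UMI counts. Validity requires a `"counts"` assay
#' of non-negative integers (genes in rows, cells in columns, the Bioconductor
#' orientation), a `tissue` column in `colData`, and the set of gene names
#' counted as mitochondrial in `metadata(x)$mitoGenes`.
#'
#' @aliases CellCounts-class
#' @exportClass CellCounts
setClass("CellCounts", contains = "SingleCellExperiment")

setValidity("CellCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    v <- if (methods::is(m, "sparseMatrix")) m@x else m
    if (length(v) && (any(v < 0) || any(v != round(v))))
      msg <- c(msg, "'counts' must be non-negative integers")
  }
  if (!"tissue" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'tissue' column")
  else if (anyNA(colData(object)$tissue))
    msg <- c(msg, "every cell needs a tissue label")
  if (is.null(rownames(object)))
    msg <- c(msg, "gene names (rownames) are required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CellCounts object
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or sparse), with gene rownames and cell colnames.
#' @param tissue character vector of per-cell tissue labels.
#' @param cluster optional per-cell cluster labels.
#' @param mitoGenes character vector of gene names counted as mitochondrial
#'   (default: rownames starting with `"mt-"`).
#' @return A [CellCounts-class] object.
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' cc <- CellCounts(m, tissue = rep(c("LI", "SI"), c(2, 3)))
#' tissues(cc)
#' @export
CellCounts <- function(counts, tissue, cluster = NULL, mitoGenes = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (length(tissue) == 1L) tissue <- rep(tissue, ncol(counts))
  cd <- DataFrame(tissue = as.character(tissue), row.names = colnames(counts))
  if (!is.null(cluster)) cd$cluster <- as.character(cluster)
  if (is.null(mitoGenes)) mitoGenes <- grep("^mt-", rownames(counts), value = TRUE)
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
  metadata(sce)$mitoGenes <- mitoGenes
  methods::new("CellCounts", sce)
}

#' @describeIn CellCounts Tissue label of every cell.
#' @param x a `CellCounts` or `PeakExperiment` object
#' @export
tissues <- function(x) colData(x)$tissue

#' @describeIn CellCounts Gene names counted as mitochondrial.
#' @export
mitoGenes <- function(x) metadata(x)$mitoGenes

#' PeakExperiment: peak x sample ATAC counts over genomic intervals
#'
#' Thin subclass of RangedSummarizedExperiment holding raw ATAC fragment
#' counts per peak and sample. Validity requires a non-negative integer
#' `"counts"` assay and `tissue` + `replicate` columns in `colData`; the
#' peaks themselves live in `rowRanges` with unique names (peak ids).
#'
#' @aliases PeakExperiment-class
#' @exportClass PeakExperiment
setClass("PeakExperiment", contains = "RangedSummarizedExperiment")

setValidity("PeakExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "'counts' must be non-negative integers")
  }
  need <- setdiff(c("tissue", "replicate"), colnames(colData(object)))
  if (length(need))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  nm <- names(rowRanges(object))
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "peaks need unique names (ids)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PeakExperiment
#'
#' @param counts peaks x samples integer matrix.
#' @param peaks a `GRanges` of peak intervals, names = peak ids (same order
#'   and length as `nrow(counts)`).
#' @param tissue,replicate per-sample labels (length `ncol(counts)`).
#' @return A [PeakExperiment-class] object.
#' @export
PeakExperiment <- function(counts, peaks, tissue, replicate) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(tissue, replicate, sep = "_")
  names(peaks) <- if (is.null(names(peaks)))
    sprintf("peak%05d", seq_along(peaks)) else names(peaks)
  rownames(counts) <- names(peaks)
  se <- SummarizedExperiment(
    assays = list(counts = counts), rowRanges = peaks,
    colData = DataFrame(tissue = as.character(tissue),
                        replicate = as.character(replicate),
                        row.names = colnames(counts)))
  methods::new("PeakExperiment", se)
}

#' GeneAnnotation: gene models for peak classification and assignment
#'
#' Holds gene spans (with strand and TSS), exon and UTR structure, and
#' chromosome lengths. All ranges are `GRanges` (1-based, closed); BED input
#' is converted on read.
#'
#' @slot genes `GRanges`, one per gene, names = gene ids; `mcols(genes)$tss`
#'   is the 1-based TSS position (start on `+`, end on `-`).
#' @slot exons,utr5,utr3 `GRangesList` keyed by gene id.
#' @slot chromSizes named integer vector of chromosome lengths.
#' @aliases GeneAnnotation-class
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
  slots = c(genes = "GRanges", exons = "GRangesList",
            utr5 = "GRangesList", utr3 = "GRangesList",
            chromSizes = "integer"))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  msg <- NULL
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "gene ids (names of @genes) must be unique")
  if (!"tss" %in% colnames(S4Vectors::mcols(g)))
    msg <- c(msg, "mcols(genes)$tss is required")
  else {
    plus <- as.character(strand(g)) == "+"
    tss <- S4Vectors::mcols(g)$tss
    if (any(tss[plus] != start(g)[plus]) || any(tss[!plus] != end(g)[!plus]))
      msg <- c(msg, "tss must equal start on '+' and end on '-' strand")
  }
  cs <- object@chromSizes
  if (length(g)) {
    if (!all(as.character(seqnames(g)) %in% names(cs)))
      msg <- c(msg, "every gene chromosome needs a chromSizes entry")
    else if (any(end(g) > cs[as.character(seqnames(g))]))
      msg <- c(msg, "gene spans exceed chromosome lengths")
  }
  if (length(object@exons) && !all(names(object@exons) %in% names(g)))
    msg <- c(msg, "exon list names must be gene ids")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneAnnotation
#'
#' @param genes `GRanges` with names (gene ids), strand, and `mcols$tss`.
#' @param exons,utr5,utr3 `GRangesList` keyed by gene id (may be empty).
#' @param chromSizes named integer vector.
#' @return A [GeneAnnotation-class] object.
#' @export
GeneAnnotation <- function(genes, exons = GRangesList(), utr5 = GRangesList(),
                           utr3 = GRangesList(), chromSizes) {
  methods::new("GeneAnnotation", genes = genes, exons = exons,
               utr5 = utr5, utr3 = utr3,
               chromSizes = stats::setNames(as.integer(chromSizes),
                                            names(chromSizes)))
}

#' @describeIn GeneAnnotation Gene spans as `GRanges`.
#' @param x,object a `GeneAnnotation`
#' @export
genes <- function(x) x@genes

#' @describeIn GeneAnnotation Named chromosome lengths.
#' @export
chromSizes <- function(x) x@chromSizes

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "genes on",
      length(object@chromSizes), "chromosome(s)\n")
})

#' DifferentialResult: per-feature statistics for one A-vs-B comparison
#'
#' A `DataFrame` subclass with columns `feature_id`, `log2fc` (group A over
#' group B), `stat`, `p`, `q` (BH over tested features), `tested`, and for
#' RNA comparisons `pct_a`/`pct_b` (fraction of cells expressing). Features
#' failing pre-filters carry the `p = 1` sentinel with `tested = FALSE`.
#' `metadata()` records the groups and test used.
#'
#' @aliases DifferentialResult-class
#' @exportClass DifferentialResult
setClass("DifferentialResult", contains = "DFrame")

setValidity("DifferentialResult", function(object) {
  need <- setdiff(c("feature_id", "log2fc", "stat", "p", "q"), colnames(object))
  if (length(need))
    return(paste("missing columns:", paste(need, collapse = ", ")))
  p <- object$p
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p outside [0,1]")
  TRUE
})

DifferentialResult <- function(df, groupA, groupB, test) {
  out <- methods::new("DifferentialResult", DataFrame(df))
  metadata(out) <- list(groupA = groupA, groupB = groupB, test = test)
  out
}

setMethod("show", "DifferentialResult", function(object) {
  md <- metadata(object)
  cat(sprintf("DifferentialResult (%s): %s vs %s, %d features (%d tested)\n",
              md$test, md$groupA, md$groupB, nrow(object),
              sum(object$tested)))
  methods::callNextMethod()
})

#' TruthManifest: planted ground truth emitted by the synthetic generator
#'
#' Records everything needed to score downstream callers: per-gene tissue
#' effects and roles, per-peak gene assignment / region class / coupling,
#' and per-cell tissue and contaminant type.
#'
#' @slot geneTruth `data.frame`: gene_id, tissue (planted tissue or NA),
#'   fold, shared_intestinal, mito, corr_sign ("+", "-", "target" or "none").
#' @slot peakTruth `data.frame`: peak_id, gene_id, region_class, tissue,
#'   fold, coupled.
#' @slot cellTruth `data.frame`: cell_id, tissue, contaminant ("none" or type).
#' @aliases TruthManifest-class
#' @exportClass TruthManifest
setClass("TruthManifest",
  slots = c(geneTruth = "data.frame", peakTruth = "data.frame",
            cellTruth = "data.frame"))

setValidity("TruthManifest", function(object) {
  msg <- NULL
  pt <- object@peakTruth
  gt <- object@geneTruth
  if (nrow(pt) && !all(pt$gene_id %in% gt$gene_id))
    msg <- c(msg, "peak truth references unknown genes")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn TruthManifest Per-gene planted effects.
#' @param x,object a `TruthManifest`
#' @export
geneTruth <- function(x) x@geneTruth

#' @describeIn TruthManifest Per-peak planted effects.
#' @export
peakTruth <- function(x) x@peakTruth

#' @describeIn TruthManifest Per-cell tissue and contaminant status.
#' @export
cellTruth <- function(x) x@cellTruth

setMethod("show", "TruthManifest", function(object) {
  cat(sprintf(
    "TruthManifest: %d genes (%d planted), %d peaks (%d coupled), %d cells\n",
    nrow(object@geneTruth), sum(!is.na(object@geneTruth$tissue)),
    nrow(object@peakTruth), sum(object@peakTruth$coupled),
    nrow(object@cellTruth)))
})
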