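qcReport <- function(nInput, lowUmi = 0, highMito = 0, contaminant = 0,
                     genesRemoved = 0, cellStatus = NULL) {
  structure(list(n_input_cells = nInput, n_removed_low_umi = lowUmi,
                 n_removed_high_mito = highMito,
                 n_removed_contaminant = contaminant,
                 n_genes_removed = genesRemoved, cellStatus = cellStatus),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0("QCReport: %d cells in; removed %d low-UMI, %d ",
                     "high-mito, %d contaminant; %d genes removed\n"),
              x$n_input_cells, x$n_removed_low_umi, x$n_removed_high_mito,
              x$n_removed_contaminant, x$n_genes_removed))
  invisible(x)
}

#' Filter cells on total UMIs and mitochondrial fraction
#'
#' Keeps cells with total UMIs >= `10^umiMinLog10` and mitochondrial UMI
#' fraction <= `mitoMaxFrac` (both thresholds inclusive on the keep side:
#' the exclusion rules are strictly "fewer than" and "over").
#'
#' @param cells a [CellCounts-class].
#' @param umiMinLog10 log10 of the minimum total UMIs (default 2.5).
#' @param mitoMaxFrac maximum mitochondrial UMI fraction (default 0.10).
#' @return `list(cells = filtered CellCounts, report = QCReport)`; removing
#'   every cell warns rather than errors.
#' @export
filterCells <- function(cells, umiMinLog10 = 2.5, mitoMaxFrac = 0.10) {
  m <- assay(cells, "counts")
  total <- colSums(m)
  mt <- intersect(mitoGenes(cells), rownames(m))
  mitoFrac <- if (length(mt)) colSums(m[mt, , drop = FALSE]) / pmax(total, 1)
              else rep(0, ncol(m))
  lowUmi <- total < 10^umiMinLog10
  highMito <- mitoFrac > mitoMaxFrac
  keep <- !lowUmi & !highMito
  if (!any(keep)) warning("all cells removed by QC filters")
  status <- data.frame(cell_id = colnames(m), pass = keep,
                       reason = ifelse(lowUmi, "low_umi",
                                       ifelse(highMito, "high_mito", "")))
  list(cells = cells[, keep],
       report = qcReport(ncol(m), lowUmi = sum(lowUmi),
                         highMito = sum(!lowUmi & highMito),
                         cellStatus = status))
}

#' Filter genes on minimum detection
#'
#' Default reading ("per_cell"): keep genes with a count of at least
#' `minTotal` in each of at least `minCells` cells. The alternative
#' "total" reading (total counts >= `minTotal` and detected in >=
#' `minCells` cells) is available via `mode`.
#'
#' @param cells a [CellCounts-class].
#' @param minTotal count threshold (default 5).
#' @param minCells cell threshold (default 2).
#' @param mode `"per_cell"` (default) or `"total"`.
#' @return The filtered [CellCounts-class].
#' @export
filterGenes <- function(cells, minTotal = 5, minCells = 2,
                        mode = c("per_cell", "total")) {
  mode <- match.arg(mode)
  m <- assay(cells, "counts")
  keep <- if (mode == "per_cell")
    rowSums(m >= minTotal) >= minCells
  else
    rowSums(m) >= minTotal & rowSums(m > 0) >= minCells
  cells[keep, ]
}

.logNorm <- function(m, scale) {
  total <- colSums(m)
  zero <- which(total == 0)
  if (length(zero))
    stop("zero-total cell(s): ",
         paste(colnames(m)[utils::head(zero, 5)], collapse = ", "))
  log1p(sweep(m, 2, scale / total, `*`))
}

#' LogNormalize: per-cell scaling and log1p transform
#'
#' `value = ln(1 + scale * count / cell_total)`; zero counts map to zero.
#'
#' @param cells a [CellCounts-class] (result gains a `"logcounts"` assay) or
#'   a plain genes x cells count matrix (result is the normalized matrix).
#' @param scale library-size target (default `1e4`).
#' @return Same type as the input.
#' @export
logNormalize <- function(cells, scale = 1e4) {
  if (methods::is(cells, "CellCounts")) {
    SummarizedExperiment::assay(cells, "logcounts") <-
      .logNorm(as.matrix(assay(cells, "counts")), scale)
    cells
  } else .logNorm(cells, scale)
}

#' Seeded PCA + k-means helper clustering
#'
#' Plumbing for [flagContaminants()]: principal components of the
#' log-normalized matrix followed by k-means. Any clustering can be used
#' instead.
#'
#' Follows the usual single-cell recipe: optionally restrict to the `nHvg`
#' most variable genes, scale each gene to unit variance, take principal
#' components, k-means.
#'
#' @param cells a [CellCounts-class] with a `"logcounts"` assay.
#' @param k number of clusters (default 12).
#' @param nPcs number of principal components (default 20).
#' @param nHvg number of highly variable genes used (default `Inf` = all
#'   non-constant genes).
#' @param seed RNG seed for k-means restarts.
#' @return character vector of per-cell cluster labels.
#' @export
clusterCells <- function(cells, k = 12, nPcs = 20, nHvg = Inf, seed = 1) {
  norm <- assay(cells, "logcounts")
  v <- matrixStats::rowVars(norm)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(nHvg, sum(v > 0)))]
  x <- t(norm[hvg, , drop = FALSE])
  x <- scale(x)
  nPcs <- min(nPcs, ncol(x) - 1L, nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nPcs)
  withSeed(seed, {
    km <- stats::kmeans(pc$x, centers = min(k, nrow(x)), nstart = 10,
                        iter.max = 100)
    as.character(km$cluster)
  })
}

#' Flag and remove contaminant clusters by marker panels
#'
#' A cluster is flagged for a marker panel when its mean panel score (mean
#' log-normalized expression over the panel genes) exceeds the
#' `scoreQuantile` quantile of per-cluster scores AND exceeds the global
#' mean cell score by `margin`. Flagged cells are removed. Apply twice for
#' an iterative two-round filter.
#'
#' @param cells a [CellCounts-class] with `"logcounts"`.
#' @param clusters per-cell cluster labels (e.g. from [clusterCells()]).
#' @param markerPanels named list of marker gene sets; unknown gene names
#'   warn and are ignored.
#' @param scoreQuantile quantile over per-cluster scores (default 0.9).
#' @param margin required excess over the global mean score (default 1,
#'   log-normalized units).
#' @return `list(cells, flagged = named list panel -> cluster labels,
#'   report = QCReport)`.
#' @export
flagContaminants <- function(cells, clusters, markerPanels,
                             scoreQuantile = 0.9, margin = 1) {
  stopifnot(length(clusters) == ncol(cells))
  norm <- assay(cells, "logcounts")
  flagged <- list()
  bad <- rep(FALSE, ncol(cells))
  for (panel in names(markerPanels)) {
    genesIn <- intersect(markerPanels[[panel]], rownames(norm))
    missing <- setdiff(markerPanels[[panel]], rownames(norm))
    if (length(missing))
      warning("panel ", panel, ": unknown marker gene(s) ",
              paste(missing, collapse = ", "))
    if (!length(genesIn)) next
    score <- colMeans(norm[genesIn, , drop = FALSE])
    clScore <- tapply(score, clusters, mean)
    hit <- names(clScore)[clScore > stats::quantile(clScore, scoreQuantile) &
                          clScore > mean(score) + margin]
    flagged[[panel]] <- hit
    bad <- bad | clusters %in% hit
  }
  list(cells = cells[, !bad], flagged = flagged,
       report = qcReport(ncol(cells), contaminant = sum(bad),
                         cellStatus = data.frame(
                           cell_id = colnames(cells), pass = !bad,
                           reason = ifelse(bad, "contaminant", ""))))
}

#' Downsample every tissue to the smallest tissue size
#'
#' Subsamples cells without replacement so every tissue matches the
#' smallest tissue's cell count; rows (cells) are carried over unchanged.
#'
#' @param cells a [CellCounts-class].
#' @param seed RNG seed (deterministic selection).
#' @return The downsampled [CellCounts-class].
#' @export
downsamplePerTissue <- function(cells, seed = 1) {
  tl <- tissues(cells)
  target <- min(table(tl))
  keep <- withSeed(seed, {
    unlist(lapply(split(seq_along(tl), tl),
                  function(ix) sort(sample(ix, target))), use.names = FALSE)
  })
  cells[, sort(keep)]
}

#' End-to-end single-cell QC pipeline
#'
#' Cell filters, gene filter, log-normalization, iterative marker-panel
#' contaminant removal (re-clustering each round), and per-tissue
#' downsampling.
#'
#' @inheritParams filterCells
#' @inheritParams filterGenes
#' @inheritParams flagContaminants
#' @param rounds contaminant-removal rounds (default 2).
#' @param k,nPcs,seed clustering and downsampling controls.
#' @param downsample downsample tissues to the minimum size (default TRUE).
#' @return `list(cells, reports = list of QCReport)`.
#' @export
runCellQC <- function(cells, umiMinLog10 = 2.5, mitoMaxFrac = 0.10,
                      minTotal = 5, minCells = 2,
                      markerPanels = list(
                        ILC3 = c("Il22", "Rorc", "Ccr6", "Klrb1c"),
                        Bcell = c("Jchain", "Mzb1", "Ebf1", "Cd79a")),
                      rounds = 2, scoreQuantile = 0.9, margin = 1,
                      k = 10, nPcs = 20, seed = 1, downsample = TRUE) {
  fc <- filterCells(cells, umiMinLog10, mitoMaxFrac)
  reports <- list(cellFilter = fc$report)
  out <- filterGenes(fc$cells, minTotal, minCells)
  reports$cellFilter$n_genes_removed <- nrow(fc$cells) - nrow(out)
  # gene filtering can zero out a borderline cell's library; drop such cells
  nz <- colSums(assay(out, "counts")) > 0
  if (!all(nz)) {
    reports$cellFilter$n_removed_zero_after_genefilter <- sum(!nz)
    out <- out[, nz]
  }
  out <- logNormalize(out)
  for (r in seq_len(rounds)) {
    cl <- clusterCells(out, k = k, nPcs = nPcs, seed = seed + r)
    fl <- flagContaminants(out, cl, markerPanels, scoreQuantile, margin)
    reports[[paste0("contaminantRound", r)]] <- fl$report
    if (ncol(fl$cells) == ncol(out)) { out <- fl$cells; break }
    out <- fl$cells
  }
  if (downsample) out <- downsamplePerTissue(out, seed = seed)
  list(cells = out, reports = reports)
}
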