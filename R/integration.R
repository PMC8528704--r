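# ATAC-RNA integration: one-vs-all expression folds, region-class-averaged
# accessibility folds, the shared-intestinal averaging, the >1.2-fold gene
# gate, and quadrant concordance / Pearson correlation per region class.

#' One-vs-all log2 fold change of expression
#'
#' Rank-sum comparison of one tissue's cells against all other cells
#' pooled; identical fold convention to [wilcoxonDE()] (of which this is
#' the pooled special case).
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels per-cell tissue labels.
#' @param tissue target tissue.
#' @param ... passed to [wilcoxonDE()].
#' @return A [DifferentialResult-class].
#' @export
oneVsAllLog2FC <- function(norm, labels, tissue, ...) {
  ia <- which(labels == tissue)
  if (!length(ia)) stop("unknown tissue: ", tissue)
  if (!length(setdiff(labels, tissue))) stop("need >= 2 tissues")
  wilcoxonDE(norm, ia, which(labels != tissue), ...)
}

#' Region-class-averaged accessibility log2 fold change
#'
#' For each (gene, region class): the arithmetic mean of the per-peak
#' log2 fold changes over *all* of the gene's peaks of that class,
#' regardless of differential significance; absent (NA) when the gene has
#' no peak in the class.
#'
#' @param peakLfc named numeric vector of per-peak log2 fold changes.
#' @param peakGenes gene id per peak (same order).
#' @param peakClasses region class per peak (promoter / intragenic /
#'   intergenic).
#' @return `data.frame` with one row per gene: `gene_id`,
#'   `acc_log2fc_<class>` and `n_peaks_<class>` for the three classes.
#' @export
avgAccessibilityLog2FC <- function(peakLfc, peakGenes, peakClasses) {
  stopifnot(length(peakLfc) == length(peakGenes),
            length(peakLfc) == length(peakClasses))
  classes <- c("promoter", "intragenic", "intergenic")
  geneIds <- sort(unique(as.character(peakGenes)))
  out <- data.frame(gene_id = geneIds)
  for (cls in classes) {
    sel <- peakClasses == cls
    mn <- tapply(peakLfc[sel], peakGenes[sel], mean)
    nn <- tapply(peakLfc[sel], peakGenes[sel], length)
    out[[paste0("acc_log2fc_", cls)]] <- unname(mn[geneIds])
    np <- unname(nn[geneIds]); np[is.na(np)] <- 0L
    out[[paste0("n_peaks_", cls)]] <- as.integer(np)
  }
  out
}

#' Shared-intestinal averaged log2 fold change
#'
#' The LI/SI common-feature fold: per feature, sum the three LI-vs-other
#' folds and divide by 3, likewise for SI, then average the two values —
#' `((sum(LI pairs)/3) + (sum(SI pairs)/3)) / 2`. Applied identically to
#' expression and accessibility folds. (Algebraically this equals the plain
#' mean of the six inputs.)
#'
#' @param liFolds,siFolds each a list/data.frame of three per-feature
#'   numeric vectors (vs BM, Lung, Pancreas), identically ordered.
#' @return per-feature numeric vector.
#' @export
sharedIntestinalLog2FC <- function(liFolds, siFolds) {
  stopifnot(length(liFolds) == 3, length(siFolds) == 3)
  li <- Reduce(`+`, liFolds) / 3
  si <- Reduce(`+`, siFolds) / 3
  (li + si) / 2
}

#' Build the expression/accessibility integration table
#'
#' Restricts to genes with significantly differential mRNA expression for
#' more than `fcThreshold`-fold (linear scale: `|log2fc| > log2(fcThreshold)`,
#' gate `q < alpha`) in the one-vs-all contrast, and attaches the
#' region-class-averaged accessibility folds.
#'
#' @param exprFolds a [DifferentialResult-class] from [oneVsAllLog2FC()]
#'   (or any object with `feature_id`, `log2fc`, `q`).
#' @param accTable output of [avgAccessibilityLog2FC()] for the matching
#'   contrast.
#' @param fcThreshold linear fold gate (default 1.2).
#' @param alpha significance gate on `q` (default 0.05).
#' @return `data.frame`, one row per retained gene: `gene_id`,
#'   `mrna_log2fc`, `q`, the three `acc_log2fc_*` columns (NA = no peak in
#'   that class) and `n_peaks_*` counts.
#' @export
buildIntegrationTable <- function(exprFolds, accTable, fcThreshold = 1.2,
                                  alpha = 0.05) {
  keep <- exprFolds$q < alpha & abs(exprFolds$log2fc) > log2(fcThreshold)
  rows <- data.frame(gene_id = exprFolds$feature_id[keep],
                     mrna_log2fc = exprFolds$log2fc[keep],
                     q = exprFolds$q[keep])
  merge(rows, accTable, by = "gene_id", all.x = TRUE, sort = TRUE)
}

#' Quadrant concordance and Pearson correlation per region class
#'
#' Per region class, over genes with at least one peak in the class:
#' counts in the signed quadrants (upper-right: both folds > 0;
#' lower-left: both < 0; zeros are non-concordant),
#' `concordant_fraction = (UR + LL) / n`, and the Pearson correlation (with
#' two-sided p) between the mRNA and averaged accessibility log2 folds.
#'
#' @param rows output of [buildIntegrationTable()].
#' @param minRows minimum genes per class (default 3; classes below it are
#'   reported with NA statistics).
#' @return `data.frame`, one row per region class: `region_class`,
#'   `n_genes`, `n_upper_right`, `n_lower_left`, `concordant_fraction`,
#'   `pearson_r`, `pearson_p`.
#' @export
concordanceSummary <- function(rows, minRows = 3) {
  classes <- c("promoter", "intragenic", "intergenic")
  out <- lapply(classes, function(cls) {
    acc <- rows[[paste0("acc_log2fc_", cls)]]
    ok <- !is.na(acc)
    x <- rows$mrna_log2fc[ok]; y <- acc[ok]
    n <- sum(ok)
    ur <- sum(x > 0 & y > 0); ll <- sum(x < 0 & y < 0)
    if (n >= minRows && stats::sd(x) > 0 && stats::sd(y) > 0) {
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate); pv <- ct$p.value
    } else { r <- NA_real_; pv <- NA_real_ }
    data.frame(region_class = cls, n_genes = n, n_upper_right = ur,
               n_lower_left = ll,
               concordant_fraction = if (n) (ur + ll) / n else NA_real_,
               pearson_r = r, pearson_p = pv)
  })
  do.call(rbind, out)
}
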