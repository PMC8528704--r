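# Single-cell target-gene correlation screen, the z-score transform, and
# descriptive reporting: Spearman sample correlation by region class,
# ordination, hierarchical tissue proximity.

#' Single-cell correlation screen against a target gene
#'
#' Removes cells with no detected target expression (raw count 0) and any
#' excluded clusters, then computes the Pearson correlation of the target's
#' normalized expression with every other gene across the remaining cells
#' (two-sided p via the t distribution with n-2 df). Significant genes are
#' partitioned by sign; no multiple-testing correction by default (the
#' screen gates on raw p), BH optionally.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param counts matching raw count matrix (defines "detected").
#' @param target target gene name.
#' @param alpha significance threshold (default 0.05).
#' @param clusters optional per-cell cluster labels.
#' @param excludeClusters cluster labels to drop (explicit user input;
#'   never inferred).
#' @param useAdjusted gate on BH-adjusted p instead.
#' @return list of class `CorrelationScreenResult`: `target`, `table`
#'   (gene, r, p, n_cells_used, degenerate flag), `positive`, `negative`,
#'   `n_cells_used`.
#' @export
targetCorrelationScreen <- function(norm, counts, target, alpha = 0.05,
                                    clusters = NULL, excludeClusters = NULL,
                                    useAdjusted = FALSE) {
  if (!target %in% rownames(norm)) stop("target gene not present: ", target)
  keep <- counts[target, ] > 0
  if (!is.null(excludeClusters)) {
    stopifnot(!is.null(clusters))
    keep <- keep & !(clusters %in% excludeClusters)
  }
  n <- sum(keep)
  if (n < 10) stop("fewer than 10 usable cells with detected ", target)
  X <- norm[, keep, drop = FALSE]
  y <- X[target, ]
  others <- setdiff(rownames(X), target)
  sds <- matrixStats::rowSds(X[others, , drop = FALSE])
  degenerate <- sds == 0 | stats::sd(y) == 0
  r <- rep(NA_real_, length(others))
  if (any(!degenerate))
    r[!degenerate] <- as.vector(stats::cor(t(X[others[!degenerate], ,
                                               drop = FALSE]), y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[degenerate] <- NA_real_
  gate <- if (useAdjusted) bhAdjust(ifelse(is.na(p), 1, p)) else p
  sig <- !degenerate & !is.na(p) & gate < alpha
  tab <- data.frame(gene = others, r = r, p = p, n_cells_used = n,
                    degenerate = degenerate)
  structure(list(target = target, table = tab,
                 positive = others[sig & r > 0],
                 negative = others[sig & r < 0],
                 n_cells_used = n),
            class = "CorrelationScreenResult")
}

#' @export
print.CorrelationScreenResult <- function(x, ...) {
  cat(sprintf("Correlation screen on %s: %d cells, %d positive / %d negative (p-gated)\n",
              x$target, x$n_cells_used, length(x$positive),
              length(x$negative)))
  invisible(x)
}

#' Row-wise standard score (Z = (x - mu) / sigma)
#'
#' Population standard deviation by default (`ddof = 0`); constant rows are
#' excluded and reported in the `constant` attribute.
#'
#' @param m feature x group numeric matrix with >= 2 columns.
#' @param ddof delta degrees of freedom for sigma (0 = population).
#' @return z-scored matrix (constant rows dropped), with attribute
#'   `constant` naming the excluded rows.
#' @export
zscoreRows <- function(m, ddof = 0) {
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  n <- ncol(m)
  sig <- sqrt(rowSums((m - mu)^2) / (n - ddof))
  const <- sig == 0
  z <- (m[!const, , drop = FALSE] - mu[!const]) / sig[!const]
  attr(z, "constant") <- rownames(m)[const]
  z
}

#' Spearman sample-sample correlation over a region-class peak subset
#'
#' @param normPeaks peaks x samples normalized accessibility matrix.
#' @param classes region class per peak (from [classifyRegions()]).
#' @param subset `"all"`, `"promoter"` or `"nonpromoter"`.
#' @return symmetric sample x sample Spearman rho matrix, unit diagonal.
#' @export
sampleSpearmanByRegion <- function(normPeaks, classes,
                                   subset = c("all", "promoter",
                                              "nonpromoter")) {
  subset <- match.arg(subset)
  sel <- switch(subset, all = rep(TRUE, nrow(normPeaks)),
                promoter = classes == "promoter",
                nonpromoter = classes != "promoter")
  if (sum(sel) < 3) stop("fewer than 3 peaks in subset")
  stats::cor(normPeaks[sel, , drop = FALSE], method = "spearman")
}

#' Sample ordination (PCA) on normalized peak coverage
#'
#' Centered principal components of the samples; the sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param normPeaks peaks x samples normalized matrix (>= 3 samples).
#' @param nComp components to return (default 2).
#' @return list: `coords` (samples x nComp), `varFrac` (variance fractions
#'   of all components, non-increasing).
#' @export
samplePCA <- function(normPeaks, nComp = 2) {
  stopifnot(ncol(normPeaks) >= 3)
  pc <- stats::prcomp(t(normPeaks), center = TRUE, scale. = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  nComp <- min(nComp, ncol(pc$x))
  coords <- pc$x[, seq_len(nComp), drop = FALSE]
  for (j in seq_len(nComp)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  list(coords = coords, varFrac = varFrac)
}

#' Hierarchical tissue proximity tree
#'
#' Average-linkage agglomeration on Euclidean distances between tissue mean
#' profiles; serializable as Newick with branch lengths = merge heights.
#'
#' @param profiles tissue x feature numeric matrix (>= 3 tissues, tissue
#'   names as rownames).
#' @return list: `hclust`, `phylo` (ape), `newick` (string).
#' @export
tissueTree <- function(profiles) {
  stopifnot(nrow(profiles) >= 3)
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph,
       newick = ape::write.tree(ph))
}

#' Are two leaves sisters in a tree?
#'
#' TRUE when the two tips share an immediate parent node.
#'
#' @param tree output of [tissueTree()] (or an `ape` phylo).
#' @param a,b tip labels.
#' @return logical.
#' @export
areSisterLeaves <- function(tree, a, b) {
  ph <- if (inherits(tree, "phylo")) tree else tree$phylo
  ia <- match(a, ph$tip.label); ib <- match(b, ph$tip.label)
  stopifnot(!is.na(ia), !is.na(ib))
  pa <- ph$edge[ph$edge[, 2] == ia, 1]
  pb <- ph$edge[ph$edge[, 2] == ib, 1]
  pa == pb
}
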