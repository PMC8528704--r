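# Set-construction logic: genuine peaks, the combined peak atlas,
# tissue-specific features by exhaustive pairwise intersection, two-tissue
# shared signatures, and plain set overlap.

#' Genuine peaks: reproducible across all biological replicates
#'
#' Merges the replicate peak sets and keeps a merged interval only when
#' every replicate contributes at least one overlapping source interval.
#'
#' @param replicates list of >= 2 named `GRanges` (one per replicate).
#' @param minOverlap passed to [mergeOverlapping()].
#' @return `GRanges` of genuine merged peaks (with source metadata).
#' @export
genuinePeaks <- function(replicates, minOverlap = 1) {
  if (length(replicates) < 2) stop("need >= 2 replicate peak sets")
  merged <- mergeOverlapping(replicates, minOverlap)
  nSets <- length(replicates)
  inAll <- vapply(S4Vectors::mcols(merged)$sourceSets,
                  function(s) length(unique(s)) == nSets, logical(1))
  merged[inAll]
}

#' Combined peak atlas across tissues
#'
#' Merges per-tissue genuine peak sets into one atlas, flags per-tissue
#' presence (>= 1 bp overlap with that tissue's genuine peaks), and marks
#' the "shared" subset present in every tissue.
#'
#' @param tissueGenuine named list of `GRanges`, one per tissue.
#' @param minOverlap passed to [mergeOverlapping()].
#' @return `GRanges` atlas with a logical presence metadata column per
#'   tissue and a `shared` column.
#' @export
combinedAtlas <- function(tissueGenuine, minOverlap = 1) {
  if (!length(tissueGenuine)) stop("empty input list")
  atlas <- mergeOverlapping(tissueGenuine, minOverlap)
  pres <- vapply(tissueGenuine, function(gr)
    IRanges::overlapsAny(atlas, gr, ignore.strand = TRUE),
    logical(length(atlas)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(atlas))
  colnames(pres) <- names(tissueGenuine)
  for (tl in colnames(pres)) S4Vectors::mcols(atlas)[[tl]] <- pres[, tl]
  S4Vectors::mcols(atlas)$shared <- rowSums(pres) == ncol(pres)
  atlas
}

# Fetch the DifferentialResult for tissue vs other, flipping sign when the
# stored comparison is the reverse orientation. Keys are "A_vs_B".
.pairResult <- function(results, tissue, other) {
  k1 <- paste(tissue, other, sep = "_vs_")
  k2 <- paste(other, tissue, sep = "_vs_")
  if (!is.null(results[[k1]])) {
    r <- results[[k1]]
    data.frame(feature_id = r$feature_id, log2fc = r$log2fc,
               p = r$p, q = r$q)
  } else if (!is.null(results[[k2]])) {
    r <- results[[k2]]
    data.frame(feature_id = r$feature_id, log2fc = -r$log2fc,
               p = r$p, q = r$q)
  } else stop("missing comparison: ", k1)
}

#' Call tissue-specific features by pairwise intersection
#'
#' A feature is tissue-specific ("1 versus 1" mode) when it is
#' significantly higher (or lower, for `direction = "down"`) in the target
#' tissue than in *every* other tissue: the per-comparison gates are
#' `p < alpha` (raw by default, per-comparison BH-adjusted q with
#' `useAdjusted = TRUE`) and signed `log2fc` strictly beyond `fcMin`.
#'
#' @param results named list of [DifferentialResult-class], keys
#'   `"A_vs_B"`; every `tissue` vs other comparison must be present (either
#'   orientation).
#' @param tissue target tissue label.
#' @param otherTissues labels of the remaining tissues.
#' @param direction `"up"` or `"down"`.
#' @param alpha significance threshold (default 0.05).
#' @param fcMin minimum |log2fc| per comparison (default 0).
#' @param useAdjusted gate on BH-adjusted q instead of raw p.
#' @return character vector of feature ids, with a `provenance` attribute
#'   recording every comparison and the thresholds.
#' @export
callTissueSpecific <- function(results, tissue, otherTissues,
                               direction = c("up", "down"), alpha = 0.05,
                               fcMin = 0, useAdjusted = FALSE) {
  direction <- match.arg(direction)
  keep <- NULL
  prov <- list(tissue = tissue, direction = direction, alpha = alpha,
               fcMin = fcMin, useAdjusted = useAdjusted,
               comparisons = character())
  for (other in otherTissues) {
    r <- .pairResult(results, tissue, other)
    pv <- if (useAdjusted) r$q else r$p
    pass <- if (direction == "up") pv < alpha & r$log2fc > fcMin
            else pv < alpha & r$log2fc < -fcMin
    ids <- r$feature_id[pass]
    keep <- if (is.null(keep)) ids else intersect(keep, ids)
    prov$comparisons <- c(prov$comparisons,
                          paste(tissue, other, sep = "_vs_"))
  }
  structure(keep, provenance = prov)
}

#' Shared signature of two tissues against the rest
#'
#' Features up (or down) in *each* of `tissuesIn` versus *every* tissue in
#' `tissuesOut` ("1 versus 1" separately, then intersected over all
#' `2 x |tissuesOut|` comparisons). With a single in-tissue this reduces to
#' [callTissueSpecific()].
#'
#' @inheritParams callTissueSpecific
#' @param tissuesIn,tissuesOut disjoint tissue label sets.
#' @return character vector of feature ids with `provenance` attribute.
#' @export
sharedSignature <- function(results, tissuesIn, tissuesOut,
                            direction = c("up", "down"), alpha = 0.05,
                            fcMin = 0, useAdjusted = FALSE) {
  if (length(intersect(tissuesIn, tissuesOut)))
    stop("tissuesIn and tissuesOut overlap")
  direction <- match.arg(direction)
  keep <- NULL
  comps <- character()
  for (ti in tissuesIn) {
    s <- callTissueSpecific(results, ti, tissuesOut, direction, alpha,
                            fcMin, useAdjusted)
    comps <- c(comps, attr(s, "provenance")$comparisons)
    keep <- if (is.null(keep)) as.character(s)
            else intersect(keep, as.character(s))
  }
  structure(keep, provenance = list(tissuesIn = tissuesIn,
                                    tissuesOut = tissuesOut,
                                    direction = direction, alpha = alpha,
                                    fcMin = fcMin, comparisons = comps))
}

#' Overlap two feature sets
#'
#' Exact set algebra with stable (input-order) element ordering.
#'
#' @param a,b character vectors of feature ids.
#' @return `list(a_only, both, b_only, counts = c(a_only, both, b_only))`.
#' @export
overlapSets <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  both <- a[a %in% b]
  out <- list(a_only = setdiff(a, b), both = both, b_only = setdiff(b, a))
  out$counts <- c(a_only = length(out$a_only), both = length(both),
                  b_only = length(out$b_only))
  out
}

#' All pairwise differential comparisons between tissues
#'
#' Runs the given two-group test for every unordered tissue pair and
#' returns the keyed result map consumed by [callTissueSpecific()] /
#' [sharedSignature()].
#'
#' @param groupIdx named list mapping tissue label to column indices.
#' @param testFun function(indexA, indexB) -> [DifferentialResult-class].
#' @return named list of results, keys `"A_vs_B"` for each pair (A before
#'   B in `names(groupIdx)` order).
#' @export
pairwiseComparisons <- function(groupIdx, testFun) {
  tl <- names(groupIdx)
  out <- list()
  for (i in seq_along(tl)) for (j in seq_along(tl)) {
    if (i >= j) next
    out[[paste(tl[i], tl[j], sep = "_vs_")]] <-
      testFun(groupIdx[[i]], groupIdx[[j]])
  }
  out
}
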