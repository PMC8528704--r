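#' Merge overlapping peaks across peak sets
#'
#' Unions intervals that overlap by at least `minOverlap` bases, across one
#' or more peak sets (the MergePeaks-style "common peak" step). Each merged
#' interval records the contributing source ids and which input sets they
#' came from, so replicate-reproducibility filters can be applied downstream.
#'
#' @param peaksets a named `GRanges` or a list of named `GRanges`.
#' @param minOverlap minimum overlap in bases for two intervals to merge
#'   (default 1; book-ended intervals never merge).
#' @return A `GRanges` of maximal merged intervals (ids `merged00001`, ...)
#'   with metadata columns `sourceIds` (CharacterList) and `sourceSets`
#'   (IntegerList of input-set indices).
#' @export
mergeOverlapping <- function(peaksets, minOverlap = 1) {
  if (methods::is(peaksets, "GRanges")) peaksets <- list(peaksets)
  if (!length(peaksets)) stop("empty input list")
  stopifnot(minOverlap >= 1)
  setIdx <- rep(seq_along(peaksets), lengths(peaksets))
  all <- do.call(c, unname(lapply(peaksets, unname)))
  ids <- unlist(lapply(peaksets, function(p)
    if (is.null(names(p))) sprintf("peak%05d", seq_along(p)) else names(p)),
    use.names = FALSE)
  if (!length(all)) return(GRanges())
  # shrink trick: overlap >= k in the originals <=> overlap >= 1 after
  # trimming k-1 bases off every end (intervals shorter than k cannot merge)
  trim <- minOverlap - 1L
  shrunk <- all
  end(shrunk) <- pmax(end(all) - trim, start(all))
  red <- GenomicRanges::reduce(shrunk, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  # expand back to the union of the original contributing intervals
  lo <- min(IRanges::extractList(start(all), revmap))
  hi <- max(IRanges::extractList(end(all), revmap))
  out <- GRanges(seqnames(red), IRanges(lo, hi))
  names(out) <- sprintf("merged%05d", seq_along(out))
  S4Vectors::mcols(out)$sourceIds <- IRanges::extractList(ids, revmap)
  S4Vectors::mcols(out)$sourceSets <- IRanges::extractList(setIdx, revmap)
  out
}

#' Strand-aware promoter windows
#'
#' @param ann a [GeneAnnotation-class].
#' @param upstream,downstream window extent around the TSS in bases
#'   (defaults 1000 / 100, the HOMER-style promoter-TSS convention; the
#'   window includes the TSS itself on the downstream side).
#' @return `GRanges` of promoter windows, names = gene ids, trimmed to
#'   chromosome bounds.
#' @export
promoterWindows <- function(ann, upstream = 1000, downstream = 100) {
  g <- ann@genes
  tssGr <- GRanges(seqnames(g),
                   IRanges(S4Vectors::mcols(g)$tss, width = 1L),
                   strand = strand(g))
  w <- GenomicRanges::promoters(tssGr, upstream = upstream,
                                downstream = downstream)
  start(w) <- pmax(start(w), 1L)
  end(w) <- pmin(end(w), ann@chromSizes[as.character(seqnames(w))])
  names(w) <- names(g)
  w
}

#' Classify peaks into promoter / intragenic / intergenic
#'
#' A peak overlapping (by any base) a promoter window is `promoter`;
#' otherwise a peak overlapping any gene span is `intragenic` (5'UTR, 3'UTR,
#' exon and intron are all inside the span); anything else is `intergenic`.
#' Priority promoter > intragenic > intergenic resolves multi-feature
#' overlaps.
#'
#' @param peaks `GRanges` of peaks.
#' @param ann a [GeneAnnotation-class]; every peak chromosome must be known.
#' @inheritParams promoterWindows
#' @return factor of length `length(peaks)` with levels
#'   `promoter`, `intragenic`, `intergenic`.
#' @export
classifyRegions <- function(peaks, ann, upstream = 1000, downstream = 100) {
  unknown <- setdiff(as.character(seqnames(peaks)), names(ann@chromSizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  prom <- IRanges::overlapsAny(peaks, promoterWindows(ann, upstream, downstream),
                               ignore.strand = TRUE)
  genic <- IRanges::overlapsAny(peaks, ann@genes, ignore.strand = TRUE)
  cls <- ifelse(prom, "promoter", ifelse(genic, "intragenic", "intergenic"))
  factor(cls, levels = c("promoter", "intragenic", "intergenic"))
}

#' Assign each peak to its nearest gene by TSS distance
#'
#' Distance is measured from the peak midpoint (integer floor of the
#' interval center) to each gene's TSS; the signed distance is
#' strand-oriented (positive = downstream of the TSS). Ties in absolute
#' distance break to the lexicographically smallest gene id. Peaks on
#' chromosomes without genes get the `NA` sentinel.
#'
#' @param peaks `GRanges` of peaks.
#' @param ann a [GeneAnnotation-class].
#' @return `DataFrame` with columns `gene_id` and `distance`, one row per
#'   peak (rownames = peak names when present).
#' @export
nearestGenes <- function(peaks, ann) {
  g <- ann@genes
  mid <- floor((start(peaks) - 1L + end(peaks)) / 2) + 1L  # 1-based midpoint
  geneId <- rep(NA_character_, length(peaks))
  dist <- rep(NA_integer_, length(peaks))
  pchr <- as.character(seqnames(peaks))
  gchr <- as.character(seqnames(g))
  for (chr in unique(pchr)) {
    gi <- which(gchr == chr)
    pi <- which(pchr == chr)
    if (!length(gi)) next
    tss <- S4Vectors::mcols(g)$tss[gi]
    ids <- names(g)[gi]
    neg <- as.character(strand(g))[gi] == "-"
    ord <- order(tss, ids)
    tss <- tss[ord]; ids <- ids[ord]; neg <- neg[ord]
    m <- mid[pi]
    k <- findInterval(m, tss)
    for (j in seq_along(pi)) {
      lo <- k[j]; cand <- c(if (lo >= 1) lo, if (lo < length(tss)) lo + 1L)
      # widen to all genes sharing the two flanking TSS positions
      best <- min(abs(m[j] - tss[cand]))
      sel <- which(abs(m[j] - tss) == best)
      pick <- sel[order(ids[sel])[1L]]
      geneId[pi[j]] <- ids[pick]
      dd <- m[j] - tss[pick]
      dist[pi[j]] <- if (neg[pick]) -dd else dd
    }
  }
  DataFrame(gene_id = geneId, distance = dist,
            row.names = if (is.null(names(peaks))) NULL else names(peaks))
}
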