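# Brute-force oracles, written independently of the package's interval
# engine and test statistics. All coordinates here are 1-based closed.

# Interval merging as union-find on the pairwise overlap graph.
oracleMerge <- function(df, minOverlap = 1) {
  n <- nrow(df)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (chr in unique(df$chrom)) {
    ix <- which(df$chrom == chr)
    if (length(ix) < 2) next
    lo <- outer(df$start[ix], df$start[ix], pmax)
    hi <- outer(df$end[ix], df$end[ix], pmin)
    edges <- which(hi - lo + 1 >= minOverlap & upper.tri(lo), arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      a <- findRoot(ix[edges[k, 1]]); b <- findRoot(ix[edges[k, 2]])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n), findRoot, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix)
    data.frame(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
               end = max(df$end[ix]))))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Genuine peaks: merged components in which every replicate contributes.
oracleGenuine <- function(dfs, minOverlap = 1) {
  df <- do.call(rbind, Map(function(d, i) cbind(d, rep_ = i),
                           dfs, seq_along(dfs)))
  merged <- oracleMerge(df[, c("chrom", "start", "end")], minOverlap)
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    inComp <- df$chrom == merged$chrom[i] &
      pmin(df$end, merged$end[i]) - pmax(df$start, merged$start[i]) + 1 >= 1
    length(unique(df$rep_[inComp])) == length(dfs)
  }, logical(1))
  merged <- merged[keep, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# Region classification from first principles: strand-oriented TSS offset
# in [-1000, 99] => promoter window.
oracleClassify <- function(pk, genesDf) {
  vapply(seq_len(nrow(pk)), function(i) {
    g <- genesDf[genesDf$chrom == pk$chrom[i], , drop = FALSE]
    if (!nrow(g)) return("intergenic")
    wlo <- ifelse(g$strand == "+", g$tss - 1000, g$tss - 99)
    whi <- ifelse(g$strand == "+", g$tss + 99, g$tss + 1000)
    if (any(pk$end[i] >= wlo & pk$start[i] <= whi)) return("promoter")
    if (any(pk$end[i] >= g$start & pk$start[i] <= g$end)) return("intragenic")
    "intergenic"
  }, "")
}

# Nearest gene by exhaustive midpoint-to-TSS scan with lexicographic ties.
oracleNearest <- function(pk, genesDf) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(pk)),
                    distance = rep(NA_integer_, nrow(pk)))
  for (i in seq_len(nrow(pk))) {
    g <- genesDf[genesDf$chrom == pk$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    mid <- floor((pk$start[i] - 1 + pk$end[i]) / 2) + 1
    d <- abs(mid - g$tss)
    cand <- g[d == min(d), , drop = FALSE]
    pick <- cand[order(cand$gene_id)[1], ]
    dd <- mid - pick$tss
    out$gene_id[i] <- pick$gene_id
    out$distance[i] <- if (pick$strand == "-") -dd else dd
  }
  out
}

# Exact permutation two-sided p for the rank-sum statistic.
oraclePermWilcox <- function(x, nA) {
  n <- length(x)
  r <- rank(x)
  combos <- utils::combn(n, nA)
  W <- colSums(matrix(r[combos], nrow = nA))
  ew <- nA * (n + 1) / 2
  wObs <- sum(r[seq_len(nA)])
  mean(abs(W - ew) >= abs(wObs - ew) - 1e-12)
}

# Independent BH step-up.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (k in seq_along(o)) {
    i <- o[k]
    rank_i <- n - k + 1
    running <- min(running, p[i] * n / rank_i)
    adj[i] <- min(running, 1)
  }
  adj
}

# GRanges -> 1-based closed data.frame in canonical (chrom, start) order
grToDf <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

annToGenesDf <- function(ann) {
  g <- genes(ann)
  data.frame(gene_id = names(g),
             chrom = as.character(GenomicRanges::seqnames(g)),
             strand = as.character(GenomicRanges::strand(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             tss = S4Vectors::mcols(g)$tss, stringsAsFactors = FALSE)
}

randomIntervals <- function(n, seed, chroms = c("chrA", "chrB"),
                            span = 100000, width = c(50, 400)) {
  set.seed(seed)
  st <- sample(span, n, replace = TRUE)
  w <- sample(width[1]:width[2], n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = st, end = st + w)
  df$id <- sprintf("iv%04d", seq_len(n))
  df
}

dfToGr <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  names(gr) <- if ("id" %in% names(df)) df$id
               else sprintf("iv%04d", seq_len(nrow(df)))
  gr
}
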