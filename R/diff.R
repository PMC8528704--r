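# Native differential statistics: tie-corrected rank-sum DE for cells,
# median-of-ratios size factors and a simplified NB Wald test for peak
# counts, and BH adjustment. These are documented simplified equivalents of
# the external tools the field uses; numeric parity with those tools is not
# a goal — planted-truth recovery and calibration are.

# Exact tie-aware two-sided permutation p of the rank sum for the first nA
# of n values, by dynamic programming over doubled (integer) average ranks.
.exactRankSumP <- function(ranks, nA) {
  r2 <- as.integer(round(2 * ranks))
  n <- length(r2)
  wObs <- sum(r2[seq_len(nA)])
  maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(nA)])
  f <- matrix(0, nA + 1L, maxS + 1L)   # f[k+1, s+1]: subsets of size k, sum s
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- nA
    for (k in kmax:1) {
      src <- seq_len(maxS + 1L - v)
      f[k + 1L, src + v] <- f[k + 1L, src + v] + f[k, src]
    }
  }
  cnt <- f[nA + 1L, ]
  s <- seq_along(cnt) - 1L
  ew <- nA * (n + 1)                   # expected doubled rank sum
  sum(cnt[abs(s - ew) >= abs(wObs - ew) - 1e-9]) / sum(cnt)
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized values:
#' normal approximation with tie correction and continuity correction, or
#' the exact tie-aware permutation distribution of the rank sum (a
#' shift-algorithm convolution) when the two groups together hold at most
#' `exactLimit` cells. The log2 fold change follows the single-cell
#' convention:
#' `log2((mean(expm1(A)) + pc) / (mean(expm1(B)) + pc))` with pseudocount
#' `pc = 1`. Genes detected below `minPct` in both groups, or with
#' `|log2fc| < logfcMin`, are reported untested with the `p = 1` sentinel
#' (mirroring the usual pre-filtering); `q` is BH over tested genes.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cellsA,cellsB disjoint index/name sets of columns, each >= 3 cells.
#' @param minPct minimum detected fraction in at least one group (default 0.1).
#' @param logfcMin minimum |log2fc| to test (default 0.25).
#' @param pseudocount added on the expm1-mean scale (default 1).
#' @param exactLimit largest combined group size for which the exact
#'   permutation p is used instead of the normal approximation (default 16).
#' @return A [DifferentialResult-class] with `pct_a`/`pct_b`.
#' @export
wilcoxonDE <- function(norm, cellsA, cellsB, minPct = 0.1, logfcMin = 0.25,
                       pseudocount = 1, exactLimit = 16) {
  ia <- if (is.character(cellsA)) match(cellsA, colnames(norm)) else cellsA
  ib <- if (is.character(cellsB)) match(cellsB, colnames(norm)) else cellsB
  if (length(intersect(ia, ib))) stop("cell groups overlap")
  nA <- length(ia); nB <- length(ib)
  stopifnot(nA >= 3, nB >= 3)
  A <- norm[, ia, drop = FALSE]; B <- norm[, ib, drop = FALSE]
  pctA <- rowMeans(A > 0); pctB <- rowMeans(B > 0)
  lfc <- log2(rowMeans(expm1(A)) + pseudocount) -
         log2(rowMeans(expm1(B)) + pseudocount)
  tested <- (pmax(pctA, pctB) >= minPct) & (abs(lfc) >= logfcMin)
  G <- nrow(norm)
  p <- rep(1, G); stat <- rep(NA_real_, G)
  idx <- which(tested)
  if (length(idx)) {
    X <- cbind(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    r <- matrixStats::rowRanks(X, ties.method = "average")
    RA <- rowSums(r[, seq_len(nA), drop = FALSE])
    n <- nA + nB
    tieTerm <- apply(X, 1, function(x) {
      t <- rle(sort(x))$lengths
      sum(t^3 - t)
    })
    mu <- nA * (n + 1) / 2
    sig2 <- nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- RA - mu
    cc <- pmin(abs(z), 0.5) * sign(z)       # continuity correction
    zz <- ifelse(sig2 > 0, (z - cc) / sqrt(sig2), 0)
    stat[idx] <- RA - nA * (nA + 1) / 2     # Mann-Whitney U
    if (n <= exactLimit) {
      p[idx] <- vapply(seq_along(idx), function(j)
        .exactRankSumP(r[j, ], nA), numeric(1))
    } else {
      p[idx] <- ifelse(sig2 > 0, pmin(1, 2 * stats::pnorm(-abs(zz))), 1)
    }
  }
  q <- rep(1, G)
  q[idx] <- bhAdjust(p[idx])
  rn <- rownames(norm)
  DifferentialResult(
    DataFrame(feature_id = if (is.null(rn)) as.character(seq_len(G)) else rn,
              log2fc = lfc, stat = stat, p = p, q = q, tested = tested,
              pct_a = pctA, pct_b = pctB),
    groupA = paste0(length(ia), " cells"), groupB = paste0(length(ib), " cells"),
    test = "wilcoxon")
}

#' Median-of-ratios size factors
#'
#' `factor_s = median over all-positive peaks of count_ps / geomean_p`,
#' rescaled to geometric mean 1. Falls back to library-size ratios (also
#' centered) with a warning when no peak is positive in every sample.
#'
#' @param counts peaks x samples matrix (or a [PeakExperiment-class]).
#' @return named positive numeric vector, geometric mean 1.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- assay(counts, "counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no peak with nonzero counts in all samples; ",
            "using library-size ratios")
    sf <- colSums(counts)
  } else {
    geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE] / geo, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Simplified negative-binomial Wald test for differential accessibility
#'
#' Per-peak NB model with groupwise means on size-factor-normalized counts.
#' Dispersion is method-of-moments per peak, pooled as the mean within
#' mean-rank bins (a dispersion-mean trend without per-peak shrinkage). The
#' Wald z is the log fold change over its delta-method standard error,
#' `Var(ln mu_hat_g) = (E(1/sf_g)/mu_g + alpha) / n_g`, two-sided normal p.
#' All-zero peaks return `log2fc = 0, p = 1`.
#'
#' @param counts peaks x samples matrix (or [PeakExperiment-class]).
#' @param groupA,groupB disjoint column index/name sets, each >= 2 samples.
#' @param sf size factors from [sizeFactorsMedianRatio()] (computed from
#'   `counts` when missing).
#' @param nBins dispersion-trend bins (default 20).
#' @return A [DifferentialResult-class].
#' @export
nbWaldDA <- function(counts, groupA, groupB, sf = NULL, nBins = 20) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- assay(counts, "counts")
  ia <- if (is.character(groupA)) match(groupA, colnames(counts)) else groupA
  ib <- if (is.character(groupB)) match(groupB, colnames(counts)) else groupB
  if (length(intersect(ia, ib))) stop("sample groups overlap")
  nA <- length(ia); nB <- length(ib)
  stopifnot(nA >= 2, nB >= 2)
  if (is.null(sf)) sf <- sizeFactorsMedianRatio(counts)
  K <- sweep(counts, 2, sf, `/`)
  KA <- K[, ia, drop = FALSE]; KB <- K[, ib, drop = FALSE]
  muA <- rowMeans(KA); muB <- rowMeans(KB)
  varP <- ((nA - 1) * matrixStats::rowVars(KA) +
           (nB - 1) * matrixStats::rowVars(KB)) / (nA + nB - 2)
  mu <- (nA * muA + nB * muB) / (nA + nB)
  invA <- mean(1 / sf[ia]); invB <- mean(1 / sf[ib])
  inv <- (nA * invA + nB * invB) / (nA + nB)
  alphaRaw <- ifelse(mu > 0, (varP - mu * inv) / mu^2, NA_real_)
  ok <- is.finite(alphaRaw) & mu > 0
  alpha <- rep(1e-8, length(mu))
  if (sum(ok) >= 2) {
    nb <- max(1L, min(nBins, floor(sum(ok) / 10)))
    bins <- cut(rank(mu[ok], ties.method = "first"), breaks = nb,
                labels = FALSE)
    # bin MEAN, not median: per-peak MoM estimates are right-skewed at few
    # samples, so the median is biased low and would inflate type-I error
    est <- tapply(alphaRaw[ok], bins, mean)
    alpha[ok] <- pmax(est[bins], 1e-8)
  }
  pc <- 0.5
  aZ <- muA == 0; bZ <- muB == 0
  muA2 <- ifelse(aZ, pc, muA); muB2 <- ifelse(bZ, pc, muB)
  lfc <- log2(muA2) - log2(muB2)
  vA <- (invA / muA2 + alpha) / nA
  vB <- (invB / muB2 + alpha) / nB
  z <- (log(muA2) - log(muB2)) / sqrt(vA + vB)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  allZero <- aZ & bZ
  lfc[allZero] <- 0; z[allZero] <- 0; p[allZero] <- 1
  lfc <- unname(lfc); z <- unname(z); p <- unname(p)
  rn <- rownames(counts)
  DifferentialResult(
    DataFrame(feature_id = if (is.null(rn))
                as.character(seq_along(mu)) else rn,
              log2fc = lfc, stat = z, p = p, q = bhAdjust(p),
              tested = !allZero),
    groupA = paste(colnames(counts)[ia], collapse = ","),
    groupB = paste(colnames(counts)[ib], collapse = ","),
    test = "nb_wald")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1); errors on p
#' outside \[0, 1\].
#'
#' @param pvals numeric vector of raw p-values.
#' @return adjusted p-values, same length.
#' @export
bhAdjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
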