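# A tiny hand-built pairwise result map: 3 tissues, 4 features.
mockResults <- function() {
  mk <- function(lfc, p) {
    DataFrame(feature_id = paste0("f", 1:4), log2fc = lfc, stat = NA_real_,
              p = p, q = bhAdjust(p), tested = TRUE)
  }
  list(
    # f1 up in LI vs both; f2 up in LI vs SI only; f3 down in LI vs both
    LI_vs_SI = mk(c(2, 1.5, -2, 0), c(0.001, 0.01, 0.001, 0.9)),
    LI_vs_BM = mk(c(2, 0.1, -2, 0), c(0.001, 0.8, 0.001, 0.9)),
    SI_vs_BM = mk(c(0, 0, 0, 0), c(0.9, 0.9, 0.9, 0.9)))
}

test_that("pairwise intersection keeps only features up against every tissue", {
  res <- mockResults()
  up <- callTissueSpecific(res, "LI", c("SI", "BM"), "up")
  expect_equal(as.character(up), "f1")          # f2 fails the BM comparison
  down <- callTissueSpecific(res, "LI", c("SI", "BM"), "down")
  expect_equal(as.character(down), "f3")
  # reverse-orientation lookup flips the sign
  upSI <- callTissueSpecific(res, "SI", c("LI"), "up")
  expect_equal(as.character(upSI), "f3")
  expect_error(callTissueSpecific(res, "LI", c("SI", "Lung"), "up"),
               "missing comparison")
  prov <- attr(up, "provenance")
  expect_setequal(prov$comparisons, c("LI_vs_SI", "LI_vs_BM"))
})

test_that("tissue-specific calls shrink as gates tighten (monotonicity)", {
  set.seed(10)
  mk <- function() DataFrame(feature_id = paste0("f", 1:200),
                             log2fc = rnorm(200), stat = NA_real_,
                             p = runif(200)^2, q = NA_real_, tested = TRUE)
  res <- list(A_vs_B = mk(), A_vs_C = mk(), B_vs_C = mk())
  for (r in names(res)) res[[r]]$q <- bhAdjust(res[[r]]$p)
  loose <- callTissueSpecific(res, "A", c("B", "C"), "up", alpha = 0.2)
  tight <- callTissueSpecific(res, "A", c("B", "C"), "up", alpha = 0.05)
  fc <- callTissueSpecific(res, "A", c("B", "C"), "up", alpha = 0.2,
                           fcMin = 0.5)
  expect_true(all(tight %in% loose))
  expect_true(all(fc %in% loose))
  # up-sets of different tissues are disjoint at fcMin > 0
  upB <- callTissueSpecific(res, "B", c("A", "C"), "up", alpha = 0.2,
                            fcMin = 0.1)
  upA <- callTissueSpecific(res, "A", c("B", "C"), "up", alpha = 0.2,
                            fcMin = 0.1)
  expect_length(intersect(upA, upB), 0)
})

test_that("shared signatures intersect both in-tissues against all out-tissues", {
  res <- mockResults()
  res$LI_vs_BM$log2fc <- c(2, 2, -2, 0); res$LI_vs_BM$p <- rep(0.001, 4)
  res$SI_vs_BM$log2fc <- c(2, 0, 0, 0); res$SI_vs_BM$p <- c(0.001, rep(0.9, 3))
  sig <- sharedSignature(res, c("LI", "SI"), "BM")
  expect_equal(as.character(sig), "f1")   # f2 is flat in SI vs BM
  expect_error(sharedSignature(res, c("LI", "SI"), c("SI")), "overlap")
  # one in-tissue reduces to callTissueSpecific
  one <- sharedSignature(res, "LI", "BM")
  expect_setequal(as.character(one),
                  as.character(callTissueSpecific(res, "LI", "BM", "up")))
})

test_that("genuine peaks require every replicate to contribute", {
  r1 <- dfToGr(data.frame(chrom = "chr1", start = c(100, 500, 900),
                          end = c(200, 600, 1000), id = paste0("a", 1:3)))
  r2 <- dfToGr(data.frame(chrom = "chr1", start = c(120, 910),
                          end = c(220, 1010), id = paste0("b", 1:2)))
  g <- genuinePeaks(list(r1, r2))
  expect_length(g, 2)                    # the 500-600 peak is rep1-only
  expect_equal(GenomicRanges::start(g), c(100, 900))
  expect_error(genuinePeaks(list(r1)), ">= 2")
})

test_that("genuine peaks equal truth peaks with dropout in neither replicate", {
  sim <- smallSim()
  truthGR <- SummarizedExperiment::rowRanges(sim$peaks)
  for (t in c("LI", "BM")) {
    reps <- sim$peaksets[[t]]
    g <- genuinePeaks(reps)
    inBoth <- names(truthGR)[names(truthGR) %in% names(reps[[1]]) &
                             names(truthGR) %in% names(reps[[2]])]
    expect_length(g, length(inBoth))
    expect_true(all(IRanges::overlapsAny(truthGR[inBoth], g)))
    # and matches the brute-force oracle
    orc <- oracleGenuine(lapply(reps, grToDf))
    expect_equal(grToDf(g), orc, ignore_attr = TRUE)
  }
})

test_that("the combined atlas unions tissues and flags shared presence", {
  a <- dfToGr(data.frame(chrom = "chr1", start = c(100, 500),
                         end = c(200, 600), id = c("a1", "a2")))
  b <- dfToGr(data.frame(chrom = "chr1", start = 900, end = 1000, id = "b1"))
  at <- combinedAtlas(list(T1 = a, T2 = a))   # identical sets
  expect_length(at, 2)
  expect_true(all(at$shared))
  at2 <- combinedAtlas(list(T1 = a, T2 = b))  # disjoint sets
  expect_length(at2, 3)
  expect_false(any(at2$shared))
  expect_equal(sum(at2$T1), 2); expect_equal(sum(at2$T2), 1)
})

test_that("shared atlas count equals the brute-force intersection", {
  sim <- smallSim()
  genuine <- lapply(sim$peaksets, genuinePeaks)
  at <- combinedAtlas(genuine)
  brute <- sum(vapply(seq_along(at), function(i)
    all(vapply(genuine, function(g)
      any(pmin(GenomicRanges::end(g), GenomicRanges::end(at)[i]) -
          pmax(GenomicRanges::start(g), GenomicRanges::start(at)[i]) >= 0 &
          as.character(GenomicRanges::seqnames(g)) ==
            as.character(GenomicRanges::seqnames(at))[i]),
      logical(1))), logical(1)))
  expect_equal(sum(at$shared), brute)
})

test_that("genuine peaks are a subset of the plain merge", {
  sim <- smallSim()
  reps <- sim$peaksets$Lung
  g <- genuinePeaks(reps)
  m <- mergeOverlapping(reps)
  expect_true(all(IRanges::overlapsAny(g, m)))
  expect_lte(length(g), length(m))
})

test_that("set overlap counts are exact with stable ordering", {
  o <- overlapSets(c("a", "b", "c"), c("x", "y"))
  expect_equal(unname(o$counts), c(3L, 0L, 2L))
  o2 <- overlapSets(c("a", "b"), c("b", "a", "z"))
  expect_equal(o2$counts[["a_only"]], 0L)
  expect_equal(o2$both, c("a", "b"))
  set.seed(11)
  pool <- sprintf("f%03d", 1:200)
  shared <- sample(pool, 28)
  a <- c(shared, sample(setdiff(pool, shared), 22))
  b <- c(shared, sample(setdiff(pool, c(shared, a)), 52))
  expect_equal(overlapSets(a, b)$counts[["both"]], 28L)
})
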