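test_that("fixed seed fixes every output bit-for-bit", {
  p <- simParams(nGenes = 100, cellsPerTissue = 30, tsGenesPerTissue = 2,
                 sharedIntestinalGenes = 1, seed = 42)
  s1 <- simulateMultiome(p)
  s2 <- simulateMultiome(p)
  expect_identical(grToDf(genes(s1$annotation)), grToDf(genes(s2$annotation)))
  expect_identical(assay(s1$cells, "counts"), assay(s2$cells, "counts"))
  expect_identical(assay(s1$peaks, "counts"), assay(s2$peaks, "counts"))
  expect_identical(geneTruth(s1$truth), geneTruth(s2$truth))
  expect_identical(lapply(s1$peaksets$LI, grToDf),
                   lapply(s2$peaksets$LI, grToDf))
})

test_that("generated gene spans never overlap and hold >= 2 exons", {
  ann <- generateAnnotation(annParams(200, seed = 8))
  gdf <- annToGenesDf(ann)
  for (chr in unique(gdf$chrom)) {
    g <- gdf[gdf$chrom == chr, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  expect_true(all(lengths(ann@exons) >= 2))
  # UTRs sit inside exons, exons inside spans
  g1 <- gdf$gene_id[1]
  expect_true(all(GenomicRanges::start(ann@exons[[g1]]) >= gdf$start[1]))
  expect_true(all(GenomicRanges::end(ann@exons[[g1]]) <= gdf$end[1]))
})

test_that("single-gene annotation yields a computable promoter window", {
  p <- simParams(nGenes = 25, tsGenesPerTissue = 0,
                 sharedIntestinalGenes = 0, corrNPos = 1, corrNNeg = 1,
                 mitoGeneCount = 1, seed = 1)
  ann <- generateAnnotation(p)
  w <- promoterWindows(ann)
  expect_length(w, 25)
  expect_true(all(GenomicRanges::width(w) == 1100))
})

test_that("tsFold = 1 produces no expected expression difference", {
  p <- simParams(nGenes = 200, cellsPerTissue = 150, tsGenesPerTissue = 3,
                 sharedIntestinalGenes = 0, contaminantFraction = 0,
                 corrLatentSd = 0, cellSizeSd = 0, seed = 5)
  p$tsFold <- 1 + 1e-9   # effectively null while passing validation
  sim <- generateScRNA(p, generateAnnotation(p))
  m <- assay(sim$cells, "counts")
  tl <- tissues(sim$cells)
  gt <- geneTruth(sim$truth)
  planted <- gt$gene_id[!is.na(gt$tissue)]
  for (g in planted) {
    t <- gt$tissue[gt$gene_id == g]
    ratio <- mean(m[g, tl == t]) / max(mean(m[g, tl != t]), 1e-9)
    expect_lt(abs(log2(ratio)), 1.5)  # sampling noise only at this n
  }
})

test_that("planted 4-fold genes show a 3-5x empirical mean ratio", {
  sim <- fixture("mc500",
    simulateMultiome(simParams(nGenes = 300, cellsPerTissue = 500,
                               tsGenesPerTissue = 3,
                               sharedIntestinalGenes = 0,
                               contaminantFraction = 0, cellImbalance = 0,
                               mitoMeanBoost = 1, seed = 13)))
  m <- assay(sim$cells, "counts")
  tl <- tissues(sim$cells)
  gt <- geneTruth(sim$truth)
  planted <- which(!is.na(gt$tissue))
  for (i in planted) {
    t <- gt$tissue[i]
    ratio <- mean(m[gt$gene_id[i], tl == t]) / mean(m[gt$gene_id[i], tl != t])
    expect_gt(ratio, 3); expect_lt(ratio, 5)
  }
})

test_that("correlation-block genes correlate with the target in sign", {
  p <- simParams(nGenes = 200, cellsPerTissue = 200, tsGenesPerTissue = 1,
                 sharedIntestinalGenes = 0, contaminantFraction = 0,
                 seed = 17)
  sim <- generateScRNA(p, generateAnnotation(p))
  m <- assay(sim$cells, "counts")           # 1000 cells total
  gt <- geneTruth(sim$truth)
  y <- m[p$corrTarget, ]
  for (g in gt$gene_id[gt$corr_sign == "+"])
    expect_gt(cor(m[g, ], y), 0)
  for (g in gt$gene_id[gt$corr_sign == "-"])
    expect_lt(cor(m[g, ], y), 0)
})

test_that("promoterCoupling = 0 plants no promoter accessibility effect", {
  sim <- smallSim()
  pt <- peakTruth(sim$truth)
  expect_true(all(!pt$coupled[pt$region_class == "promoter"]))
  expect_true(all(pt$coupled[pt$region_class == "intragenic" &
                             pt$gene_id %in%
                               geneTruth(sim$truth)$gene_id[
                                 !is.na(geneTruth(sim$truth)$fold)]]))
  # coupled peaks always reference planted genes
  gt <- geneTruth(sim$truth)
  expect_true(all(!is.na(gt$fold[match(pt$gene_id[pt$coupled],
                                       gt$gene_id)])))
})

test_that("zero dropout lets the genuine-peak filter retain every peak", {
  p <- annParams(60, seed = 19)
  p$peakDropout <- 0
  sim <- simulateMultiome(p)
  for (t in names(sim$peaksets)) {
    g <- genuinePeaks(sim$peaksets[[t]])
    expect_equal(length(g), length(SummarizedExperiment::rowRanges(sim$peaks)))
  }
})

test_that("coupled peaks carry a 3-5x normalized count ratio", {
  sim <- smallSim()
  pt <- peakTruth(sim$truth)
  counts <- assay(sim$peaks, "counts")
  sf <- sizeFactorsMedianRatio(counts)
  K <- sweep(counts, 2, sf, `/`)
  st <- tissues(sim$peaks)
  coupled <- pt[pt$coupled & pt$tissue %in% unique(st), ]
  ratios <- vapply(seq_len(nrow(coupled)), function(i) {
    t <- coupled$tissue[i]
    mean(K[coupled$peak_id[i], st == t]) /
      mean(K[coupled$peak_id[i], st != t])
  }, numeric(1))
  expect_gt(median(ratios), 3)
  expect_lt(median(ratios), 5)
  expect_true(all(ratios > 2 & ratios < 7))  # per-peak at 2 replicates
})

test_that("marginal counts follow the negative binomial law", {
  # noise-free covariates so the marginal is exactly NB(mean, dispersion)
  p <- simParams(nGenes = 60, cellsPerTissue = 2000, nTissues = 5,
                 tsGenesPerTissue = 0, sharedIntestinalGenes = 0,
                 contaminantFraction = 0, corrLatentSd = 0, cellSizeSd = 0,
                 cellImbalance = 0, mitoMeanBoost = 1, corrTargetMean = 0.3,
                 corrBlockMean = 0.3, seed = 23)
  sim <- generateScRNA(p, generateAnnotation(p))
  m <- assay(sim$cells, "counts")
  draws <- as.vector(m[1:5, ])   # 5 genes x 10^4 cells, all NB(0.3, 0.5)
  kmax <- max(draws)
  obs <- tabulate(draws + 1L, nbins = kmax + 1L)
  expProb <- dnbinom(0:kmax, mu = 0.3, size = 1 / 0.5)
  keep <- expProb * length(draws) >= 5
  chi <- sum((obs[keep] - expProb[keep] * length(draws))^2 /
             (expProb[keep] * length(draws)))
  expect_lt(chi, qchisq(0.999, df = sum(keep) - 1))
  expect_gt(var(draws) / mean(draws), 1.05)  # overdispersed
})

test_that("the truth manifest reconciles with the emitted matrices", {
  sim <- smallSim()
  expect_setequal(geneTruth(sim$truth)$gene_id, rownames(sim$cells))
  expect_setequal(cellTruth(sim$truth)$cell_id, colnames(sim$cells))
  expect_setequal(peakTruth(sim$truth)$peak_id,
                  names(SummarizedExperiment::rowRanges(sim$peaks)))
  gt <- geneTruth(sim$truth)
  expect_true(all(table(gt$tissue[!is.na(gt$tissue)]) == 4))
  expect_equal(sum(gt$shared_intestinal), 2)
})
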