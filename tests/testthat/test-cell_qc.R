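test_that("cell filters remove exactly the threshold violators", {
  cc <- qcFixture()
  res <- filterCells(cc)
  # 316 < 10^2.5 ~ 316.23 removed; 317 kept; 11% mito removed; 10% kept
  expect_setequal(colnames(res$cells),
                  c("c02", "c04", "c06", "c07", "c08", "c09", "c10", "c12"))
  expect_equal(res$report$n_removed_low_umi, 2)     # c01, c05
  expect_equal(res$report$n_removed_high_mito, 2)   # c03, c11
  expect_equal(res$report$n_input_cells, 12)
  # removals reconcile exactly with the output shape
  expect_equal(res$report$n_input_cells - res$report$n_removed_low_umi -
                 res$report$n_removed_high_mito, ncol(res$cells))
  st <- res$report$cellStatus
  expect_equal(st$reason[st$cell_id == "c01"], "low_umi")
  expect_equal(st$reason[st$cell_id == "c03"], "high_mito")
})

test_that("removing every cell warns instead of erroring", {
  cc <- qcFixture()
  expect_warning(res <- filterCells(cc, umiMinLog10 = 6), "all cells")
  expect_equal(ncol(res$cells), 0)
})

test_that("gene filter follows the per-cell reading, with a total-mode switch", {
  m <- rbind(gKeep = c(5L, 5L, 0L),   # >= 5 in two cells -> kept
             gDrop = c(7L, 4L, 4L),   # only one cell >= 5 -> removed
             gZero = c(0L, 0L, 0L),   # all-zero -> removed
             gBig = c(50L, 40L, 30L))
  colnames(m) <- paste0("c", 1:3)
  cc <- CellCounts(m, tissue = c("LI", "LI", "SI"))
  expect_setequal(rownames(filterGenes(cc)), c("gKeep", "gBig"))
  # total reading: gDrop has 15 total counts in 3 expressing cells
  expect_setequal(rownames(filterGenes(cc, mode = "total")),
                  c("gKeep", "gDrop", "gBig"))
  expect_false("gZero" %in% rownames(filterGenes(cc, mode = "total")))
})

test_that("cell-then-gene filtering is order-stable on the fixture", {
  cc <- qcFixture()
  a <- filterGenes(filterCells(cc)$cells)
  b <- filterCells(filterGenes(cc))$cells
  expect_equal(dimnames(assay(a, "counts")), dimnames(assay(b, "counts")))
})

test_that("log-normalization matches ln(1 + scale*count/total) elementwise", {
  cc <- qcFixture()
  norm <- assay(logNormalize(cc), "logcounts")
  m <- assay(cc, "counts")
  manual <- log(1 + 1e4 * sweep(m, 2, colSums(m), `/`))
  expect_lt(max(abs(norm - manual)), 1e-12)
  expect_true(all(norm[m == 0] == 0))

  # closed form: count 1 when the cell total equals the scale factor
  one <- matrix(c(1L, 9999L), 2, 1, dimnames = list(c("a", "b"), "c1"))
  n1 <- logNormalize(one, scale = 1e4)
  expect_equal(n1["a", 1], log(2))

  # random fixture, elementwise
  set.seed(1)
  r <- matrix(rpois(1000, 4) + 1L, 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  expect_lt(max(abs(logNormalize(r) -
                    log1p(1e4 * sweep(r, 2, colSums(r), `/`)))), 1e-12)
})

test_that("log-normalization errors on zero-total cells, naming them", {
  m <- matrix(c(1L, 0L), 1, 2, dimnames = list("g", c("ok", "empty")))
  expect_error(logNormalize(m), "empty")
})

test_that("log-normalization is monotone in count within a cell", {
  set.seed(2)
  m <- matrix(sample(0:50, 60, TRUE), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
  m[1, ] <- pmax(m[1, ], 1L)
  n <- logNormalize(m)
  for (j in 1:3) expect_equal(order(n[, j]), order(m[, j], seq_len(20)))
})

test_that("marker-panel flagging hits the planted extreme and spares the null", {
  set.seed(3)
  m <- matrix(rpois(200 * 60, 2), 200, 60,
              dimnames = list(c(paste0("g", 1:196),
                                "Jchain", "Mzb1", "Ebf1", "Cd79a"),
                              paste0("c", 1:60)))
  m[197:200, 1:10] <- m[197:200, 1:10] + 40L   # 10x-elevated B-cell cluster
  cc <- logNormalize(CellCounts(m, tissue = "LI"))
  clusters <- rep(c("bad", "ok1", "ok2"), c(10, 25, 25))
  panels <- list(Bcell = c("Jchain", "Mzb1", "Ebf1", "Cd79a"))
  fl <- flagContaminants(cc, clusters, panels)
  expect_equal(fl$flagged$Bcell, "bad")
  expect_setequal(colnames(fl$cells), paste0("c", 11:60))
  expect_equal(fl$report$n_removed_contaminant, 10)

  # nothing elevated -> nothing flagged
  m0 <- matrix(rpois(200 * 60, 2), 200, 60, dimnames = dimnames(m))
  fl0 <- flagContaminants(logNormalize(CellCounts(m0, tissue = "LI")),
                          clusters, panels)
  expect_length(fl0$flagged$Bcell, 0)
  expect_equal(ncol(fl0$cells), 60)

  # unknown marker names warn and are ignored
  expect_warning(
    flagContaminants(cc, clusters, list(X = c("Jchain", "NotAGene"))),
    "NotAGene")
})

test_that("planted contaminant clusters are recovered from the manifest", {
  sim <- accSim()
  ct <- cellTruth(sim$truth)
  out <- logNormalize(filterGenes(filterCells(sim$cells)$cells))
  cl <- clusterCells(out, seed = 12)
  fl <- flagContaminants(out, cl, list(
    ILC3 = c("Il22", "Rorc", "Ccr6", "Klrb1c"),
    Bcell = c("Jchain", "Mzb1", "Ebf1", "Cd79a")))
  removed <- setdiff(colnames(out), colnames(fl$cells))
  marker <- intersect(ct$cell_id[ct$contaminant %in% c("ILC3", "Bcell")],
                      colnames(out))
  expect_gte(mean(marker %in% removed), 0.95)
  falsePos <- ct$contaminant[match(removed, ct$cell_id)] == "none"
  expect_lt(mean(falsePos), 0.2)
})

test_that("downsampling equalizes tissues to the minimum without mutation", {
  sim <- smallSim()
  cells <- sim$cells
  down <- downsamplePerTissue(cells, seed = 4)
  tb <- table(tissues(down))
  expect_true(all(tb == min(table(tissues(cells)))))
  # per-cell columns carried over unchanged
  common <- colnames(down)
  expect_identical(assay(down, "counts")[, common],
                   assay(cells, "counts")[, common])
  # deterministic
  down2 <- downsamplePerTissue(cells, seed = 4)
  expect_identical(colnames(down), colnames(down2))
  # different seed, generally different selection
  down3 <- downsamplePerTissue(cells, seed = 5)
  expect_false(identical(colnames(down), colnames(down3)))
})

test_that("equal tissue sizes downsample to the identity up to order", {
  m <- matrix(rpois(40, 3), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  cc <- CellCounts(m, tissue = rep(c("LI", "SI"), each = 5))
  expect_setequal(colnames(downsamplePerTissue(cc, seed = 1)), colnames(cc))
})
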