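# Shared fixtures, computed once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# Full default-condition simulation shared by the planted-truth and
# qualitative-structure acceptance checks.
accSim <- function() fixture("accSim", simulateMultiome(simParams(seed = 11)))

accQC <- function() fixture("accQC", runCellQC(accSim()$cells, rounds = 2,
                                               seed = 11))

accOCR <- function() fixture("accOCR", runTSOCRs(accSim()$peaks,
                                                 accSim()$peaksets))

# Small simulation for module-level planted-truth checks (umiMinLog10 must
# be scaled down with it: at 300 genes a cell's library is far below the
# default 10^2.5 floor).
smallSim <- function() fixture("smallSim",
  simulateMultiome(simParams(nGenes = 300, cellsPerTissue = 80,
                             tsGenesPerTissue = 4, sharedIntestinalGenes = 2,
                             mitoMeanBoost = 1, seed = 7)))

# Hand-built 12-cell / 10-gene QC fixture. Thresholds: 10^2.5 = 316.23
# total UMIs, 10% mitochondrial fraction (genes mt-a, mt-b).
qcFixture <- function() {
  genes <- c(paste0("g", 1:8), "mt-a", "mt-b")
  cells <- sprintf("c%02d", 1:12)
  m <- matrix(0L, 10, 12, dimnames = list(genes, cells))
  fill <- function(cell, total, mito) {
    m[9, cell] <<- mito
    rest <- total - mito
    base <- rest %/% 8L
    m[1:8, cell] <<- base
    m[1, cell] <<- m[1, cell] + rest - 8L * base
  }
  fill("c01", 316L, 0L)    # below 316.23 -> removed (low UMI)
  fill("c02", 317L, 0L)    # boundary keep side
  fill("c03", 1000L, 110L) # 11% mito -> removed
  fill("c04", 1000L, 100L) # exactly 10% -> kept (inclusive)
  fill("c05", 300L, 0L)    # removed (low UMI)
  fill("c06", 400L, 20L)
  fill("c07", 500L, 10L)
  fill("c08", 640L, 60L)
  fill("c09", 800L, 30L)
  fill("c10", 900L, 89L)
  fill("c11", 320L, 33L)   # 10.3% mito -> removed
  fill("c12", 2000L, 120L) # 6% -> kept
  CellCounts(m, tissue = rep(c("LI", "SI", "BM"), 4),
             mitoGenes = c("mt-a", "mt-b"))
}

# Annotation-only parameter helper for small interval fixtures.
annParams <- function(nGenes, seed)
  simParams(nGenes = nGenes, tsGenesPerTissue = 1, sharedIntestinalGenes = 0,
            corrNPos = 2, corrNNeg = 1, mitoGeneCount = 2, seed = seed)
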