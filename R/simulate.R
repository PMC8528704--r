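# Synthetic five-tissue multi-omic generator with a planted-truth manifest.
# Counts are Gamma-Poisson (negative binomial) in both modalities; the
# correlation block rides on a shared log-normal per-cell latent factor so
# marginals stay NB.

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

#' Parameters for the synthetic multi-tissue generator
#'
#' Defaults encode the simulation's study conditions: five tissues (BM, LI,
#' SI, Lung, Pancreas), 500 cells/tissue (+-30% imbalance), 2,000 genes with
#' NB dispersion 0.5, 20 planted tissue-specific genes per tissue at 4-fold,
#' 15 shared intestinal genes (up in both LI and SI), 13 mitochondrial
#' genes, 5% contaminant cells bearing ILC3 / B-cell marker panels plus
#' high-mito dying cells, a latent-factor correlation block of 12 positive
#' and 3 negative genes around the target gene Ikzf3, and replicate ATAC
#' peak counts (2 replicates/tissue, 5,000 peaks at 2,000 genes) whose
#' planted 4-fold accessibility effects are routed to non-promoter peaks
#' (`promoterCoupling = 0`).
#'
#' @param nTissues,tissueLabels number and names of tissues.
#' @param cellsPerTissue target cells per tissue before imbalance.
#' @param cellImbalance per-tissue multiplicative jitter half-width (0.3
#'   means tissue sizes are drawn uniformly in 70--130% of the target).
#' @param nGenes,nbDispersion,baselineMean,cellSizeSd scRNA gene count, NB
#'   dispersion, baseline mean counts/gene/cell, and log-SD of per-cell
#'   size factors.
#' @param tsGenesPerTissue,tsFold,sharedIntestinalGenes planted
#'   tissue-specific genes per tissue, their multiplicative fold (> 1), and
#'   the number of genes planted up in both LI and SI.
#' @param mitoGeneCount,mitoMeanBoost,dyingMitoBoost mitochondrial genes
#'   (named `mt-*`), their mean boost over baseline, and the extra boost in
#'   dying contaminant cells (pushes mito fraction above 10%).
#' @param contaminantFraction,markerPanels,markerFold fraction of cells that
#'   are contaminants (split over the marker panels plus a "dying" type),
#'   the named marker gene sets, and the marker mean fold in their cells.
#' @param contaminantProgramSize,contaminantProgramFold each marker-bearing
#'   contaminant type also elevates a type-specific random background
#'   program of this many genes by this fold — contaminant cell types
#'   differ transcriptome-wide, not just at their markers.
#' @param corrTarget,corrNPos,corrNNeg,corrLatentSd,corrTargetMean,corrBlockMean
#'   correlation-block target gene name, positive/negative block sizes,
#'   latent log-SD, and mean counts for target and block genes.
#' @param atacReplicates,peaksPerClass,atacBaselineMean,peakNbDispersion,coupledFold,promoterCoupling,atacLibSd,peakDropout
#'   ATAC replicates per tissue (>= 2), peaks per gene per region class
#'   (values in (0, 1]; a fraction f plants one peak on every
#'   `round(1/f)`-th gene), baseline peak mean, NB dispersion, the
#'   accessibility fold coupled to planted genes, the fraction of coupling
#'   routed to promoter peaks, log-SD of sample library factors, and the
#'   per-replicate peak-set dropout rate.
#' @param geneBlockBp genomic block reserved per gene (>= 10000).
#' @param seed integer seed fixing all outputs bit-for-bit.
#' @return A validated parameter list of class `simParams`.
#' @export
simParams <- function(nTissues = 5,
                      tissueLabels = c("BM", "LI", "SI", "Lung", "Pancreas"),
                      cellsPerTissue = 500, cellImbalance = 0.3,
                      nGenes = 2000, nbDispersion = 0.5, baselineMean = 0.3,
                      cellSizeSd = 0.3,
                      tsGenesPerTissue = 20, tsFold = 4,
                      sharedIntestinalGenes = 15,
                      mitoGeneCount = 13, mitoMeanBoost = 6, dyingMitoBoost = 5,
                      contaminantFraction = 0.05,
                      markerPanels = list(
                        ILC3 = c("Il22", "Rorc", "Ccr6", "Klrb1c"),
                        Bcell = c("Jchain", "Mzb1", "Ebf1", "Cd79a")),
                      markerFold = 20,
                      contaminantProgramSize = 150,
                      contaminantProgramFold = 6,
                      corrTarget = "Ikzf3", corrNPos = 12, corrNNeg = 3,
                      corrLatentSd = 1.0, corrTargetMean = 2.0,
                      corrBlockMean = 1.0,
                      atacReplicates = 2,
                      peaksPerClass = c(promoter = 1, intragenic = 1,
                                        intergenic = 0.5),
                      atacBaselineMean = 50, peakNbDispersion = 0.05,
                      coupledFold = 4, promoterCoupling = 0,
                      atacLibSd = 0.2, peakDropout = 0.05,
                      geneBlockBp = 10000, seed = 1) {
  p <- as.list(environment())
  stopifnot(p$tsFold > 1,
            p$contaminantFraction >= 0, p$contaminantFraction < 1,
            p$atacReplicates >= 2, p$nGenes >= 1,
            length(p$tissueLabels) == p$nTissues,
            all(p$peaksPerClass >= 0), all(p$peaksPerClass <= 1),
            p$promoterCoupling >= 0, p$promoterCoupling <= 1)
  if (p$geneBlockBp < 10000)
    stop("geneBlockBp < 10000: genome too small to place genes without overlap")
  nSpecial <- p$mitoGeneCount + length(unlist(p$markerPanels)) + 1L
  if (p$nGenes < nSpecial + 2L * (p$nTissues * p$tsGenesPerTissue +
                                  p$sharedIntestinalGenes))
    stop("nGenes too small for the requested planted structure")
  class(p) <- "simParams"
  p
}

# Deterministic gene naming: generic ids, with mito/marker/target genes at
# the tail so planted effects never land on them.
simGeneNames <- function(params) {
  nm <- sprintf("g%04d", seq_len(params$nGenes))
  special <- c(paste0("mt-", seq_len(params$mitoGeneCount)),
               unlist(params$markerPanels, use.names = FALSE),
               params$corrTarget)
  nm[(params$nGenes - length(special) + 1L):params$nGenes] <- special
  nm
}

#' Generate a toy genome annotation
#'
#' Lays `nGenes` non-overlapping gene models on two synthetic chromosomes,
#' one per `geneBlockBp` block: span at block offset 3000--7000 (0-based),
#' two 1-kb exons flanking a 2-kb intron, 200-bp UTRs at the span ends,
#' random strand. Deterministic for a fixed `seed`.
#'
#' @param params a [simParams()] list.
#' @return A [GeneAnnotation-class].
#' @export
generateAnnotation <- function(params) {
  withSeed(params$seed, {
    n <- params$nGenes
    bl <- params$geneBlockBp
    nm <- simGeneNames(params)
    n1 <- ceiling(n / 2)
    chrom <- rep(c("chrS1", "chrS2"), c(n1, n - n1))
    blockIdx <- c(seq_len(n1), seq_len(n - n1)) - 1L
    off <- blockIdx * bl
    strand <- sample(c("+", "-"), n, replace = TRUE)
    st <- off + 3001L; en <- off + 7000L
    g <- GRanges(chrom, IRanges(st, en), strand = strand)
    names(g) <- nm
    S4Vectors::mcols(g)$tss <- ifelse(strand == "+", st, en)
    splitGRL <- function(s, e, gene) {
      gr <- GRanges(chrom[match(gene, nm)], IRanges(s, e))
      grl <- GenomicRanges::split(gr, factor(gene, levels = nm))
      grl
    }
    exons <- splitGRL(c(st, off + 6001L), c(off + 4000L, en), c(nm, nm))
    plus <- strand == "+"
    u5s <- ifelse(plus, st, en - 199L); u5e <- ifelse(plus, st + 199L, en)
    u3s <- ifelse(plus, en - 199L, st); u3e <- ifelse(plus, en, st + 199L)
    oneGRL <- function(s, e) splitGRL(s, e, nm)
    chromSizes <- c(chrS1 = n1 * bl + 1000L,
                    chrS2 = max(n - n1, 1L) * bl + 1000L)
    GeneAnnotation(genes = g, exons = exons,
                   utr5 = oneGRL(u5s, u5e), utr3 = oneGRL(u3s, u3e),
                   chromSizes = chromSizes)
  })
}

#' Generate the five-tissue scRNA count matrix with planted truth
#'
#' Counts are NB with mean `baselineMean x tissue fold x cell size factor`;
#' planted tissue-specific genes carry `tsFold` in one tissue (shared
#' intestinal genes in both LI and SI); the correlation block multiplies the
#' target's and positive genes' means by a per-cell log-normal latent factor
#' and divides the negative genes' means by it; contaminant cells get
#' `markerFold`-elevated panel markers, and dying cells a high mitochondrial
#' fraction.
#'
#' @param params a [simParams()] list.
#' @param ann the matching [generateAnnotation()] output.
#' @return `list(cells = CellCounts, truth = TruthManifest)`.
#' @export
generateScRNA <- function(params, ann) {
  withSeed(params$seed + 1L, {
    p <- params
    nm <- names(ann@genes)
    G <- length(nm)
    mito <- startsWith(nm, "mt-")
    markers <- nm %in% unlist(p$markerPanels)
    isTarget <- nm == p$corrTarget
    eligible <- which(!mito & !markers & !isTarget)

    nTS <- p$nTissues * p$tsGenesPerTissue
    planted <- sample(eligible, nTS + p$sharedIntestinalGenes)
    tsIdx <- planted[seq_len(nTS)]
    sharedIdx <- planted[-seq_len(nTS)]
    tsTissue <- rep(p$tissueLabels, each = p$tsGenesPerTissue)
    blockPool <- setdiff(eligible, planted)
    posIdx <- sample(blockPool, p$corrNPos)
    negIdx <- sample(setdiff(blockPool, posIdx), p$corrNNeg)

    sizes <- pmax(2L, round(p$cellsPerTissue *
      stats::runif(p$nTissues, 1 - p$cellImbalance, 1 + p$cellImbalance)))
    tissue <- rep(p$tissueLabels, sizes)
    C <- length(tissue)
    types <- c(names(p$markerPanels), "dying")
    nCont <- round(p$contaminantFraction * C)
    contaminant <- rep("none", C)
    if (nCont > 0) {
      who <- sample(C, nCont)
      contaminant[who] <- rep_len(types, nCont)
    }

    foldMat <- matrix(1, G, p$nTissues, dimnames = list(nm, p$tissueLabels))
    foldMat[cbind(tsIdx, match(tsTissue, p$tissueLabels))] <- p$tsFold
    foldMat[sharedIdx, c("LI", "SI")] <- p$tsFold

    baseMu <- rep(p$baselineMean, G)
    baseMu[mito] <- p$baselineMean * p$mitoMeanBoost
    baseMu[isTarget] <- p$corrTargetMean
    baseMu[c(posIdx, negIdx)] <- p$corrBlockMean

    sizeFac <- exp(stats::rnorm(C, 0, p$cellSizeSd))
    latent <- exp(stats::rnorm(C, 0, p$corrLatentSd))

    mu <- baseMu * foldMat[, match(tissue, p$tissueLabels)]
    mu <- sweep(mu, 2, sizeFac, `*`)
    mu[isTarget, ] <- mu[isTarget, ] * latent
    mu[posIdx, ] <- sweep(mu[posIdx, , drop = FALSE], 2, latent, `*`)
    mu[negIdx, ] <- sweep(mu[negIdx, , drop = FALSE], 2, latent, `/`)
    programPool <- setdiff(blockPool, c(posIdx, negIdx))
    for (ty in names(p$markerPanels)) {
      cols <- contaminant == ty
      program <- sample(programPool, min(p$contaminantProgramSize,
                                         length(programPool)))
      if (any(cols)) {
        mu[nm %in% p$markerPanels[[ty]], cols] <-
          mu[nm %in% p$markerPanels[[ty]], cols] * p$markerFold
        mu[program, cols] <- mu[program, cols] * p$contaminantProgramFold
      }
    }
    dying <- contaminant == "dying"
    if (any(dying))
      mu[mito, dying] <- mu[mito, dying] * p$dyingMitoBoost

    counts <- matrix(stats::rnbinom(G * C, mu = mu, size = 1 / p$nbDispersion),
                     G, C, dimnames = list(nm, sprintf("cell%05d", seq_len(C))))

    corrSign <- rep("none", G)
    corrSign[posIdx] <- "+"; corrSign[negIdx] <- "-"
    corrSign[isTarget] <- "target"
    geneTissue <- rep(NA_character_, G)
    geneTissue[tsIdx] <- tsTissue
    geneFold <- rep(NA_real_, G)
    geneFold[c(tsIdx, sharedIdx)] <- p$tsFold
    truth <- methods::new("TruthManifest",
      geneTruth = data.frame(
        gene_id = nm, tissue = geneTissue, fold = geneFold,
        shared_intestinal = seq_len(G) %in% sharedIdx,
        mito = mito, corr_sign = corrSign),
      peakTruth = data.frame(peak_id = character(), gene_id = character(),
                             region_class = character(), tissue = character(),
                             fold = numeric(), coupled = logical()),
      cellTruth = data.frame(cell_id = colnames(counts), tissue = tissue,
                             contaminant = contaminant))
    list(cells = CellCounts(counts, tissue = tissue,
                            mitoGenes = nm[mito]),
         truth = truth)
  })
}

# Deterministic per-gene peak placement (0-based block offsets chosen so
# that every peak's nearest TSS is its own gene and classes are unambiguous)
simPeakOffsets <- function(plus) {
  list(promoter = c(-200L, 199L),          # centered on the TSS
       intragenic = c(4501L, 4900L),       # mid-intron, outside both windows
       intergenic = if (plus) c(501L, 900L) else c(9101L, 9500L))
}

#' Generate replicate ATAC peak counts coupled to the planted genes
#'
#' Places up to one peak per gene per region class (promoter peak on the
#' TSS, intragenic peak mid-intron, intergenic peak 2.3 kb upstream-distal),
#' plants `coupledFold` accessibility effects on the non-promoter peaks of
#' planted genes in the same tissue(s) (promoter peaks join with probability
#' `promoterCoupling`), and draws NB counts per (peak, sample) with
#' log-normal sample library factors. Per-replicate peak sets drop each peak
#' independently at rate `peakDropout`, creating replicate-irreproducible
#' peaks for the genuine-peak filter.
#'
#' @param params a [simParams()] list.
#' @param ann the matching annotation.
#' @param truth the [TruthManifest-class] from [generateScRNA()].
#' @return `list(peaks = PeakExperiment, peaksets = named list
#'   (tissue -> list of replicate GRanges), truth = updated TruthManifest)`.
#' @export
generateATAC <- function(params, ann, truth) {
  withSeed(params$seed + 2L, {
    p <- params
    g <- ann@genes
    nm <- names(g)
    plus <- as.character(strand(g)) == "+"
    tss <- S4Vectors::mcols(g)$tss
    blockStart <- start(g) - 3001L  # 1-based block origin

    rows <- list()
    for (cls in names(p$peaksPerClass)) {
      f <- p$peaksPerClass[[cls]]
      if (f <= 0) next
      keep <- if (f >= 1) rep(TRUE, length(g))
              else (seq_along(g) %% round(1 / f)) == 0L
      for (i in which(keep)) {
        offs <- simPeakOffsets(plus[i])[[cls]]
        rng <- if (cls == "promoter") c(tss[i] + offs[1], tss[i] + offs[2])
               else c(blockStart[i] + offs[1], blockStart[i] + offs[2])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = as.character(seqnames(g))[i], start = rng[1], end = rng[2],
          gene_id = nm[i], region_class = cls,
          peak_id = paste(nm[i], cls, sep = "_"))
      }
    }
    tab <- do.call(rbind, rows)
    peaks <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
    names(peaks) <- tab$peak_id
    P <- length(peaks)

    gt <- geneTruth(truth)
    planted <- gt[!is.na(gt$fold), ]
    peakTissue <- rep(NA_character_, P)
    peakFold <- rep(NA_real_, P)
    coupled <- rep(FALSE, P)
    m <- match(tab$gene_id, planted$gene_id)
    hit <- !is.na(m)
    promo <- tab$region_class == "promoter"
    takes <- hit & (!promo | stats::rbinom(P, 1, p$promoterCoupling) == 1)
    peakTissue[takes] <- ifelse(planted$shared_intestinal[m[takes]],
                                "LI+SI", planted$tissue[m[takes]])
    peakFold[takes] <- p$coupledFold
    coupled[takes] <- TRUE

    sTissue <- rep(p$tissueLabels, each = p$atacReplicates)
    sRep <- rep(seq_len(p$atacReplicates), p$nTissues)
    S <- length(sTissue)
    lib <- exp(stats::rnorm(S, 0, p$atacLibSd))

    foldMat <- matrix(1, P, p$nTissues,
                      dimnames = list(names(peaks), p$tissueLabels))
    for (j in which(coupled)) {
      tset <- if (peakTissue[j] == "LI+SI") c("LI", "SI") else peakTissue[j]
      foldMat[j, tset] <- peakFold[j]
    }
    mu <- sweep(p$atacBaselineMean * foldMat[, match(sTissue, p$tissueLabels)],
                2, lib, `*`)
    counts <- matrix(stats::rnbinom(P * S, mu = mu,
                                    size = 1 / p$peakNbDispersion),
                     P, S, dimnames = list(names(peaks),
                                           paste(sTissue, sRep, sep = "_")))

    peaksets <- lapply(stats::setNames(p$tissueLabels, p$tissueLabels),
      function(tl) lapply(seq_len(p$atacReplicates), function(r) {
        drop <- stats::rbinom(P, 1, p$peakDropout) == 1
        gr <- peaks[!drop]
        S4Vectors::mcols(gr) <- NULL
        gr
      }))

    newTruth <- methods::new("TruthManifest",
      geneTruth = gt,
      peakTruth = data.frame(peak_id = names(peaks), gene_id = tab$gene_id,
                             region_class = tab$region_class,
                             tissue = peakTissue, fold = peakFold,
                             coupled = coupled),
      cellTruth = cellTruth(truth))
    list(peaks = PeakExperiment(counts, peaks, tissue = sTissue,
                                replicate = sRep),
         peaksets = peaksets, truth = newTruth)
  })
}

#' Simulate a full multi-tissue multi-omic dataset
#'
#' Convenience wrapper running [generateAnnotation()], [generateScRNA()] and
#' [generateATAC()] with one parameter set.
#'
#' @param params a [simParams()] list.
#' @return `list(annotation, cells, peaks, peaksets, truth)`.
#' @examples
#' sim <- simulateMultiome(simParams(nGenes = 60, cellsPerTissue = 30,
#'                                   tsGenesPerTissue = 2,
#'                                   sharedIntestinalGenes = 2, seed = 7))
#' sim$truth
#' @export
simulateMultiome <- function(params = simParams()) {
  ann <- generateAnnotation(params)
  rna <- generateScRNA(params, ann)
  atac <- generateATAC(params, ann, rna$truth)
  list(annotation = ann, cells = rna$cells, peaks = atac$peaks,
       peaksets = atac$peaksets, truth = atac$truth)
}
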