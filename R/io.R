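#' Read a BED file of peaks
#'
#' Reads a 3+ column tab-separated BED file (0-based, half-open) into a
#' `GRanges` (1-based, closed — the conversion happens here, at the I/O
#' boundary). Peak ids come from column 4 when present, otherwise they are
#' synthesized as `chrom:start-end` in BED coordinates.
#'
#' @param path path to a BED3/BED4 file.
#' @return A `GRanges` with unique names (peak ids), sorted by (chrom, start).
#' @export
readPeaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", which(nf < 3)[1], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("line ", bad[1], ": non-numeric coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("line ", bad[1], ": invalid interval (start >= end or start < 0)")
  ids <- ifelse(nf >= 4, vapply(fields, `[`, "", 4L),
                sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0)))
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  names(gr) <- ids
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (anyDuplicated(names(gr)))
    stop("duplicate peak ids in ", path)
  gr
}

#' Write peaks as BED4
#'
#' @param peaks a named `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   id = if (is.null(names(peaks)))
                     sprintf("peak%05d", seq_along(peaks)) else names(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count matrix (MatrixMarket triplet or TSV)
#'
#' For `format = "mtx"`, `path` is the `.mtx` file and the row/column name
#' sidecars default to `<path>.rownames` / `<path>.colnames` (one name per
#' line). For `format = "tsv"`, the file has a header of column names and
#' row names in the first column. Values must be non-negative integers;
#' violations are reported with their matrix coordinates.
#'
#' @param path input path.
#' @param format `"mtx"` or `"tsv"` (default: guessed from the extension).
#' @param rownamesPath,colnamesPath sidecar paths for MTX input.
#' @return An integer matrix (dense for TSV, `dgCMatrix` for MTX) with
#'   dimnames.
#' @export
readCountMatrix <- function(path, format = NULL,
                            rownamesPath = paste0(path, ".rownames"),
                            colnamesPath = paste0(path, ".colnames")) {
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    rn <- readLines(rownamesPath)
    cn <- readLines(colnamesPath)
    stopifnot(length(rn) == nrow(m), length(cn) == ncol(m))
    dimnames(m) <- list(rn, cn)
    m <- methods::as(m, "CsparseMatrix")
    bad <- which(m@x < 0 | m@x != round(m@x))
    if (length(bad)) {
      ij <- Matrix::summary(m)[bad[1], ]
      stop(sprintf("non-integer or negative count at (%d, %d)", ij$i, ij$j))
    }
    return(m)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at (%d, %d)",
                 bad[1, 1], bad[1, 2]))
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix (MatrixMarket triplet or TSV)
#'
#' Inverse of [readCountMatrix()]; MTX output writes the two name sidecars
#' next to the matrix file.
#'
#' @param m matrix with dimnames.
#' @inheritParams readCountMatrix
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(m, path, format = NULL,
                             rownamesPath = paste0(path, ".rownames"),
                             colnamesPath = paste0(path, ".colnames")) {
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), rownamesPath)
    writeLines(colnames(m), colnamesPath)
  } else {
    df <- data.frame(feature = rownames(m), as.data.frame(as.matrix(m)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GTF-lite gene annotation table
#'
#' The GTF-lite format is a TSV with header and columns `gene_id`, `chrom`,
#' `strand`, `start`, `end` (0-based half-open, BED-style), `exons`,
#' `utr5`, `utr3` (each a `;`-separated list of `start-end` blocks, 0-based
#' half-open, possibly empty), plus a `chromSizes` header comment line
#' `#chrom_sizes: chr1=1000,chr2=2000`.
#'
#' @param path input path.
#' @return A [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
  lines <- readLines(path)
  szline <- grep("^#chrom_sizes:", lines, value = TRUE)
  if (!length(szline)) stop("missing '#chrom_sizes:' header line")
  kv <- strsplit(strsplit(sub("^#chrom_sizes:\\s*", "", szline[1]),
                          ",")[[1]], "=")
  chromSizes <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                                vapply(kv, `[`, "", 1L))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, colClasses = "character")
  st <- as.integer(df$start); en <- as.integer(df$end)
  g <- GRanges(df$chrom, IRanges(st + 1L, en), strand = df$strand)
  names(g) <- df$gene_id
  S4Vectors::mcols(g)$tss <- ifelse(df$strand == "+", st + 1L, en)
  parseBlocks <- function(s, chrom) {
    if (is.na(s) || !nzchar(s)) return(GRanges())
    parts <- do.call(rbind, strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-"))
    GRanges(chrom, IRanges(as.integer(parts[, 1]) + 1L,
                           as.integer(parts[, 2])))
  }
  mk <- function(col) {
    grl <- GRangesList(lapply(seq_len(nrow(df)), function(i)
      parseBlocks(df[[col]][i], df$chrom[i])))
    names(grl) <- df$gene_id
    grl
  }
  GeneAnnotation(genes = g, exons = mk("exons"), utr5 = mk("utr5"),
                 utr3 = mk("utr3"), chromSizes = chromSizes)
}

#' Write a GeneAnnotation as GTF-lite
#'
#' @param ann a [GeneAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(ann, path) {
  g <- ann@genes
  fmtBlocks <- function(grl) {
    vapply(grl, function(gr) {
      if (!length(gr)) return("")
      paste(sprintf("%d-%d", start(gr) - 1L, end(gr)), collapse = ";")
    }, "")
  }
  blocks <- function(slot) {
    grl <- slot
    out <- stats::setNames(rep("", length(g)), names(g))
    if (length(grl)) out[names(grl)] <- fmtBlocks(grl)
    out
  }
  df <- data.frame(gene_id = names(g), chrom = as.character(seqnames(g)),
                   strand = as.character(strand(g)), start = start(g) - 1L,
                   end = end(g), exons = blocks(ann@exons),
                   utr5 = blocks(ann@utr5), utr3 = blocks(ann@utr3))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#chrom_sizes: %s",
                     paste(sprintf("%s=%d", names(ann@chromSizes),
                                   ann@chromSizes), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TruthManifest as JSON
#'
#' @param truth a [TruthManifest-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthManifest <- function(truth, path) {
  jsonlite::write_json(
    list(genes = geneTruth(truth), peaks = peakTruth(truth),
         cells = cellTruth(truth)),
    path, dataframe = "columns", na = "null")
  invisible(path)
}
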