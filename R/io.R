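#' Read a single-cell count matrix
#'
#' Reads a raw cells-by-genes count table from CSV/TSV (first column cell
#' identifiers, header row gene identifiers) or from a MatrixMarket
#' triplet (`*.mtx` with `genes.tsv` and `barcodes.tsv` companions, one
#' name per line, in the same directory). The result is a
#' [SingleCellExperiment::SingleCellExperiment] with a `counts` assay in
#' the usual genes-by-cells orientation.
#'
#' @param path file to read (`.csv`/`.tsv`, or the `.mtx` file of a
#'   triplet).
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; default guessed from
#'   the file extension.
#' @param mtxOrientation how the MTX file is stored: `"genes-cells"`
#'   (the 10x convention, default) or `"cells-genes"`.
#' @return a `SingleCellExperiment` with integer `counts`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("cell,g1,g2,g3", "c1,1,0,2", "c2,0,0,5"), f)
#' sce <- readCountMatrix(f)
#' dim(sce)  # 3 genes x 2 cells
#' @export
readCountMatrix <- function(path,
                            format = c("auto", "csv", "tsv", "mtx"),
                            mtxOrientation = c("genes-cells", "cells-genes")) {
  format <- match.arg(format)
  mtxOrientation <- match.arg(mtxOrientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    # header may carry one field per gene (cell ids become row names) or
    # an extra leading field naming the cell-id column
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    geneIds <- names(df)
    if (.rowNamesAreAutomatic(df)) {
      if (ncol(df) < 2L) stop("parse error in ", path, ": no gene columns found")
      cellIds <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
      geneIds <- geneIds[-1L]   # subsetting mangles duplicated names
    } else {
      cellIds <- rownames(df)
    }
    if (!all(vapply(df, is.numeric, logical(1)))) {
      bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
      stop("parse error in ", path, ": non-numeric entries in column '",
           geneIds[bad], "'")
    }
    m <- as.matrix(df)
    dimnames(m) <- list(cellIds, geneIds)
    counts <- t(m)  # store genes x cells
  } else {
    dir <- dirname(path)
    geneFile <- file.path(dir, "genes.tsv")
    cellFile <- file.path(dir, "barcodes.tsv")
    if (!file.exists(geneFile) || !file.exists(cellFile))
      stop("MTX companions genes.tsv / barcodes.tsv not found next to ", path)
    counts <- as.matrix(Matrix::readMM(path))
    genes <- readLines(geneFile)
    cells <- readLines(cellFile)
    if (mtxOrientation == "cells-genes") counts <- t(counts)
    if (nrow(counts) != length(genes) || ncol(counts) != length(cells))
      stop("MTX dimensions (", nrow(counts), " x ", ncol(counts),
           ") do not match companion files (", length(genes), " genes, ",
           length(cells), " cells) under orientation ", mtxOrientation)
    dimnames(counts) <- list(genes, cells)
  }
  .validateCounts(counts)
  storage.mode(counts) <- "integer"
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts)
  )
}

.rowNamesAreAutomatic <- function(df) {
  is.integer(attr(df, "row.names")) ||
    identical(rownames(df), as.character(seq_len(nrow(df))))
}

.validateCounts <- function(counts) {
  if (anyNA(counts)) stop("validation error: missing values in count matrix")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("validation error: negative count at gene '", rownames(counts)[idx[1L]],
         "', cell '", colnames(counts)[idx[2L]], "'")
  }
  if (any(counts != round(counts)))
    stop("validation error: non-integer counts present")
  if (anyDuplicated(rownames(counts)))
    stop("validation error: duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("validation error: duplicate cell identifiers")
  invisible(TRUE)
}

#' Write a count matrix to disk
#'
#' Inverse of [readCountMatrix()]: CSV/TSV as cells-by-genes with a
#' leading `cell` column, or a MatrixMarket triplet (genes-by-cells)
#' with `genes.tsv` / `barcodes.tsv` companions.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path output file; for `"mtx"` the `.mtx` file (companions are
#'   written alongside).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return invisibly, the path written.
#' @export
writeCountMatrix <- function(sce, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  counts <- SingleCellExperiment::counts(sce)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    m <- t(as.matrix(counts))  # cells x genes
    df <- data.frame(cell = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(counts), file.path(dirname(path), "barcodes.tsv"))
  }
  invisible(path)
}
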