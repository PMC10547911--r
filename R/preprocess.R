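#' Remove genes with no counts in any cell
#'
#' Genes whose total count over all cells is zero carry no information
#' and are dropped before normalization. Gene order and all cells are
#' preserved.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @return the input restricted to genes with positive total count.
#' @export
filterZeroGenes <- function(sce) {
  counts <- SingleCellExperiment::counts(sce)
  keep <- Matrix::rowSums(counts) > 0
  if (!any(keep)) stop("all genes have zero counts: empty feature space")
  sce[keep, ]
}

#' Library-size normalization and log2 transform
#'
#' Scales each cell's counts to a common library size and applies
#' `log2(x + 1)`. Adds two assays: `normcounts` (linear, library-size
#' scaled) and `logcounts` (its log2(x+1) transform).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param scale target library size; defaults to the median of the
#'   per-cell totals.
#' @return the input with `normcounts` and `logcounts` assays added.
#' @export
normalizeLog <- function(sce, scale = NULL) {
  counts <- SingleCellExperiment::counts(sce)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    stop("cells with zero total count cannot be normalized: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (is.null(scale)) scale <- stats::median(totals)
  if (scale <= 0) stop("scale must be positive")
  norm <- sweep(as.matrix(counts), 2L, scale / totals, "*")
  SummarizedExperiment::assay(sce, "normcounts") <- norm
  SummarizedExperiment::assay(sce, "logcounts") <- log2(norm + 1)
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic on the log expression:
#' per-gene dispersion (variance / mean) is z-scored within 20 bins of
#' mean expression, and the top `D` genes by z-score are kept. Genes
#' with zero variance rank strictly last. If the input has `D` genes or
#' fewer it is returned unchanged. Gene order of the input is preserved
#' in the output.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay (see
#'   [normalizeLog()]).
#' @param D number of highly variable genes to keep (default 2000).
#' @param nBins number of mean-expression bins (default 20).
#' @return the input restricted to the selected genes; the ranking
#'   statistic is recorded in `rowData(sce)$hvgScore`.
#' @export
selectHVG <- function(sce, D = 2000L, nBins = 20L) {
  if (D < 2L) stop("D must be >= 2")
  x <- SummarizedExperiment::assay(sce, "logcounts")
  nGenes <- nrow(x)
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  v <- (Matrix::rowSums(x * x) - n * mu^2) / (n - 1L)
  v <- pmax(v, 0)  # guard tiny negatives from cancellation
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = max(1L, min(nBins, nGenes)), include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::sd(d)
    if (length(d) < 2L || !is.finite(s) || s == 0) rep(0, length(d))
    else (d - mean(d)) / s
  })
  z[v == 0] <- -Inf  # invariant genes can never be "variable"
  SummarizedExperiment::rowData(sce)$hvgScore <- z
  if (nGenes <= D) return(sce)
  ord <- order(-z, -disp, seq_len(nGenes))
  keep <- sort(ord[seq_len(D)])
  sce[keep, ]
}

# cells x genes numeric matrix of the log expression, the orientation
# the search and clustering code works in
.exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    t(as.matrix(SummarizedExperiment::assay(x, "logcounts")))
  else as.matrix(x)
}
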