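#' Simulate a count matrix with planted cell clusters
#'
#' Generates an scRNA-seq-like raw count matrix with known structure:
#' cells are assigned round-robin to `kTrue` clusters; a chosen set of
#' informative genes receives cluster-specific negative-binomial means
#' `baseMean * 2^(effect * z)`, where each informative gene's offsets
#' `z` are a balanced, randomly permuted split of `+1/2` and `-1/2`
#' over the clusters (so the log2 fold separation between an "up" and a
#' "down" cluster is `effect`); the remaining noise genes share the
#' base mean in every cluster. Counts are drawn negative-binomial with
#' the given overdispersion and then thinned by Bernoulli dropout.
#'
#' The generator emulates the noise structure of UMI-style single-cell
#' counts at desk scale — negative-binomial overdispersion plus optional
#' technical dropout — for a panel of moderately expressed genes; it
#' does not model batch effects, trajectories, doublets, or the extreme
#' sparsity of a full (pre-HVG) gene panel.
#'
#' @param nCells,nGenes matrix dimensions (defaults 200 x 200).
#' @param kTrue number of planted clusters (default 2).
#' @param nInformative number of informative genes (default 20).
#' @param effect log2 fold separation on informative genes (default 2).
#' @param baseMean negative-binomial mean of a noise gene (default 20,
#'   a moderately expressed highly variable gene).
#' @param dispersion negative-binomial overdispersion; the NB size
#'   parameter is `1 / dispersion`, so variance is
#'   `mu + dispersion * mu^2` (default 0.1).
#' @param dropout probability that any entry is zeroed on top of the
#'   sampling zeros (default 0.01; droplet UMI counts are close to
#'   negative binomial with little extra zero inflation).
#' @param seed optional integer seed; the draw is fully reproducible.
#' @return a `SingleCellExperiment` with a `counts` assay,
#'   `colData(.)$trueLabel` (0-based planted cluster),
#'   `rowData(.)$informative`, and the generator parameters in
#'   `metadata(.)$simParams`.
#' @examples
#' sce <- simulateCounts(nCells = 60, nGenes = 40, seed = 1)
#' table(SummarizedExperiment::colData(sce)$trueLabel)
#' @export
simulateCounts <- function(nCells = 200L, nGenes = 200L, kTrue = 2L,
                           nInformative = 20L, effect = 2,
                           baseMean = 20, dispersion = 0.1,
                           dropout = 0.01, seed = NULL) {
  if (nInformative > nGenes) stop("nInformative exceeds nGenes")
  if (kTrue > nCells) stop("kTrue exceeds nCells")
  if (nCells < 2L * kTrue) stop("cluster sizes must be >= 2")
  if (effect < 0 || baseMean <= 0 || dispersion < 0)
    stop("effect must be >= 0, baseMean > 0, dispersion >= 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  labels <- rep_len(seq_len(kTrue) - 1L, nCells)
  geneIds <- sprintf("g%04d", seq_len(nGenes))
  cellIds <- sprintf("c%04d", seq_len(nCells))
  informative <- seq_len(nInformative)

  # balanced +-1/2 offsets per informative gene, permuted over clusters
  zBase <- rep(c(0.5, -0.5), length.out = kTrue)
  mu <- matrix(baseMean, nGenes, nCells)
  for (g in informative) {
    z <- sample(zBase)
    mu[g, ] <- baseMean * 2^(effect * z[labels + 1L])
  }

  size <- if (dispersion > 0) 1 / dispersion else Inf
  counts <- if (is.finite(size)) {
    matrix(stats::rnbinom(nGenes * nCells, mu = mu, size = size),
           nGenes, nCells)
  } else {
    matrix(stats::rpois(nGenes * nCells, lambda = mu), nGenes, nCells)
  }
  if (dropout > 0) {
    drop <- matrix(stats::rbinom(nGenes * nCells, 1L, dropout) == 1L,
                   nGenes, nCells)
    counts[drop] <- 0L
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(geneIds, cellIds)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(trueLabel = labels, row.names = cellIds),
    rowData = S4Vectors::DataFrame(
      informative = seq_len(nGenes) %in% informative, row.names = geneIds)
  )
  S4Vectors::metadata(sce)$simParams <- list(
    nCells = nCells, nGenes = nGenes, kTrue = kTrue,
    nInformative = nInformative, effect = effect, baseMean = baseMean,
    dispersion = dispersion, dropout = dropout, seed = seed
  )
  sce
}

#' Write a simulated fixture to disk
#'
#' Emits the count matrix (CSV or MatrixMarket triplet) plus
#' `labels.csv` (`cell_id,cluster`) when planted labels are present and
#' `informative_genes.txt` when the informative-gene flag is present.
#' [readCountMatrix()] round-trips the matrix exactly.
#'
#' @param sce a `SingleCellExperiment`, typically from
#'   [simulateCounts()].
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"mtx"`.
#' @return invisibly, the directory.
#' @export
writeFixture <- function(sce, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  matFile <- file.path(dir, if (format == "csv") "matrix.csv" else "matrix.mtx")
  writeCountMatrix(sce, matFile, format = format)
  cd <- SummarizedExperiment::colData(sce)
  if ("trueLabel" %in% names(cd))
    utils::write.csv(
      data.frame(cell_id = colnames(sce), cluster = cd$trueLabel),
      file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  rd <- SummarizedExperiment::rowData(sce)
  if ("informative" %in% names(rd))
    writeLines(rownames(sce)[rd$informative],
               file.path(dir, "informative_genes.txt"))
  invisible(dir)
}
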