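#' Result of one end-to-end clustering run
#'
#' @slot fit the [QSSAFit-class] from the gene-subset search.
#' @slot labels final 0-based cluster labels, named by cell id.
#' @slot kUsed number of clusters in the final partition.
#' @slot kMethod `"kmeans"` (K supplied) or `"louvain"` (K estimated).
#' @slot metrics a [ClusterEval-class], or `NULL` when no reference
#'   labels were supplied.
#' @slot seed the run seed.
#' @slot params resolved parameters sufficient to reproduce the run.
#' @export
setClass("ClusterRun",
  representation(fit = "QSSAFit", labels = "integer", kUsed = "integer",
                 kMethod = "character", metrics = "ANY", seed = "integer",
                 params = "list")
)

setMethod("show", "ClusterRun", function(object) {
  cat("ClusterRun:", length(object@labels), "cells in", object@kUsed,
      "clusters (", object@kMethod, "),",
      sum(object@fit@mask), "genes selected\n")
  if (!is.null(object@metrics)) print(object@metrics)
})

#' @describeIn ClusterRun-class final per-cell cluster labels.
#' @param object a `ClusterRun`.
#' @export
cellLabels <- function(object) object@labels

#' @describeIn ClusterRun-class the evaluation panel (or `NULL`).
#' @export
runMetrics <- function(object) object@metrics

#' Run the full feature-selection clustering pipeline
#'
#' Orchestrates the complete analysis: read the counts, drop all-zero
#' genes, library-size normalize and log2-transform, keep the top-D
#' highly variable genes, search for an optimal gene subset with the
#' quantum-bit squirrel search, then cluster the cells on the selected
#' genes — K-means when the number of clusters `K` is supplied, Louvain
#' community detection on a kNN graph otherwise. When reference labels
#' are available the final partition is scored with the six-metric
#' panel.
#'
#' When `K` is not supplied, the search itself still needs a cluster
#' count for its K-means fitness; it is estimated once up front by
#' Louvain on the full highly-variable-gene matrix.
#'
#' @param input a `SingleCellExperiment` with a `counts` assay, or a
#'   path readable by [readCountMatrix()].
#' @param format,mtxOrientation passed to [readCountMatrix()] when
#'   `input` is a path.
#' @param K number of clusters, or `NULL` to estimate it.
#' @param labels optional reference labels: a vector (one per cell) or
#'   a path to a `cell_id,cluster` CSV.
#' @param hvg number of highly variable genes to search over
#'   (default 2000).
#' @param control a [QSSAControl-class].
#' @param seed integer seed driving the entire run.
#' @param outDir optional directory; when given, the selected genes,
#'   labels, convergence trace, metrics and resolved configuration are
#'   written there as plain-text files.
#' @param verbose log stage-by-stage dimensions (default TRUE).
#' @return a [ClusterRun-class].
#' @export
runPipeline <- function(input, format = "auto", K = NULL, labels = NULL,
                        hvg = 2000L, control = qssaControl(), seed = NULL,
                        outDir = NULL, mtxOrientation = "genes-cells",
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  sce <- if (methods::is(input, "SummarizedExperiment")) input
         else readCountMatrix(input, format = format,
                              mtxOrientation = mtxOrientation)
  say("input: ", nrow(sce), " genes x ", ncol(sce), " cells")

  truth <- .resolveLabels(labels, colnames(sce))
  if (!is.null(seed)) set.seed(seed)

  sce <- filterZeroGenes(sce)
  say("after zero-gene filter: ", nrow(sce), " genes")
  sce <- normalizeLog(sce)
  sce <- selectHVG(sce, D = hvg)
  say("highly variable genes retained: ", nrow(sce))

  expr <- .exprMatrix(sce)
  kFit <- K
  if (is.null(kFit)) {
    est0 <- estimateKLouvain(expr, nNeighbors = min(control@nNeighbors,
                                                    nrow(expr) - 1L))
    kFit <- max(2L, est0$K)
    say("K estimated for the search fitness (Louvain, all HVGs): ", kFit)
  }

  fit <- runQSSA(expr, K = kFit, control = control, seed = NULL,
                 verbose = FALSE)
  say("search done: ", sum(fit@mask), " genes selected, fitness ",
      format(fit@fitness, digits = 5))

  if (!is.null(K)) {
    finalLabels <- kmeansMask(expr, fit@mask, K, control)
    kUsed <- as.integer(K)
    kMethod <- "kmeans"
  } else {
    est <- estimateKLouvain(expr, fit@mask,
                            nNeighbors = min(control@nNeighbors,
                                             nrow(expr) - 1L))
    finalLabels <- est$labels
    kUsed <- as.integer(est$K)
    kMethod <- "louvain"
  }
  names(finalLabels) <- rownames(expr)
  metrics <- if (!is.null(truth)) clusterMetrics(truth, finalLabels) else NULL

  run <- new("ClusterRun",
    fit = fit, labels = as.integer(finalLabels) |> stats::setNames(rownames(expr)),
    kUsed = kUsed, kMethod = kMethod, metrics = metrics,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    params = list(
      hvg = hvg, K = K, seed = seed, kFit = kFit,
      control = .controlAsList(control)
    )
  )
  if (!is.null(outDir)) .writeRunArtifacts(run, outDir)
  run
}

.resolveLabels <- function(labels, cellIds) {
  if (is.null(labels)) return(NULL)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    df <- utils::read.csv(labels, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "cluster") %in% names(df)))
      stop("labels file must have columns cell_id,cluster")
    idx <- match(cellIds, df$cell_id)
    if (anyNA(idx)) stop("labels file is missing some cells")
    return(df$cluster[idx])
  }
  if (length(labels) != length(cellIds))
    stop("labels length does not match the number of cells")
  labels
}

.controlAsList <- function(control) {
  nm <- methods::slotNames(control)
  stats::setNames(lapply(nm, function(s) methods::slot(control, s)), nm)
}

.writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(selectedGenes(run@fit), file.path(outDir, "selected_genes.txt"))
  utils::write.csv(
    data.frame(cell_id = names(run@labels), cluster = unname(run@labels)),
    file.path(outDir, "labels.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(run@fit@trace, file.path(outDir, "trace.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    fitness = run@fit@fitness, silhouette = run@fit@sc,
    nSelected = sum(run@fit@mask), kUsed = run@kUsed,
    kMethod = run@kMethod, seed = run@seed
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run@params, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(run@metrics)) {
    ev <- run@metrics
    jsonlite::write_json(
      c(as.list(ev@metrics), list(n = ev@n, K_true = ev@kTrue,
                                  K_pred = ev@kPred)),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(outDir)
}

#' Repeated pipeline runs with gene-selection frequency aggregation
#'
#' Because the search is stochastic, repeated runs from different seeds
#' yield different optimal gene subsets; genes that recur across many
#' runs are the reliable discriminative core. This driver runs
#' [runPipeline()] with consecutive seeds `baseSeed, baseSeed + 1, ...`
#' (each run an independent stream, so execution order is irrelevant)
#' and tallies, per gene, the number of runs whose best mask selected
#' it. Individual run failures are recorded with a warning and
#' excluded; if every run fails, an error is raised.
#'
#' @inheritParams runPipeline
#' @param nRuns number of repeated runs (>= 1).
#' @param baseSeed first seed of the consecutive block.
#' @param outDir optional directory; per-run artifacts go to
#'   `run_<seed>/` subdirectories and the aggregate to
#'   `frequency.csv`.
#' @return a list with `frequency` (data.frame `gene_id`, `count`,
#'   sorted as [topFrequentGenes()] sorts), `nRuns` (successful runs)
#'   and `runs` (the [ClusterRun-class] objects).
#' @export
runRepeats <- function(input, format = "auto", K = NULL, labels = NULL,
                       hvg = 2000L, control = qssaControl(),
                       nRuns = 20L, baseSeed = 1L, outDir = NULL,
                       verbose = FALSE) {
  if (nRuns < 1L) stop("nRuns must be >= 1")
  seeds <- baseSeed + seq_len(nRuns) - 1L
  runs <- list()
  for (s in seeds) {
    sub <- if (is.null(outDir)) NULL else file.path(outDir, paste0("run_", s))
    res <- tryCatch(
      runPipeline(input, format = format, K = K, labels = labels, hvg = hvg,
                  control = control, seed = s, outDir = sub,
                  verbose = verbose),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("run with seed ", s, " failed: ", conditionMessage(res))
    } else {
      runs[[as.character(s)]] <- res
    }
  }
  if (!length(runs)) stop("all ", nRuns, " runs failed")
  geneIds <- names(runs[[1L]]@fit@mask)
  count <- Reduce(`+`, lapply(runs, function(r) as.integer(r@fit@mask)))
  freq <- data.frame(gene_id = geneIds, count = count)
  freq <- freq[order(-freq$count, freq$gene_id), ]
  rownames(freq) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(freq, file.path(outDir, "frequency.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(frequency = freq, nRuns = length(runs), runs = runs)
}

#' Most frequently selected genes across repeated runs
#'
#' @param freq the `frequency` data.frame from [runRepeats()] (columns
#'   `gene_id`, `count`).
#' @param topN how many genes to return (default 50); if larger than
#'   the table, the full ranking is returned.
#' @return data.frame of the top genes, ordered by count descending
#'   with lexicographic gene-id tie-break.
#' @export
topFrequentGenes <- function(freq, topN = 50L) {
  ord <- order(-freq$count, freq$gene_id)
  out <- freq[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topN)
}
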