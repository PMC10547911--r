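#' K-means clustering on a masked gene subset
#'
#' Runs multi-start Lloyd/Hartigan-Wong K-means on the cells-by-genes
#' expression submatrix restricted to the selected genes. When the
#' submatrix has fewer distinct rows than `K` (e.g., all cells
#' identical on the subset) the distinct row groups are mapped onto the
#' available labels instead of calling `kmeans`, so the call always
#' terminates with valid labels.
#'
#' @param expr cells-by-genes numeric matrix, or a
#'   `SingleCellExperiment` with `logcounts`.
#' @param mask logical (or 0/1) vector over genes; at least one selected.
#' @param K number of clusters, `2 <= K <=` number of cells (K = 1 is
#'   accepted and trivially labels every cell 0).
#' @param control a [QSSAControl-class]; supplies the number of restarts
#'   and the Lloyd iteration cap.
#' @return integer vector of 0-based cluster labels, one per cell.
#' @export
kmeansMask <- function(expr, mask, K, control = qssaControl()) {
  x <- .exprMatrix(expr)
  mask <- .asMask(mask, ncol(x))
  if (!any(mask)) stop("empty gene mask: nothing to cluster on")
  if (K > nrow(x)) stop("K (", K, ") exceeds the number of cells (", nrow(x), ")")
  if (K < 1L) stop("K must be >= 1")
  sub <- x[, mask, drop = FALSE]
  if (K == 1L) return(rep.int(0L, nrow(sub)))
  key <- do.call(paste, c(as.data.frame(sub), sep = "\r"))
  nDistinct <- length(unique(key))
  if (nDistinct <= K) {
    # as many clusters as distinct rows (or fewer): label by row group,
    # folding onto the available labels; stats::kmeans needs K < n
    grp <- match(key, unique(key)) - 1L
    return(as.integer(grp %% K))
  }
  km <- suppressWarnings(
    stats::kmeans(sub, centers = K, nstart = control@kmNstart,
                  iter.max = control@kmIterMax)
  )
  as.integer(km$cluster - 1L)
}

.asMask <- function(mask, D) {
  if (length(mask) != D)
    stop("mask length (", length(mask), ") does not match gene count (", D, ")")
  if (is.numeric(mask)) mask <- mask != 0
  as.logical(mask)
}

#' Mean silhouette coefficient
#'
#' Mean over cells of `(b - a) / max(a, b)`, with `a` the mean distance
#' to the cell's own cluster and `b` the smallest mean distance to any
#' other cluster (Euclidean). Cells in singleton clusters contribute 0.
#'
#' @param x cells-by-features numeric matrix.
#' @param labels per-cell cluster labels; at least two distinct values.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouetteScore <- function(x, labels) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x))
    stop("labels length does not match the number of rows")
  f <- factor(labels)
  if (nlevels(f) < 2L)
    stop("silhouette is undefined for a single cluster")
  d <- as.matrix(stats::dist(x))
  sizes <- tabulate(f)
  sums <- rowsum(d, f)                       # cluster x cell distance sums
  li <- as.integer(f)
  idx <- cbind(li, seq_len(nrow(x)))
  a <- sums[idx] / pmax(sizes[li] - 1L, 1L)
  means <- sums / sizes                      # mean distance to each cluster
  means[idx] <- Inf                          # mask own cluster
  b <- apply(means, 2L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[li] == 1L] <- 0                    # singleton convention
  s[!is.finite(s)] <- 0                      # all-coincident degenerate pairs
  mean(s)
}

#' Fitness of a gene mask
#'
#' The search objective: `w * SC + (1 - w) * (1 - |S| / D)`, balancing
#' clustering quality (mean silhouette `SC` of the K-means labels on
#' the masked matrix) against subset size `|S|` out of `D` candidate
#' genes. An empty mask is inadmissible and receives `-Inf`; a
#' clustering that collapses onto a single distinct label is scored
#' with `SC = -1`.
#'
#' @inheritParams kmeansMask
#' @param D total number of candidate genes (defaults to the mask
#'   length).
#' @return a list with `value`, `sc`, `nSelected` and the 0-based
#'   `labels` used for scoring.
#' @export
maskFitness <- function(expr, mask, K, control = qssaControl(),
                        D = NULL) {
  x <- .exprMatrix(expr)
  mask <- .asMask(mask, ncol(x))
  if (is.null(D)) D <- length(mask)
  ns <- sum(mask)
  if (ns == 0L)
    return(list(value = -Inf, sc = NA_real_, nSelected = 0L,
                labels = integer()))
  labels <- kmeansMask(x, mask, K, control)
  sc <- if (length(unique(labels)) < 2L) -1
        else silhouetteScore(x[, mask, drop = FALSE], labels)
  w <- control@w
  list(value = w * sc + (1 - w) * (1 - ns / D),
       sc = sc, nSelected = as.integer(ns), labels = labels)
}

#' Estimate the number of clusters by Louvain community detection
#'
#' Builds an unweighted k-nearest-neighbour graph (Euclidean) on the
#' masked expression matrix and maximizes modularity with the Louvain
#' algorithm at resolution 1. Used for the final clustering when the
#' number of cell types is not known in advance.
#'
#' @inheritParams kmeansMask
#' @param mask optional gene mask; `NULL` uses all genes.
#' @param nNeighbors neighbourhood size (default 15); must be smaller
#'   than the number of cells.
#' @param resolution Louvain resolution parameter (default 1).
#' @return a list with `K` (number of communities) and 0-based `labels`.
#' @export
estimateKLouvain <- function(expr, mask = NULL, nNeighbors = 15L,
                             resolution = 1) {
  x <- .exprMatrix(expr)
  if (!is.null(mask)) {
    mask <- .asMask(mask, ncol(x))
    if (!any(mask)) stop("empty gene mask")
    x <- x[, mask, drop = FALSE]
  }
  n <- nrow(x)
  if (nNeighbors >= n)
    stop("nNeighbors (", nNeighbors, ") must be smaller than the number of cells (", n, ")")
  key <- do.call(paste, c(as.data.frame(x), sep = "\r"))
  if (length(unique(key)) == 1L)           # all cells identical: one community
    return(list(K = 1L, labels = rep.int(0L, n)))
  nn <- FNN::get.knn(x, k = nNeighbors)$nn.index
  edges <- cbind(rep(seq_len(n), times = nNeighbors), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm)) - 1L
  list(K = length(unique(labels)), labels = labels)
}
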