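#' Pairwise agreement counts between two partitions
#'
#' Over all unordered pairs of cells: `TP` pairs grouped together in
#' both partitions, `TN` separated in both, `FP` together only in the
#' prediction, `FN` together only in the reference. The four counts sum
#' to `choose(n, 2)`.
#'
#' @param truth,pred per-cell labels of equal length (any atomic type;
#'   labels are opaque categories).
#' @return named numeric vector `c(TP, FP, FN, TN)`.
#' @examples
#' pairCounts(c(0, 0, 1, 1), c(0, 0, 1, 2))
#' @export
pairCounts <- function(truth, pred) {
  lp <- .labelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  n <- lp$n
  TP <- sum(choose(tab, 2))
  sameU <- sum(choose(rowSums(tab), 2))
  sameV <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  c(TP = TP, FP = sameV - TP, FN = sameU - TP,
    TN = total - sameU - sameV + TP)
}

.labelPair <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors must have equal length")
  n <- length(truth)
  if (n < 2L) stop("need at least 2 cells to compare partitions")
  if (anyNA(truth) || anyNA(pred)) stop("labels must not contain NA")
  list(truth = as.factor(truth), pred = as.factor(pred), n = n)
}

#' Rand index
#'
#' Fraction of cell pairs on which the two partitions agree
#' (together-together or apart-apart).
#'
#' @inheritParams pairCounts
#' @return a value in \[0, 1\].
#' @export
randIndex <- function(truth, pred) {
  pc <- pairCounts(truth, pred)
  unname((pc["TP"] + pc["TN"]) / sum(pc))
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation model; 1 iff
#' the partitions are identical, ~0 for independent labelings.
#'
#' @inheritParams pairCounts
#' @return a value <= 1.
#' @export
adjustedRandIndex <- function(truth, pred) {
  lp <- .labelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(lp$n, 2)
  denom <- (sumA + sumB) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical structure
  (sumij - expected) / denom
}

# contingency-table entropies and mutual information, natural log
.miParts <- function(truth, pred) {
  lp <- .labelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  n <- lp$n
  pij <- tab / n
  pi. <- rowSums(pij)
  p.j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi., p.j)[nz]))
  hu <- -sum(pi.[pi. > 0] * log(pi.[pi. > 0]))
  hv <- -sum(p.j[p.j > 0] * log(p.j[p.j > 0]))
  list(tab = tab, n = n, mi = mi, hu = hu, hv = hv)
}

#' Normalized mutual information
#'
#' Mutual information between the partitions divided by the arithmetic
#' mean of their entropies.
#'
#' @inheritParams pairCounts
#' @return a value in \[0, 1\].
#' @export
nmiScore <- function(truth, pred) {
  p <- .miParts(truth, pred)
  if (p$hu + p$hv == 0) return(1)  # both single-cluster: identical partitions
  p$mi / ((p$hu + p$hv) / 2)
}

# exact expected mutual information under the hypergeometric
# (permutation) model, Vinh et al. style sum over feasible cell counts
.expectedMI <- function(tab, n) {
  a <- rowSums(tab)
  b <- colSums(tab)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      logp <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(logp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance: `(MI - E[MI]) / (mean
#' entropy - E[MI])` with the exact hypergeometric-model expectation of
#' MI (no sampling).
#'
#' @inheritParams pairCounts
#' @return a value <= 1 (0 expected for independent labelings).
#' @export
amiScore <- function(truth, pred) {
  p <- .miParts(truth, pred)
  if (p$hu == 0 && p$hv == 0) return(1)
  emi <- .expectedMI(p$tab, p$n)
  denom <- (p$hu + p$hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (p$mi - emi) / denom
}

#' Clustering accuracy
#'
#' Two conventions are provided. `"hungarian"` (default): the fraction
#' of cells correctly assigned under the cluster-to-class mapping that
#' maximizes agreement, found by optimal bipartite assignment on the
#' contingency table. `"pairwise"`: `(TP + TN) / choose(n, 2)` from the
#' pair counts, which is algebraically the Rand index.
#'
#' @inheritParams pairCounts
#' @param mode `"hungarian"` or `"pairwise"`.
#' @return a value in \[0, 1\].
#' @export
clusteringAccuracy <- function(truth, pred, mode = c("hungarian", "pairwise")) {
  mode <- match.arg(mode)
  if (mode == "pairwise") return(randIndex(truth, pred))
  lp <- .labelPair(truth, pred)
  tab <- unclass(table(lp$truth, lp$pred))
  flipped <- nrow(tab) > ncol(tab)
  if (flipped) tab <- t(tab)
  sol <- clue::solve_LSAP(tab, maximum = TRUE)
  matched <- sum(tab[cbind(seq_len(nrow(tab)), as.integer(sol))])
  matched / lp$n
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall:
#' `TP / sqrt((TP + FP) (TP + FN))`, with 0 when `TP = 0`.
#'
#' @inheritParams pairCounts
#' @return a value in \[0, 1\].
#' @export
fmIndex <- function(truth, pred) {
  pc <- pairCounts(truth, pred)
  if (pc["TP"] == 0) return(0)
  unname(pc["TP"] / sqrt((pc["TP"] + pc["FP"]) * (pc["TP"] + pc["FN"])))
}

#' Evaluate a predicted partition against a reference
#'
#' Computes the full six-metric panel (RI, ARI, NMI, AMI,
#' Hungarian-matched ACC, FMI).
#'
#' @inheritParams pairCounts
#' @return a [ClusterEval-class] object.
#' @examples
#' ev <- clusterMetrics(rep(1:2, each = 5), rep(c(2, 1), each = 5))
#' metricValues(ev)
#' @export
clusterMetrics <- function(truth, pred) {
  lp <- .labelPair(truth, pred)
  new("ClusterEval",
    metrics = c(
      ri = randIndex(truth, pred),
      ari = adjustedRandIndex(truth, pred),
      nmi = nmiScore(truth, pred),
      ami = amiScore(truth, pred),
      acc = clusteringAccuracy(truth, pred),
      fmi = fmIndex(truth, pred)
    ),
    n = lp$n,
    kTrue = nlevels(lp$truth),
    kPred = nlevels(lp$pred)
  )
}
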