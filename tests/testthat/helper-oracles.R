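# Independent brute-force oracles: pair enumeration and direct
# contingency arithmetic, deliberately naive (loops, factorials).
# They never call the package's own metric code.

oraclePairCounts <- function(u, v) {
  n <- length(u)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sameU <- u[i] == u[j]
      sameV <- v[i] == v[j]
      if (sameU && sameV) tp <- tp + 1
      else if (!sameU && !sameV) tn <- tn + 1
      else if (!sameU && sameV) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracleRI <- function(u, v) {
  pc <- oraclePairCounts(u, v)
  (pc["TP"] + pc["TN"]) / sum(pc)
}

oracleARI <- function(u, v) {
  pc <- oraclePairCounts(u, v)
  sameU <- pc["TP"] + pc["FN"]
  sameV <- pc["TP"] + pc["FP"]
  total <- sum(pc)
  e <- sameU * sameV / total
  denom <- (sameU + sameV) / 2 - e
  if (denom == 0) return(1)
  unname((pc["TP"] - e) / denom)
}

oracleFMI <- function(u, v) {
  pc <- oraclePairCounts(u, v)
  if (pc["TP"] == 0) return(0)
  unname(pc["TP"] / sqrt((pc["TP"] + pc["FP"]) * (pc["TP"] + pc["FN"])))
}

.oracleTab <- function(u, v) {
  lu <- unique(u)
  lv <- unique(v)
  tab <- matrix(0, length(lu), length(lv))
  for (i in seq_along(u))
    tab[match(u[i], lu), match(v[i], lv)] <- tab[match(u[i], lu), match(v[i], lv)] + 1
  tab
}

.oracleEntropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

oracleMI <- function(u, v) {
  tab <- .oracleTab(u, v)
  n <- length(u)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}

oracleNMI <- function(u, v) {
  tab <- .oracleTab(u, v)
  n <- length(u)
  hu <- .oracleEntropy(rowSums(tab), n)
  hv <- .oracleEntropy(colSums(tab), n)
  if (hu + hv == 0) return(1)
  oracleMI(u, v) / ((hu + hv) / 2)
}

# exact expected MI by explicit factorials; only valid for small n
oracleEMI <- function(u, v) {
  tab <- .oracleTab(u, v)
  n <- length(u)
  a <- rowSums(tab)
  b <- colSums(tab)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        p <- factorial(ai) * factorial(bj) * factorial(n - ai) *
          factorial(n - bj) /
          (factorial(n) * factorial(nij) * factorial(ai - nij) *
             factorial(bj - nij) * factorial(n - ai - bj + nij))
        emi <- emi + nij / n * log(n * nij / (ai * bj)) * p
      }
    }
  }
  emi
}

oracleAMI <- function(u, v) {
  tab <- .oracleTab(u, v)
  n <- length(u)
  hu <- .oracleEntropy(rowSums(tab), n)
  hv <- .oracleEntropy(colSums(tab), n)
  if (hu == 0 && hv == 0) return(1)
  emi <- oracleEMI(u, v)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (oracleMI(u, v) - emi) / denom
}

# matched accuracy by exhaustive enumeration of injective cluster maps
oracleHungarianACC <- function(u, v) {
  tab <- .oracleTab(u, v)
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  r <- nrow(tab)
  c <- ncol(tab)
  perms <- function(pool, k) {
    if (k == 0L) return(list(integer()))
    out <- list()
    for (i in seq_along(pool))
      for (rest in perms(pool[-i], k - 1L))
        out[[length(out) + 1L]] <- c(pool[i], rest)
    out
  }
  best <- 0
  for (p in perms(seq_len(c), r))
    best <- max(best, sum(tab[cbind(seq_len(r), p)]))
  best / length(u)
}

# naive per-point silhouette with explicit loops
oracleSilhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# cells x genes log-expression view of a SingleCellExperiment
.exprOf <- function(sce) {
  t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
}

# canonical form of a partition: index groups ordered by first member
.partitionOf <- function(u) {
  g <- split(seq_along(u), u)
  unname(g[order(vapply(g, min, 1L))])
}

randomLabelPair <- function(n, kMax = 4L) {
  list(u = sample.int(sample.int(kMax, 1L), n, replace = TRUE),
       v = sample.int(sample.int(kMax, 1L), n, replace = TRUE))
}

# two well-separated Gaussian blobs, cells x features
makeBlobs <- function(nPerBlob = 20L, nFeat = 5L, sep = 10, sd = 0.5) {
  x <- rbind(
    matrix(rnorm(nPerBlob * nFeat, 0, sd), nPerBlob),
    matrix(rnorm(nPerBlob * nFeat, sep, sd), nPerBlob)
  )
  list(x = x, labels = rep(0:1, each = nPerBlob))
}
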