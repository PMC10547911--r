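test_that("K-means on a masked submatrix separates clean blobs", {
  set.seed(1)
  b <- makeBlobs(nPerBlob = 15, nFeat = 6)
  # pad with 4 pure-noise features; mask selects only the blob features
  x <- cbind(b$x, matrix(rnorm(30 * 4, 5, 0.5), 30))
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  lab <- kmeansMask(x, mask, 2)
  expect_equal(adjustedRandIndex(b$labels, lab), 1)

  # K = n: every cell its own cluster
  small <- b$x[1:6, ]
  lab6 <- kmeansMask(small, rep(TRUE, 6), 6)
  expect_identical(sort(lab6), 0:5)

  # identical rows must terminate with valid labels
  same <- matrix(1, 8, 3)
  labSame <- kmeansMask(same, rep(TRUE, 3), 2)
  expect_identical(length(labSame), 8L)
  expect_true(all(labSame %in% 0:1))

  expect_error(kmeansMask(small, rep(TRUE, 6), 7), "exceeds the number of cells")
  expect_error(kmeansMask(small, rep(FALSE, 6), 2), "empty gene mask")
})

test_that("silhouette matches naive and library implementations", {
  set.seed(2)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 3), n)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(1, 2)
    expect_equal(silhouetteScore(x, labels), oracleSilhouette(x, labels),
                 tolerance = 1e-10)
    if (requireNamespace("cluster", quietly = TRUE) &&
        all(tabulate(factor(labels)) >= 1)) {
      sil <- cluster::silhouette(as.integer(factor(labels)), dist(x))
      expect_equal(silhouetteScore(x, labels), mean(sil[, "sil_width"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("silhouette behaves at the documented extremes", {
  # two tight far-apart pairs, correct labels
  x <- rbind(c(0, 0), c(0, 0.01), c(10, 10), c(10, 10.01))
  expect_gt(silhouetteScore(x, c(1, 1, 2, 2)), 0.9)
  # adversarial labels: one member of each pair per cluster
  expect_lt(silhouetteScore(x, c(1, 2, 1, 2)), 0)
  # duplicate points, one cluster per duplicate group: exactly 1
  dup <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_identical(silhouetteScore(dup, c(1, 1, 2, 2)), 1)
  expect_error(silhouetteScore(x, rep(1, 4)), "single cluster")
})

test_that("fitness combines silhouette and size penalty exactly", {
  sce <- simulateCounts(nCells = 60, nGenes = 30, nInformative = 8, seed = 9)
  expr <- t(as.matrix(SummarizedExperiment::assay(
    normalizeLog(filterZeroGenes(sce)), "logcounts")))
  D <- ncol(expr)
  w <- 0.9
  set.seed(20)
  for (i in 1:15) {
    mask <- runif(D) < runif(1, 0.1, 0.9)
    if (!any(mask)) mask[1] <- TRUE
    f <- maskFitness(expr, mask, K = 2)
    expect_equal(f$value, w * f$sc + (1 - w) * (1 - f$nSelected / D),
                 tolerance = 1e-12)
    expect_gte(f$value, -w)
    expect_lte(f$value, w + (1 - w) * (1 - 1 / D))
    expect_identical(f$nSelected, as.integer(sum(mask)))
  }
  # empty mask: sentinel worst value, never an error
  f0 <- maskFitness(expr, rep(FALSE, D), K = 2)
  expect_identical(f0$value, -Inf)
  expect_identical(f0$nSelected, 0L)
  # full mask: size term vanishes, fitness = w * SC
  fFull <- maskFitness(expr, rep(TRUE, D), K = 2)
  expect_equal(fFull$value, w * fFull$sc, tolerance = 1e-12)
})

test_that("fitness and silhouette are label-permutation invariant", {
  set.seed(3)
  b <- makeBlobs(nPerBlob = 10, nFeat = 4)
  s1 <- silhouetteScore(b$x, b$labels)
  s2 <- silhouetteScore(b$x, 1 - b$labels)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("size penalty is strictly monotone at fixed silhouette", {
  # duplicated informative columns keep the geometry (hence SC) similar
  # while the selected count grows; check the penalty term algebraically
  D <- 40
  w <- 0.9
  sc <- 0.5
  vals <- vapply(1:D, function(ns) w * sc + (1 - w) * (1 - ns / D), 1)
  expect_true(all(diff(vals) < 0))
})

test_that("Louvain K estimation finds separated blobs and degenerates sanely", {
  set.seed(4)
  b <- makeBlobs(nPerBlob = 50, nFeat = 8, sep = 12)
  est <- estimateKLouvain(b$x, nNeighbors = 15)
  expect_identical(est$K, 2L)
  expect_equal(adjustedRandIndex(b$labels, est$labels), 1)

  # identical cells: one community
  same <- matrix(2, 30, 4)
  est1 <- estimateKLouvain(same, nNeighbors = 5)
  expect_identical(est1$K, 1L)
  expect_identical(unique(est1$labels), 0L)

  # determinism under a fixed seed
  set.seed(11); a <- estimateKLouvain(b$x, nNeighbors = 10)
  set.seed(11); b2 <- estimateKLouvain(b$x, nNeighbors = 10)
  expect_identical(a, b2)

  expect_error(estimateKLouvain(b$x[1:10, ], nNeighbors = 10), "smaller than")
})
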