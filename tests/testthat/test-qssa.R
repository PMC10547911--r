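test_that("binarization follows the quantum-bit amplitude rule", {
  expect_identical(binarizeTheta(0), 0L)        # alpha = 1: excluded
  expect_identical(binarizeTheta(pi / 2), 1L)   # beta = 1: included
  expect_identical(binarizeTheta(pi / 4), 1L)   # boundary is inclusive
  th <- seq(0, pi / 2, length.out = 101)
  expect_identical(binarizeTheta(th), as.integer(cos(th)^2 - sin(th)^2 < 1e-9))
})

test_that("initial positions are uniform within bounds and reproducible", {
  ctrl <- qssaControl()
  set.seed(1); a <- initThetas(50, 30, ctrl)
  set.seed(1); b <- initThetas(50, 30, ctrl)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= pi / 2))
  # quantum-bit normalization holds identically for stored angles
  expect_true(all(abs(cos(a)^2 + sin(a)^2 - 1) < 1e-12))
  # degenerate bounds collapse every angle onto the bound
  dg <- qssaControl(thetaLow = 0.7, thetaHigh = 0.7)
  set.seed(2)
  expect_true(all(initThetas(10, 5, dg) == 0.7))
  expect_error(initThetas(10, 1, ctrl), "D must be >= 2")
})

test_that("glide update has the documented fixed point and limits", {
  noEscape <- qssaControl(Pdp = 0)
  src <- c(0.3, 0.8, 1.2)
  set.seed(3)
  expect_identical(glideUpdate(src, src, noEscape), src)  # fixed point
  # Pdp = 0: result always on the segment toward the target (clipped)
  tgt <- c(1.0, 0.2, 0.5)
  set.seed(4)
  for (i in 1:20) {
    out <- glideUpdate(src, tgt, noEscape)
    raw <- (out - src) / (tgt - src)  # implied dg * Gc per dimension
    expect_true(all(abs(raw - raw[1]) < 1e-12))  # one dg for all dims
    expect_true(all(raw >= 0.3 * 1.9 - 1e-12 & raw <= 0.7 * 1.9 + 1e-12))
  }
  # Pdp = 1: always a fresh uniform location, unrelated to source
  always <- qssaControl(Pdp = 1)
  set.seed(5)
  outs <- replicate(50, glideUpdate(src, src, always))
  expect_gt(stats::sd(outs), 0.2)
  expect_true(all(outs >= 0 & outs <= pi / 2))
})

test_that("seasonal constant and threshold behave as specified", {
  expect_identical(seasonalConstant(c(1, 2), c(1, 2)), 0)
  expect_equal(seasonalConstant(c(0.5, 0.5), c(0.2, 0.1)), 0.25,
               tolerance = 1e-12)
  set.seed(6)
  a <- runif(10); h <- runif(10)
  expect_gte(seasonalConstant(a, h), 0)

  expect_equal(sMin(1, 1e9), 1e-6, tolerance = 1e-6)  # exponent -> 0 limit
  expect_equal(sMin(100, 100), 1e-6 / 365^2.5, tolerance = 1e-18)
  s <- vapply(1:100, sMin, 1, tm = 100)
  expect_true(all(diff(s) < 0))  # strictly decreasing
  expect_error(sMin(1, 0), "tm must be positive")
})

test_that("Levy relocation is bounded, reproducible and heavy-tailed", {
  ctrl <- qssaControl()
  set.seed(7); a <- levyRelocate(1000, ctrl)
  set.seed(7); b <- levyRelocate(1000, ctrl)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= pi / 2))
  # unclipped Mantegna steps have far heavier tails than a Gaussian
  set.seed(8)
  steps <- squirrelClust:::.levyStep(1e5, 1.5)
  kurt <- mean((steps - mean(steps))^4) / stats::var(steps)^2
  expect_gt(kurt, 20)  # Gaussian kurtosis is 3
})

test_that("role assignment ranks by fitness with deterministic ties", {
  ctrl <- qssaControl(popSize = 10L)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0)
  roles <- assignRoles(vals, control = ctrl)
  expect_identical(roles[1], "hickory")
  expect_identical(roles[2:4], rep("acorn", 3))
  expect_identical(roles[5:10], rep("normal", 6))

  # ties broken by smaller subset, then original index
  tied <- assignRoles(rep(1, 10), nSelected = c(5L, 3L, rep(9L, 8L)),
                      control = ctrl)
  expect_identical(tied[2], "hickory")   # smallest subset wins
  expect_identical(tied[1], "acorn")
  expect_identical(tied[3:4], rep("acorn", 2))  # then stable index order

  # default population splits 1 / 3 / 46
  r50 <- assignRoles(runif(50))
  expect_identical(as.integer(table(r50)[c("hickory", "acorn", "normal")]),
                   c(1L, 3L, 46L))
  expect_error(assignRoles(c(1, NA, 1), control = ctrl), "evaluated fitness")
  expect_error(assignRoles(runif(5), control = ctrl), "popSize")
})

test_that("the search is elitist, deterministic and returns an admissible mask", {
  sce <- simulateCounts(nCells = 80, nGenes = 40, nInformative = 10, seed = 21)
  p <- normalizeLog(filterZeroGenes(sce))
  ctrl <- qssaControl(maxIter = 8L)
  fit1 <- runQSSA(p, K = 2, control = ctrl, seed = 99)
  fit2 <- runQSSA(p, K = 2, control = ctrl, seed = 99)
  expect_identical(bestMask(fit1), bestMask(fit2))
  expect_identical(convergenceTrace(fit1), convergenceTrace(fit2))
  expect_true(any(bestMask(fit1)))
  expect_true(all(diff(convergenceTrace(fit1)$bestFitness) >= 0))
  expect_identical(nrow(convergenceTrace(fit1)), 9L)  # init record + 8

  # a single-iteration run still records init + one update round
  one <- runQSSA(p, K = 2, control = qssaControl(maxIter = 1L), seed = 4)
  expect_identical(nrow(convergenceTrace(one)), 2L)
})

test_that("a pure size objective drives the mask toward the minimum", {
  ctrl <- qssaControl(maxIter = 100L)
  sizeObjective <- function(mask) 1 - sum(mask) / length(mask)
  x <- matrix(rnorm(20 * 30), 20, 30)  # data ignored by the objective
  for (s in 1:3) {
    fit <- runQSSA(x, control = ctrl, fitnessFun = sizeObjective, seed = s)
    tr <- convergenceTrace(fit)
    expect_true(all(diff(tr$nSelectedBest) <= 0))      # monotone shrink
    expect_lt(tr$nSelectedBest[nrow(tr)], tr$nSelectedBest[1])
    expect_identical(tr$nSelectedBest[nrow(tr)], sum(bestMask(fit)))
    expect_lte(sum(bestMask(fit)), 2L)                 # near the optimum of 1
    expect_gte(sum(bestMask(fit)), 1L)                 # never empty
  }
})

test_that("informative genes are enriched in the best mask (planted data)", {
  # fixture calibrated so the planted 10-gene block is the fitness
  # optimum at this scale (at effect 2 and 60 genes it is not: compact
  # noise splits score higher silhouette; see the methods vignette)
  sce <- simulateCounts(nCells = 200, nGenes = 60, nInformative = 10,
                        effect = 3, seed = 1)
  p <- normalizeLog(filterZeroGenes(sce))
  inf <- SummarizedExperiment::rowData(p)$informative
  fit <- runQSSA(p, K = 2, control = qssaControl(maxIter = 30L), seed = 1)
  m <- bestMask(fit)
  pHyp <- stats::phyper(sum(m & inf) - 1, sum(inf), sum(!inf), sum(m),
                        lower.tail = FALSE)
  expect_lt(pHyp, 0.01)
  expect_gt(sum(m & inf) / sum(m), sum(inf) / length(inf))
})

test_that("guided search outperforms pure random search (Pdp = 1)", {
  # with Pdp = 1 every move is a uniform redraw, so the search
  # degenerates to random search; under the size objective the guided
  # default must reach at least as small a best mask on average
  sizeObjective <- function(mask) 1 - sum(mask) / length(mask)
  x <- matrix(rnorm(15 * 30), 15, 30)
  ctrl <- qssaControl(maxIter = 30L)
  rand <- qssaControl(maxIter = 30L, Pdp = 1)
  guided <- vapply(1:20, function(s)
    bestFitness(runQSSA(x, control = ctrl, fitnessFun = sizeObjective,
                        seed = s)), 1)
  blind <- vapply(1:20, function(s)
    bestFitness(runQSSA(x, control = rand, fitnessFun = sizeObjective,
                        seed = 1000 + s)), 1)
  expect_gte(mean(guided), mean(blind))
})

test_that("an always-failing objective aborts with a diagnostic", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(
    runQSSA(x, fitnessFun = function(mask) stop("boom"),
            control = qssaControl(popSize = 6L, maxIter = 2L), seed = 1),
    "failed for every squirrel")
})
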