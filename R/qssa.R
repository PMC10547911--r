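#' Binarize quantum-bit angles into a gene mask
#'
#' Each gene's inclusion state is encoded by a quantum bit
#' `q = alpha|0> + beta|1>` with `alpha = cos(theta)`,
#' `beta = sin(theta)`; the gene is selected when the |1> amplitude
#' dominates, i.e. `|alpha|^2 <= |beta|^2`. Angles are maintained in
#' the first quadrant `[0, pi/2]`, where that condition is exactly
#' `theta >= pi/4` (inclusive at the boundary), which is how it is
#' evaluated so the representable `pi/4` maps to 1.
#'
#' @param theta numeric vector of angles in radians.
#' @return integer 0/1 vector of the same length.
#' @examples
#' binarizeTheta(c(0, pi / 4, pi / 2))
#' @export
binarizeTheta <- function(theta) {
  as.integer(theta >= pi / 4)
}

#' Initialize squirrel positions
#'
#' Draws a population of angle vectors uniformly within the angle
#' bounds, one squirrel per row.
#'
#' @param popSize number of squirrels.
#' @param D number of genes (dimensions); must be >= 2.
#' @param control a [QSSAControl-class] supplying the angle bounds.
#' @return `popSize` x `D` matrix of angles.
#' @export
initThetas <- function(popSize, D, control = qssaControl()) {
  if (D < 2L) stop("D must be >= 2")
  lo <- control@thetaLow
  hi <- control@thetaHigh
  matrix(lo + stats::runif(popSize * D) * (hi - lo), nrow = popSize)
}

.clipTheta <- function(theta, control) {
  pmin(pmax(theta, control@thetaLow), control@thetaHigh)
}

#' One gliding move of a squirrel
#'
#' With probability `1 - Pdp` (no predator) the squirrel glides from
#' its position toward the target position:
#' `source + dg * Gc * (target - source)` with a single random glide
#' distance `dg ~ U(dgLow, dgHigh)` shared across dimensions, clipped
#' into the angle bounds. With probability `Pdp` it flees to a uniform
#' random location instead.
#'
#' @param source,target angle vectors of equal length.
#' @param control a [QSSAControl-class].
#' @return the new angle vector.
#' @export
glideUpdate <- function(source, target, control = qssaControl()) {
  stopifnot(length(source) == length(target))
  if (stats::runif(1) >= control@Pdp) {
    dg <- stats::runif(1, control@dgLow, control@dgHigh)
    .clipTheta(source + dg * control@Gc * (target - source), control)
  } else {
    control@thetaLow +
      stats::runif(length(source)) * (control@thetaHigh - control@thetaLow)
  }
}

#' Seasonal constant
#'
#' Squared Euclidean distance between an acorn squirrel's position and
#' the hickory squirrel's position, summed over all dimensions. Small
#' values signal that the runners-up have converged onto the optimum.
#'
#' @param acorn,hickory angle vectors of equal length.
#' @return a non-negative scalar.
#' @export
seasonalConstant <- function(acorn, hickory) {
  stopifnot(length(acorn) == length(hickory))
  sum((acorn - hickory)^2)
}

#' Seasonal-monitoring threshold
#'
#' The decaying threshold `1e-6 / 365^(t / (tm / 2.5))` compared with
#' the seasonal constant; strictly decreasing in `t`, so relocation is
#' triggered more easily late in the run, shifting the balance from
#' exploitation back to exploration.
#'
#' @param t current iteration (1-based).
#' @param tm total number of iterations.
#' @return a positive scalar.
#' @export
sMin <- function(t, tm) {
  if (tm <= 0) stop("tm must be positive")
  1e-6 / 365^(t / (tm / 2.5))
}

#' Levy-flight relocation
#'
#' Draws a heavy-tailed random position used for winter migration of
#' normal-tree squirrels: `thetaLow + step * (thetaHigh - thetaLow)`
#' with the step from Mantegna's algorithm (stability index
#' `levyBeta`), clipped into the angle bounds.
#'
#' @param D number of dimensions.
#' @param control a [QSSAControl-class].
#' @return an angle vector of length `D` within the bounds.
#' @export
levyRelocate <- function(D, control = qssaControl()) {
  step <- .levyStep(D, control@levyBeta)
  .clipTheta(control@thetaLow + step * (control@thetaHigh - control@thetaLow),
             control)
}

# Mantegna step: u / |v|^(1/beta), u ~ N(0, sigma_u^2), v ~ N(0, 1)
.levyStep <- function(D, beta) {
  sigmaU <- (gamma(1 + beta) * sin(pi * beta / 2) /
               (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  stats::rnorm(D, sd = sigmaU) / abs(stats::rnorm(D))^(1 / beta)
}

# stable fitness ranking: best first, ties broken by smaller gene
# subset, then by original index
.rankSquirrels <- function(values, nSelected) {
  order(-values, nSelected, seq_along(values))
}

#' Assign tree roles from fitness
#'
#' Ranks the population by fitness (descending) and maps rank 1 to the
#' hickory tree, the next `nAcorn` ranks to acorn trees, and the rest
#' to normal trees. Ties are broken by smaller selected-gene count,
#' then by original index, so the assignment is deterministic.
#'
#' @param values per-squirrel fitness values (no `NA`: every squirrel
#'   must have been evaluated).
#' @param nSelected per-squirrel selected-gene counts (tie-break).
#' @param control a [QSSAControl-class]; its `popSize` must match.
#' @return character vector of roles (`"hickory"`, `"acorn"`,
#'   `"normal"`), one per squirrel, in the original order.
#' @export
assignRoles <- function(values, nSelected = integer(length(values)),
                        control = qssaControl()) {
  if (anyNA(values)) stop("every squirrel must have an evaluated fitness")
  if (length(values) != control@popSize)
    stop("length(values) must equal control popSize")
  ord <- .rankSquirrels(values, nSelected)
  roles <- character(length(values))
  roles[ord[1L]] <- "hickory"
  roles[ord[seq_len(control@nAcorn) + 1L]] <- "acorn"
  roles[ord[-seq_len(control@nAcorn + 1L)]] <- "normal"
  roles
}

#' Quantum-bit squirrel search over gene subsets
#'
#' The wrapper feature-selection loop. A population of squirrels, each
#' a vector of quantum-bit angles over the candidate genes, is ranked
#' by fitness into one hickory squirrel (the incumbent optimum), a band
#' of acorn squirrels and the remaining normal-tree squirrels. Each
#' iteration the acorn squirrels glide toward the hickory position, and
#' each normal squirrel glides either toward a random acorn squirrel or
#' directly toward the hickory position (an even random split); any
#' glide is replaced by a random relocation with predator probability
#' `Pdp`. If any acorn squirrel's squared distance to the hickory
#' position falls below the decaying seasonal threshold, all
#' normal-tree squirrels are relocated by Levy flight. Moved squirrels
#' are re-binarized and re-scored (cached when the mask is unchanged),
#' roles are re-assigned once per iteration, and the best-ever solution
#' is retained outside the population (elitism).
#'
#' @param x a `SingleCellExperiment` carrying `logcounts` (typically
#'   the highly-variable-gene matrix from [selectHVG()]) or a
#'   cells-by-genes numeric matrix.
#' @param K number of clusters used by the K-means fitness.
#' @param control a [QSSAControl-class].
#' @param fitnessFun optional objective: a function of a named logical
#'   mask returning either a numeric fitness or a list with at least
#'   `value` (see [maskFitness()], the default). Masks with no selected
#'   gene are never passed to it; they score `-Inf`.
#' @param seed optional integer seed; the whole run consumes a single
#'   seeded RNG stream, so identical inputs and seed reproduce the run
#'   exactly.
#' @param verbose print per-iteration progress.
#' @return a [QSSAFit-class] with the best mask, its fitness and
#'   silhouette, the labels that scored it, and the convergence trace.
#' @export
runQSSA <- function(x, K, control = qssaControl(), fitnessFun = NULL,
                    seed = NULL, verbose = FALSE) {
  expr <- .exprMatrix(x)
  D <- ncol(expr)
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(D))
  if (D < 2L) stop("need at least 2 candidate genes")
  if (!is.null(fitnessFun)) {
    rawFun <- fitnessFun
    fitnessFun <- function(mask) {
      res <- rawFun(mask)
      if (is.numeric(res)) res <- list(value = res)
      res
    }
  } else {
    if (missing(K)) stop("K is required with the default K-means fitness")
    if (K > nrow(expr)) stop("K exceeds the number of cells")
    fitnessFun <- function(mask) maskFitness(expr, mask, K, control, D = D)
  }
  if (!is.null(seed)) set.seed(seed)

  pop <- control@popSize
  nAcorn <- control@nAcorn
  tm <- control@maxIter

  thetas <- initThetas(pop, D, control)
  masks <- matrix(FALSE, pop, D)
  values <- rep.int(-Inf, pop)
  nSel <- integer(pop)
  info <- vector("list", pop)

  evalOne <- function(i) {
    m <- binarizeTheta(thetas[i, ]) == 1L
    if (identical(m, masks[i, ]) && !is.null(info[[i]])) return(NULL)
    masks[i, ] <<- m
    nSel[i] <<- sum(m)
    if (!any(m)) {
      values[i] <<- -Inf
      info[[i]] <<- list(value = -Inf, failed = FALSE)
      return(NULL)
    }
    res <- tryCatch(fitnessFun(stats::setNames(m, genes)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      values[i] <<- -Inf
      info[[i]] <<- list(value = -Inf, failed = TRUE, message = conditionMessage(res))
    } else {
      values[i] <<- res$value
      info[[i]] <<- c(res, failed = FALSE)
    }
    NULL
  }

  for (i in seq_len(pop)) evalOne(i)
  if (all(vapply(info, function(z) isTRUE(z$failed), logical(1))))
    stop("fitness evaluation failed for every squirrel; first error: ",
         info[[1L]]$message)

  best <- list(mask = NULL, value = -Inf, info = NULL)
  updateBest <- function() {
    ord <- .rankSquirrels(values, nSel)
    top <- ord[1L]
    if (values[top] > best$value ||
        (values[top] == best$value && is.finite(values[top]) &&
         nSel[top] < sum(best$mask))) {
      best <<- list(mask = masks[top, ], value = values[top],
                    info = info[[top]])
    }
    ord
  }
  ord <- updateBest()

  trace <- data.frame(iteration = 0L, bestFitness = best$value,
                      meanFitness = mean(values[is.finite(values)]),
                      nSelectedBest = sum(best$mask))

  for (t in seq_len(tm)) {
    hickory <- ord[1L]
    acorns <- ord[seq_len(nAcorn) + 1L]
    normals <- ord[-seq_len(nAcorn + 1L)]
    hTheta <- thetas[hickory, ]

    for (i in acorns)                                    # case 1
      thetas[i, ] <- glideUpdate(thetas[i, ], hTheta, control)
    for (i in normals) {
      if (stats::runif(1) < 0.5) {                       # case 2
        a <- acorns[sample.int(nAcorn, 1L)]
        thetas[i, ] <- glideUpdate(thetas[i, ], thetas[a, ], control)
      } else {                                           # case 3
        thetas[i, ] <- glideUpdate(thetas[i, ], hTheta, control)
      }
    }
    moved <- c(acorns, normals)

    sc <- vapply(acorns, function(i) seasonalConstant(thetas[i, ], hTheta),
                 numeric(1))
    if (any(sc < sMin(t, tm)))
      for (i in normals) thetas[i, ] <- levyRelocate(D, control)

    for (i in moved) evalOne(i)
    ord <- updateBest()

    trace <- rbind(trace, data.frame(
      iteration = t, bestFitness = best$value,
      meanFitness = mean(values[is.finite(values)]),
      nSelectedBest = sum(best$mask)
    ))
    if (verbose)
      message(sprintf("iter %3d: best %.5f (|S| = %d), mean %.5f",
                      t, best$value, sum(best$mask),
                      trace$meanFitness[nrow(trace)]))
  }

  if (!any(best$mask))
    stop("search never found an admissible (non-empty) gene mask")
  new("QSSAFit",
    mask = stats::setNames(best$mask, genes),
    fitness = best$value,
    sc = if (!is.null(best$info$sc)) best$info$sc else NA_real_,
    labels = if (!is.null(best$info$labels)) as.integer(best$info$labels)
             else integer(),
    trace = trace,
    control = control,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}
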