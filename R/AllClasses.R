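#' @import methods
#' @importFrom stats kmeans dist median rnbinom rbinom runif rnorm var setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Control parameters for the squirrel search
#'
#' Holds every tunable of the quantum-bit squirrel search: population
#' layout (one hickory squirrel at the current optimum, a small band of
#' acorn squirrels at the runners-up, the rest on normal trees), glide
#' dynamics, predator-escape probability, seasonal-monitoring decay,
#' Levy-flight exploration, the fitness weight, and the K-means settings
#' used inside the fitness evaluation.
#'
#' @slot popSize total number of squirrels (default 50).
#' @slot nAcorn number of acorn-tree squirrels (default 3); one squirrel
#'   is always on the hickory tree, the remaining `popSize - nAcorn - 1`
#'   on normal trees (46 at the defaults).
#' @slot maxIter number of search iterations (default 100).
#' @slot w fitness weight on clustering quality versus subset size
#'   (default 0.9).
#' @slot Pdp predator-presence probability: chance that a glide is
#'   replaced by a jump to a random location (default 0.1).
#' @slot Gc gliding constant scaling each glide step (default 1.9).
#' @slot dgLow,dgHigh bounds of the uniform random glide distance
#'   (defaults 0.3 and 0.7).
#' @slot thetaLow,thetaHigh angle bounds in radians; kept inside
#'   \[0, pi/2\] so cos(theta) and sin(theta) are valid non-negative
#'   quantum-bit amplitudes (defaults 0 and pi/2).
#' @slot levyBeta stability index of the Mantegna Levy step (default 1.5).
#' @slot kmNstart,kmIterMax restarts and Lloyd iterations for each
#'   K-means call inside the fitness (defaults 5 and 100).
#' @slot nNeighbors neighbourhood size of the kNN graph used by the
#'   Louvain K estimator (default 15).
#'
#' @seealso [qssaControl()] for the user-facing constructor.
#' @export
setClass("QSSAControl",
  representation(
    popSize = "integer", nAcorn = "integer", maxIter = "integer",
    w = "numeric", Pdp = "numeric", Gc = "numeric",
    dgLow = "numeric", dgHigh = "numeric",
    thetaLow = "numeric", thetaHigh = "numeric",
    levyBeta = "numeric", kmNstart = "integer", kmIterMax = "integer",
    nNeighbors = "integer"
  ),
  prototype(
    popSize = 50L, nAcorn = 3L, maxIter = 100L,
    w = 0.9, Pdp = 0.1, Gc = 1.9, dgLow = 0.3, dgHigh = 0.7,
    thetaLow = 0, thetaHigh = pi / 2, levyBeta = 1.5,
    kmNstart = 5L, kmIterMax = 100L, nNeighbors = 15L
  )
)

setValidity("QSSAControl", function(object) {
  msg <- character()
  if (object@popSize < object@nAcorn + 2L)
    msg <- c(msg, "popSize must allow 1 hickory, nAcorn acorn and >= 1 normal squirrel")
  if (object@nAcorn < 1L) msg <- c(msg, "nAcorn must be >= 1")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@w < 0 || object@w > 1) msg <- c(msg, "w must lie in [0, 1]")
  if (object@Pdp < 0 || object@Pdp > 1) msg <- c(msg, "Pdp must lie in [0, 1]")
  if (object@Gc <= 0) msg <- c(msg, "Gc must be positive")
  if (object@dgLow < 0 || object@dgLow > object@dgHigh)
    msg <- c(msg, "need 0 <= dgLow <= dgHigh")
  if (object@thetaLow < 0 || object@thetaHigh > pi / 2 ||
      object@thetaLow > object@thetaHigh)
    msg <- c(msg, "angle bounds must satisfy 0 <= thetaLow <= thetaHigh <= pi/2")
  if (object@levyBeta <= 0 || object@levyBeta >= 2)
    msg <- c(msg, "levyBeta must lie in (0, 2)")
  if (object@kmNstart < 1L || object@kmIterMax < 1L)
    msg <- c(msg, "kmNstart and kmIterMax must be >= 1")
  if (object@nNeighbors < 1L) msg <- c(msg, "nNeighbors must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct search control parameters
#'
#' @param popSize,nAcorn,maxIter,w,Pdp,Gc,dgLow,dgHigh,thetaLow,thetaHigh,levyBeta,kmNstart,kmIterMax,nNeighbors
#'   see the slot documentation of [QSSAControl-class].
#' @return a validated [QSSAControl-class] object.
#' @examples
#' qssaControl(maxIter = 30L)
#' @export
qssaControl <- function(popSize = 50L, nAcorn = 3L, maxIter = 100L,
                        w = 0.9, Pdp = 0.1, Gc = 1.9,
                        dgLow = 0.3, dgHigh = 0.7,
                        thetaLow = 0, thetaHigh = pi / 2,
                        levyBeta = 1.5, kmNstart = 5L, kmIterMax = 100L,
                        nNeighbors = 15L) {
  new("QSSAControl",
    popSize = as.integer(popSize), nAcorn = as.integer(nAcorn),
    maxIter = as.integer(maxIter), w = w, Pdp = Pdp, Gc = Gc,
    dgLow = dgLow, dgHigh = dgHigh,
    thetaLow = thetaLow, thetaHigh = thetaHigh, levyBeta = levyBeta,
    kmNstart = as.integer(kmNstart), kmIterMax = as.integer(kmIterMax),
    nNeighbors = as.integer(nNeighbors)
  )
}

setMethod("show", "QSSAControl", function(object) {
  cat("QSSAControl: pop", object@popSize,
      sprintf("(1 hickory / %d acorn / %d normal),", object@nAcorn,
              object@popSize - object@nAcorn - 1L),
      object@maxIter, "iterations\n")
  cat(sprintf("  w = %g, Pdp = %g, Gc = %g, dg in [%g, %g], theta in [%g, %g]\n",
              object@w, object@Pdp, object@Gc, object@dgLow, object@dgHigh,
              object@thetaLow, object@thetaHigh))
})

#' Result of a squirrel-search feature-selection run
#'
#' @slot mask named logical vector over the searched genes; `TRUE` marks
#'   a selected gene.
#' @slot fitness fitness of the best-ever gene subset.
#' @slot sc silhouette coefficient of the best subset's clustering.
#' @slot labels integer cluster labels (0-based) produced while scoring
#'   the best subset.
#' @slot trace per-iteration convergence record with columns
#'   `iteration`, `bestFitness`, `meanFitness`, `nSelectedBest`
#'   (iteration 0 is the state after initial evaluation).
#' @slot control the [QSSAControl-class] used.
#' @slot seed the seed the run was started from (NA if none given).
#' @export
setClass("QSSAFit",
  representation(
    mask = "logical", fitness = "numeric", sc = "numeric",
    labels = "integer", trace = "data.frame",
    control = "QSSAControl", seed = "integer"
  )
)

setValidity("QSSAFit", function(object) {
  msg <- character()
  if (!any(object@mask)) msg <- c(msg, "best mask must select at least one gene")
  if (is.null(names(object@mask))) msg <- c(msg, "mask must be named by gene id")
  tr <- object@trace
  need <- c("iteration", "bestFitness", "meanFitness", "nSelectedBest")
  if (!all(need %in% names(tr))) msg <- c(msg, "trace lacks required columns")
  else if (is.unsorted(tr$bestFitness)) msg <- c(msg, "elitist best fitness must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QSSAFit", function(object) {
  cat("QSSAFit:", sum(object@mask), "of", length(object@mask),
      "genes selected; fitness", format(object@fitness, digits = 5),
      "(silhouette", paste0(format(object@sc, digits = 4), ")"), "\n")
  cat("  ", nrow(object@trace) - 1L, "iterations, seed",
      object@seed, "\n")
})

#' @describeIn QSSAFit-class identifiers of the selected genes.
#' @param object,x a `QSSAFit`.
#' @export
selectedGenes <- function(object) names(object@mask)[object@mask]

#' @describeIn QSSAFit-class the best gene mask (named logical).
#' @export
bestMask <- function(object) object@mask

#' @describeIn QSSAFit-class the best fitness value.
#' @export
bestFitness <- function(object) object@fitness

#' @describeIn QSSAFit-class convergence trace as a data.frame.
#' @export
convergenceTrace <- function(object) object@trace

#' External clustering evaluation
#'
#' Six external validity indices comparing a predicted partition with a
#' reference partition: Rand index, adjusted Rand index, normalized and
#' adjusted mutual information, clustering accuracy (Hungarian-matched
#' by default) and the Fowlkes-Mallows index.
#'
#' @slot metrics named numeric vector with elements `ri`, `ari`, `nmi`,
#'   `ami`, `acc`, `fmi`.
#' @slot n number of cells compared.
#' @slot kTrue,kPred number of distinct reference / predicted clusters.
#' @export
setClass("ClusterEval",
  representation(metrics = "numeric", n = "integer",
                 kTrue = "integer", kPred = "integer")
)

setValidity("ClusterEval", function(object) {
  need <- c("ri", "ari", "nmi", "ami", "acc", "fmi")
  if (!identical(names(object@metrics), need))
    return("metrics must be named ri, ari, nmi, ami, acc, fmi")
  TRUE
})

setMethod("show", "ClusterEval", function(object) {
  cat("ClusterEval on", object@n, "cells (K true =", object@kTrue,
      ", K pred =", paste0(object@kPred, "):"), "\n")
  print(round(object@metrics, 4))
})

#' @describeIn ClusterEval-class extract the metrics as a named vector.
#' @param object a `ClusterEval`.
#' @export
metricValues <- function(object) object@metrics

#' @export
#' @method as.data.frame ClusterEval
as.data.frame.ClusterEval <- function(x, ...) {
  data.frame(t(x@metrics), n = x@n, kTrue = x@kTrue, kPred = x@kPred)
}
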