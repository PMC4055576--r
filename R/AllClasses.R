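#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t drop0
#' @importFrom stats runif rnorm setNames lm coef chisq.test pchisq sd
#' @importFrom utils read.table write.table head tail
#' @useDynLib multicontagion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Matrix Matrix
NULL

#' Single-layer contact network
#'
#' An undirected simple graph on \code{N} nodes, stored as a canonical sorted
#' edge matrix plus derived adjacency structures.  Nodes are indexed
#' \code{1..N} internally; \code{origIds} retains the identifiers found in an
#' input edge-list file (canonical graphs use \code{0..N-1}, the convention of
#' the plain-text edge-list format).
#'
#' @slot N integer, number of nodes (>= 1).
#' @slot edges two-column integer matrix of unordered node pairs, each row
#'   sorted, rows sorted lexicographically, no self-loops, no duplicates.
#' @slot adjacency sparse symmetric 0/1 adjacency matrix.
#' @slot neighbors list of integer vectors, \code{neighbors[[i]]} = nodes
#'   adjacent to \code{i}.
#' @slot origIds integer vector mapping internal index to original identifier.
#' @slot connected logical, whether the graph is connected.
#' @exportClass ContagionNetwork
setClass("ContagionNetwork",
  representation(N = "integer", edges = "matrix", adjacency = "Matrix",
                 neighbors = "list", origIds = "integer",
                 connected = "logical"))

setValidity("ContagionNetwork", function(object) {
  msg <- character()
  E <- object@edges
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (ncol(E) != 2L && nrow(E) > 0L) msg <- c(msg, "edges must have 2 columns")
  if (nrow(E) > 0L) {
    if (any(E[, 1] == E[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (any(E < 1L) || any(E > object@N)) msg <- c(msg, "edge endpoint out of range")
    key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(object@origIds) != object@N) msg <- c(msg, "origIds length != N")
  if (length(msg)) msg else TRUE
})

#' Multiplex contact network
#'
#' An ordered list of \linkS4class{ContagionNetwork} layers over one shared
#' node universe.  A node absent from a layer's edges simply has degree zero
#' there.
#'
#' @slot N integer, shared node count.
#' @slot layers list of \linkS4class{ContagionNetwork}, all with the same N.
#' @slot origIds integer vector of original node identifiers.
#' @exportClass MultiplexContagionNetwork
setClass("MultiplexContagionNetwork",
  representation(N = "integer", layers = "list", origIds = "integer"))

setValidity("MultiplexContagionNetwork", function(object) {
  msg <- character()
  if (length(object@layers) < 1L) msg <- c(msg, "need at least one layer")
  for (l in object@layers) {
    if (!is(l, "ContagionNetwork")) msg <- c(msg, "layers must be ContagionNetwork")
    else if (l@N != object@N) msg <- c(msg, "all layers must share one node count")
  }
  if (length(msg)) msg else TRUE
})

#' Contagion model parameters
#'
#' The parameter triple (Gamma, Delta, Theta) over \code{m} node states.
#' \code{gamma[k, l]} is the probability (or rate) that a node in state
#' \code{k} is successfully infected when contacted by a neighbor in state
#' \code{l}; \code{delta[k, l]} (k != l) the probability (or rate) of a
#' spontaneous transition k -> l, with probability-form diagonal
#' \code{delta[k, k] = 1 - sum(off-diagonal row k)}; \code{theta[k, r, l]}
#' the 0/1 indicator that exposure of a node in state \code{k} to a
#' transmitted state \code{r} makes it adopt state \code{l} (exactly one
#' \code{l} per \code{(k, r)}, default \code{l = r}).
#'
#' @slot states character vector of state labels (length m).
#' @slot gamma m x m numeric matrix of transmission parameters.
#' @slot delta m x m numeric matrix of spontaneous-transition parameters.
#' @slot theta m x m x m 0/1 array of adoption indicators.
#' @slot form "probability" or "rate".
#' @exportClass ContagionModel
setClass("ContagionModel",
  representation(states = "character", gamma = "matrix", delta = "matrix",
                 theta = "array", form = "character"))

setValidity("ContagionModel", function(object) {
  v <- validateModel(object)
  if (length(v)) v else TRUE
})

#' Multiplex contagion model
#'
#' As \linkS4class{ContagionModel}, but with one transmission matrix per
#' network layer: \code{gammaLayers[[a]][k, l]} applies to contacts on layer
#' \code{a}.  Spontaneous transitions and the stimulation tensor are
#' layer-independent.
#'
#' @slot gammaLayers list of m x m transmission matrices, one per layer.
#' @exportClass MultiplexContagionModel
setClass("MultiplexContagionModel",
  contains = "ContagionModel",
  representation(gammaLayers = "list"))

setValidity("MultiplexContagionModel", function(object) {
  v <- validateModel(object)
  if (length(v)) v else TRUE
})

#' Result of a one-step adoption computation
#'
#' For a receiving node in a fixed state: \code{q[l]} is the probability that
#' state \code{l} is the single adopted transmission, \code{qhat} the same
#' mass after redistribution through the Theta tensor, and \code{h} the
#' probability that no link became infectious.  For exact computations
#' \code{sum(q) + h == 1}.
#'
#' @slot q numeric length-m vector of raw adoption probabilities.
#' @slot qhat numeric length-m vector after Theta stimulation.
#' @slot h numeric scalar, no-adoption probability.
#' @exportClass AdoptionResult
setClass("AdoptionResult",
  representation(q = "numeric", qhat = "numeric", h = "numeric"))

#' One stochastic simulation run
#'
#' @slot seed integer seed used.
#' @slot steps integer number of steps T.
#' @slot states character state labels.
#' @slot fractions (T+1) x m matrix of per-step state fractions (row t+1 is
#'   the state after t steps); each row sums to 1.
#' @slot snapshots named list of full per-node state vectors at requested
#'   steps (names are the step numbers).
#' @exportClass SimulationRun
setClass("SimulationRun",
  representation(seed = "integer", steps = "integer", states = "character",
                 fractions = "matrix", snapshots = "list"))

#' Fixed-point iteration report
#'
#' @slot field final N x m probability field.
#' @slot fractions macroscopic state fractions (column means of the field).
#' @slot iterations number of iterations performed.
#' @slot converged logical; oscillatory systems report FALSE with a bounded
#'   residual rather than an error.
#' @slot residual final L-infinity step change.
#' @slot residualHistory tail of the residual sequence (for oscillation
#'   diagnosis).
#' @exportClass FixedPointReport
setClass("FixedPointReport",
  representation(field = "matrix", fractions = "numeric",
                 iterations = "integer", converged = "logical",
                 residual = "numeric", residualHistory = "numeric"))

setMethod("show", "ContagionNetwork", function(object) {
  cat(sprintf("ContagionNetwork: %d nodes, %d edges%s\n", object@N,
              nrow(object@edges),
              if (object@connected) "" else " (disconnected)"))
})

setMethod("show", "MultiplexContagionNetwork", function(object) {
  cat(sprintf("MultiplexContagionNetwork: %d nodes, %d layers (%s edges)\n",
              object@N, length(object@layers),
              paste(vapply(object@layers, function(l) nrow(l@edges), 1L),
                    collapse = "/")))
})

setMethod("show", "ContagionModel", function(object) {
  cat(sprintf("ContagionModel (%s form): %d states [%s]\n", object@form,
              length(object@states), paste(object@states, collapse = ", ")))
})

setMethod("show", "MultiplexContagionModel", function(object) {
  cat(sprintf("MultiplexContagionModel (%s form): %d states [%s], %d layers\n",
              object@form, length(object@states),
              paste(object@states, collapse = ", "),
              length(object@gammaLayers)))
})

setMethod("show", "AdoptionResult", function(object) {
  cat("AdoptionResult\n  q:   ", paste(signif(object@q, 6), collapse = " "),
      "\n  qhat:", paste(signif(object@qhat, 6), collapse = " "),
      "\n  h:   ", signif(object@h, 6), "\n")
})

setMethod("show", "SimulationRun", function(object) {
  cat(sprintf("SimulationRun: %d steps, %d states, seed %d\n",
              object@steps, length(object@states), object@seed))
})

setMethod("show", "FixedPointReport", function(object) {
  cat(sprintf("FixedPointReport: %s after %d iterations (residual %.3g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
  cat("  fractions:", paste(signif(object@fractions, 6), collapse = " "), "\n")
})
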