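# Deterministic discrete-time counterpart: the nonlinear dynamical system on
# per-node probability mass vectors, with exact and approximate adoption
# backends, and fixed-point iteration.

checkField <- function(P, model, network, tol = 1e-9) {
  P <- rbind(P)
  m <- length(model@states)
  if (nrow(P) != network@N || ncol(P) != m)
    stop("probability field must be N x m")
  if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol))
    stop("probability field rows must be nonnegative and sum to 1")
  unname(P)
}

#' Degenerate probability field from a state assignment
#'
#' @param assignment integer state indices (1..m).
#' @param model the model (defines m).
#' @return N x m 0/1 matrix with one 1 per row.
#' @export
fieldFromAssignment <- function(assignment, model) {
  m <- length(model@states)
  P <- matrix(0, length(assignment), m)
  P[cbind(seq_along(assignment), as.integer(assignment))] <- 1
  P
}

#' One deterministic (expected-value) step
#'
#' Evolves the N x m probability field by the three-term composition: mass
#' entering each state by spontaneous transition, mass entering by
#' contact-induced adoption given no spontaneous move, and mass staying put
#' (no spontaneous move, no infectious link).  Neighbor states are treated as
#' independent.  The \code{"exact"} backend evaluates the full
#' configuration-by-event sum (guarded, cost ~ m^k 2^k per node of degree k);
#' the \code{"approx"} backend is the closed-form approximation, with the
#' no-adoption probability still computed exactly.  Rows of the result sum
#' to 1.
#'
#' @param P N x m probability field (rows sum to 1).
#' @param model probability-form \linkS4class{ContagionModel} (multiplex
#'   models pair with multiplex networks; links from all layers compete in
#'   one uniform choice).
#' @param network the matching network.
#' @param backend \code{"approx"} or \code{"exact"}.
#' @param budget elementary-term budget for the exact backend.
#' @return the next N x m field.
#' @export
stepField <- function(P, model, network, backend = c("approx", "exact"),
                      budget = 1e7) {
  backend <- match.arg(backend)
  if (model@form != "probability")
    stop("the discrete-time solver requires a probability-form model; ",
         "use toProbabilities()")
  checkModelNetwork(model, network)
  P <- checkField(P, model, network)
  lk <- networkLinkLists(network)
  m <- length(model@states)
  cpp_step_field(P, lk$nbrs, lk$lays, gammaCube(model), model@delta,
                 thetaTargets(model), m, lk$L, backend == "exact", budget)
}

#' Per-node adoption probabilities for a whole field
#'
#' Returns, for every node and every hypothetical receiver state k, the
#' Theta-composed adoption probabilities \code{qhat[i, k, l]} and the exact
#' no-adoption probability \code{h[i, k]}.  This is the quantity the
#' deterministic step composes with the spontaneous mechanism; it is exposed
#' for one-step distribution checks.
#'
#' @inheritParams stepField
#' @return list with \code{qhat} (N x m x m array) and \code{h} (N x m).
#' @export
fieldAdoption <- function(P, model, network, backend = c("approx", "exact"),
                          budget = 1e7) {
  backend <- match.arg(backend)
  checkModelNetwork(model, network)
  P <- checkField(P, model, network)
  lk <- networkLinkLists(network)
  m <- length(model@states)
  cpp_adoption_field(P, lk$nbrs, lk$lays, gammaCube(model),
                     thetaTargets(model), m, lk$L, backend == "exact", budget)
}

#' Iterate the deterministic step to a fixed point
#'
#' Repeats \code{\link{stepField}} until the L-infinity step change drops
#' below \code{tol} or \code{maxIter} is reached.  Systems with sustained
#' oscillations do not converge; this is reported honestly via
#' \code{converged = FALSE} together with the tail of the residual history,
#' not raised as an error.
#'
#' @inheritParams stepField
#' @param tol convergence tolerance on the L-infinity step change.
#' @param maxIter iteration cap.
#' @return a \linkS4class{FixedPointReport}.
#' @export
iterateFixedPoint <- function(P, model, network,
                              backend = c("approx", "exact"),
                              tol = 1e-10, maxIter = 1e5, budget = 1e7) {
  backend <- match.arg(backend)
  if (model@form != "probability")
    stop("the discrete-time solver requires a probability-form model")
  checkModelNetwork(model, network)
  P <- checkField(P, model, network)
  lk <- networkLinkLists(network)
  m <- length(model@states)
  res <- cpp_iterate_fixed_point(P, lk$nbrs, lk$lays, gammaCube(model),
                                 model@delta, thetaTargets(model), m, lk$L,
                                 backend == "exact", budget, tol,
                                 as.integer(maxIter), 64L)
  field <- res$field
  colnames(field) <- model@states
  new("FixedPointReport", field = field,
      fractions = colMeans(field),
      iterations = as.integer(res$iterations),
      converged = res$converged, residual = res$residual,
      residualHistory = res$residualHistory)
}

#' Macroscopic state fractions of a field
#' @param P N x m probability field (or a \linkS4class{FixedPointReport}).
#' @return length-m vector of unweighted column means.
#' @export
macroFractions <- function(P) {
  if (is(P, "FixedPointReport")) return(P@fractions)
  colMeans(rbind(P))
}
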