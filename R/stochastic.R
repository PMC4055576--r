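# Discrete-time stochastic simulator: the synchronous reactive process.

# Pooled link structure shared by the simulator and the deterministic solver:
# per node, the neighbors over all layers together with each link's layer.
networkLinkLists <- function(network) {
  if (is(network, "MultiplexContagionNetwork")) {
    L <- length(network@layers)
    N <- network@N
    nbrs <- vector("list", N)
    lays <- vector("list", N)
    for (i in seq_len(N)) {
      nb <- integer()
      la <- integer()
      for (a in seq_len(L)) {
        nbA <- network@layers[[a]]@neighbors[[i]]
        nb <- c(nb, nbA)
        la <- c(la, rep(a, length(nbA)))
      }
      nbrs[[i]] <- nb
      lays[[i]] <- la
    }
    list(nbrs = nbrs, lays = lays, L = L)
  } else {
    list(nbrs = network@neighbors,
         lays = lapply(network@neighbors, function(nb) rep(1L, length(nb))),
         L = 1L)
  }
}

checkModelNetwork <- function(model, network) {
  mxModel <- is(model, "MultiplexContagionModel")
  mxNet <- is(network, "MultiplexContagionNetwork")
  if (mxModel != mxNet)
    stop("multiplex models require multiplex networks (and vice versa)")
  if (mxModel && length(model@gammaLayers) != length(network@layers))
    stop("model has ", length(model@gammaLayers), " transmission layers but ",
         "the network has ", length(network@layers))
  invisible(TRUE)
}

checkAssignment <- function(assignment, model, network) {
  m <- length(model@states)
  assignment <- as.integer(assignment)
  if (length(assignment) != network@N)
    stop("assignment length must equal the node count")
  if (any(assignment < 1L | assignment > m))
    stop("assignment entries must be state indices in 1..", m)
  assignment
}

#' Random 1-of-m state assignment
#'
#' @param network the network (defines the node count).
#' @param model the model (defines the states).
#' @param prob optional length-m sampling probabilities (default uniform).
#' @return integer vector of state indices, length N.
#' @export
randomStateAssignment <- function(network, model, prob = NULL) {
  m <- length(model@states)
  sample.int(m, network@N, replace = TRUE, prob = prob)
}

#' One synchronous stochastic step
#'
#' Every node is updated from the step-start assignment: first the
#' spontaneous loaded-dice draw from its row of Delta; only if that leaves
#' the state unchanged, every neighbor (on every layer) transmits its current
#' state independently with the layer's transmission probability, one
#' successful link is chosen uniformly at random, and the state dictated by
#' Theta is adopted.  Transmissions are directed: the link i <- j being
#' infectious is independent of j <- i.
#'
#' @param assignment integer state indices (1..m), length N.
#' @param model a probability-form \linkS4class{ContagionModel}.
#' @param network the matching network.
#' @return the next assignment.
#' @export
simulateStep <- function(assignment, model, network) {
  if (model@form != "probability")
    stop("the stochastic simulator requires a probability-form model; ",
         "use toProbabilities()")
  checkModelNetwork(model, network)
  assignment <- checkAssignment(assignment, model, network)
  lk <- networkLinkLists(network)
  m <- length(model@states)
  cpp_stoch_step(assignment, lk$nbrs, lk$lays, gammaCube(model),
                 model@delta, thetaTargets(model), m)
}

runInternal <- function(assignment, model, network, steps, lk,
                        snapshotSteps = integer(), method = "exact") {
  m <- length(model@states)
  gc <- gammaCube(model)
  tt <- thetaTargets(model)
  frac <- matrix(0, steps + 1L, m, dimnames = list(NULL, model@states))
  frac[1L, ] <- tabulate(assignment, m) / network@N
  snaps <- list()
  if (0L %in% snapshotSteps) snaps[["0"]] <- assignment
  for (t in seq_len(steps)) {
    assignment <- if (method == "approx")
      cpp_stoch_step_approx(assignment, lk$nbrs, lk$lays, gc,
                            model@delta, tt, m, lk$L)
    else
      cpp_stoch_step(assignment, lk$nbrs, lk$lays, gc,
                     model@delta, tt, m)
    frac[t + 1L, ] <- tabulate(assignment, m) / network@N
    if (t %in% snapshotSteps) snaps[[as.character(t)]] <- assignment
  }
  list(fractions = frac, snapshots = snaps, final = assignment)
}

#' Run the stochastic process for T steps
#'
#' @param assignment integer initial state indices (1..m).
#' @param model probability-form \linkS4class{ContagionModel}.
#' @param network the matching network.
#' @param steps number of steps T (>= 0).
#' @param seed optional integer seed (results are reproducible given the
#'   seed and inputs).
#' @param snapshotSteps integer steps at which to keep the full per-node
#'   state (0 = initial state).
#' @param method \code{"exact"} simulates every link event (the model
#'   itself); \code{"approx"} draws each node's next state from the
#'   closed-form approximate adoption distribution given its neighbors'
#'   states (the approximated version of the stochastic model).
#' @return a \linkS4class{SimulationRun}.
#' @export
simulateRun <- function(assignment, model, network, steps, seed = NULL,
                        snapshotSteps = integer(),
                        method = c("exact", "approx")) {
  method <- match.arg(method)
  if (model@form != "probability")
    stop("the stochastic simulator requires a probability-form model")
  checkModelNetwork(model, network)
  assignment <- checkAssignment(assignment, model, network)
  if (!is.null(seed)) set.seed(seed)
  lk <- networkLinkLists(network)
  res <- runInternal(assignment, model, network, as.integer(steps), lk,
                     as.integer(snapshotSteps), method)
  new("SimulationRun", seed = if (is.null(seed)) NA_integer_ else
        as.integer(seed),
      steps = as.integer(steps), states = model@states,
      fractions = res$fractions, snapshots = res$snapshots)
}

#' Per-step state fractions of a run
#' @param run a \linkS4class{SimulationRun}.
#' @return (T+1) x m matrix of fractions.
#' @export
runFractions <- function(run) run@fractions

#' Stored per-node snapshots of a run
#' @param run a \linkS4class{SimulationRun}.
#' @return named list of state vectors.
#' @export
runSnapshots <- function(run) run@snapshots

#' Ensemble of independent stochastic runs
#'
#' Runs \code{nRuns} independently seeded realisations from the same initial
#' assignment and returns the per-step mean and standard error of the state
#' fractions.
#'
#' @inheritParams simulateRun
#' @param nRuns number of realisations.
#' @param baseSeed integer; run r uses seed \code{baseSeed + r}.
#' @param method \code{"exact"} or \code{"approx"} (see
#'   \code{\link{simulateRun}}).
#' @return list with (T+1) x m matrices \code{mean} and \code{stderr}, plus
#'   \code{states} and \code{nRuns}.
#' @export
simulateEnsemble <- function(assignment, model, network, steps, nRuns,
                             baseSeed = 1L, method = c("exact", "approx")) {
  method <- match.arg(method)
  if (model@form != "probability")
    stop("the stochastic simulator requires a probability-form model")
  checkModelNetwork(model, network)
  assignment <- checkAssignment(assignment, model, network)
  lk <- networkLinkLists(network)
  m <- length(model@states)
  sum1 <- matrix(0, steps + 1L, m)
  sum2 <- matrix(0, steps + 1L, m)
  for (r in seq_len(nRuns)) {
    set.seed(baseSeed + r)
    fr <- runInternal(assignment, model, network, as.integer(steps), lk,
                      method = method)$fractions
    sum1 <- sum1 + fr
    sum2 <- sum2 + fr^2
  }
  mu <- sum1 / nRuns
  se <- if (nRuns > 1)
    sqrt(pmax((sum2 / nRuns - mu^2) * nRuns / (nRuns - 1), 0) / nRuns)
  else matrix(0, steps + 1L, m)
  colnames(mu) <- colnames(se) <- model@states
  list(mean = mu, stderr = se, states = model@states, nRuns = nRuns)
}
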