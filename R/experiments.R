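# Desk-scale computational experiments: approximation-vs-exact fixed-point
# scans for the two-contagion competition, stochastic-vs-deterministic
# trajectory comparisons, lattice snapshot runs, and the fixture generator.

#' Fixed-point error scan for the two-contagion competition
#'
#' Sweeps the two transmission probabilities (tau1, tau2) over a grid on
#' [0, 1]^2 and, for each cell, iterates both the approximate and the exact
#' deterministic backend to their macroscopic fixed points from the same
#' random initial state assignments.  The recorded error is the Euclidean
#' norm of the difference between the two macroscopic fraction vectors
#' (worst case over the initial assignments).  Off the tau1 = tau2 diagonal
#' the standard competition has a clear winner and both backends agree; on
#' the diagonal the approximation need not produce zero error.
#'
#' @param network a small network (the exact backend is guarded; degrees
#'   beyond ~8 exceed the default budget).
#' @param delta1,delta2 recovery parameters held fixed during the scan.
#' @param gridStep grid spacing for tau1 and tau2.
#' @param variant \code{"standard"} (spontaneous recovery) or
#'   \code{"contact_only"} (recovery by contacting susceptible neighbors).
#' @param nInits number of random initial state assignments per cell.
#' @param seed seed for the initial assignments.
#' @param tol,maxIter fixed-point iteration controls.
#' @param budget exact-backend term budget.
#' @return data frame with columns \code{tau1, tau2, error}, the exact-
#'   backend fixed-point fractions \code{S, I1, I2} (per-state maxima over
#'   the initial assignments, so a loser fraction below a threshold holds
#'   for every init), and \code{iterations} (max over backends and inits).
#' @export
scanCompetition <- function(network, delta1 = 0.2, delta2 = 0.2,
                            gridStep = 0.05,
                            variant = c("standard", "contact_only"),
                            nInits = 3, seed = 1,
                            tol = 1e-10, maxIter = 2e4, budget = 1e7) {
  variant <- match.arg(variant)
  taus <- seq(0, 1, by = gridStep)
  preset <- if (variant == "standard") presetSI1I2S else
    presetSI1I2SContactOnly
  set.seed(seed)
  template <- preset(0.5, 0.5, delta1, delta2)
  m <- length(template@states)
  # random assignments, redrawn until every state is represented: the
  # competition outcome is only informative when both contagions start out
  # present somewhere in the network
  inits <- lapply(seq_len(nInits), function(r) {
    repeat {
      a <- randomStateAssignment(network, template)
      if (length(unique(a)) == m) return(a)
    }
  })
  grid <- expand.grid(tau1 = taus, tau2 = taus)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    model <- preset(grid$tau1[g], grid$tau2[g], delta1, delta2)
    err <- 0
    iters <- 0L
    fracE <- numeric(3)
    for (init in inits) {
      P0 <- fieldFromAssignment(init, model)
      fpA <- iterateFixedPoint(P0, model, network, "approx", tol, maxIter)
      fpE <- iterateFixedPoint(P0, model, network, "exact", tol, maxIter,
                               budget)
      err <- max(err, sqrt(sum((fpA@fractions - fpE@fractions)^2)))
      iters <- max(iters, fpA@iterations, fpE@iterations)
      fracE <- pmax(fracE, fpE@fractions)
    }
    c(error = err, S = fracE[[1]], I1 = fracE[[2]], I2 = fracE[[3]],
      iterations = iters)
  })
  cbind(grid, do.call(rbind, res))
}

#' Ensemble-averaged stochastic vs approximated deterministic trajectories
#'
#' Runs \code{nRuns} independently seeded stochastic realisations from one
#' random initial assignment (the non-approximated model) and the
#' approximated deterministic solver from the matching degenerate field, and
#' compares the per-step macroscopic state fractions.
#'
#' @param network the network.
#' @param model probability-form \linkS4class{ContagionModel}.
#' @param nRuns number of stochastic realisations.
#' @param steps horizon T.
#' @param seed seed (initial assignment and run seeds derive from it).
#' @return list with \code{stochMean}, \code{stochStderr}, \code{det}
#'   ((T+1) x m matrices), \code{maxGap}, and \code{withinBand} (TRUE when
#'   every recorded fraction lies within 3 standard errors).
#' @export
compareStochasticDeterministic <- function(network, model, nRuns = 200,
                                           steps = 50, seed = 1) {
  set.seed(seed)
  init <- randomStateAssignment(network, model)
  ens <- simulateEnsemble(init, model, network, steps, nRuns,
                          baseSeed = seed)
  P <- fieldFromAssignment(init, model)
  m <- length(model@states)
  det <- matrix(0, steps + 1L, m, dimnames = list(NULL, model@states))
  det[1L, ] <- colMeans(P)
  for (t in seq_len(steps)) {
    P <- stepField(P, model, network, "approx")
    det[t + 1L, ] <- colMeans(P)
  }
  gap <- abs(ens$mean - det)
  band <- 3 * ens$stderr
  list(stochMean = ens$mean, stochStderr = ens$stderr, det = det,
       maxGap = max(gap), withinBand = all(gap <= pmax(band, 1e-12)),
       gapOverStderr = max(gap / pmax(ens$stderr, 1e-12)))
}

#' Approximated vs non-approximated stochastic ensembles
#'
#' The trajectory-level accuracy assessment for models where fixed-point
#' comparison is uninformative: \code{nRuns} realisations of the
#' non-approximated stochastic model (every link event simulated) and
#' \code{nRuns} realisations of its approximated version (each node samples
#' its next state from the closed-form adoption distribution) are averaged
#' from the same initial assignment, and the per-step macroscopic fractions
#' are compared within Monte-Carlo error of the difference.
#'
#' @param network the network.
#' @param model probability-form \linkS4class{ContagionModel}.
#' @param nRuns realisations per version.
#' @param steps horizon T.
#' @param seed seed (initial assignment and run seeds derive from it).
#' @return list with \code{exact}, \code{approx} (ensemble summaries),
#'   \code{maxGap}, \code{gapOverStderr} (max ratio of |difference| to its
#'   standard error) and \code{withinBand} (TRUE when every recorded
#'   fraction difference is within 3 standard errors).
#' @export
compareApproximationStochastic <- function(network, model, nRuns = 200,
                                           steps = 50, seed = 1) {
  set.seed(seed)
  init <- randomStateAssignment(network, model)
  ensE <- simulateEnsemble(init, model, network, steps, nRuns,
                           baseSeed = seed, method = "exact")
  ensA <- simulateEnsemble(init, model, network, steps, nRuns,
                           baseSeed = seed + nRuns, method = "approx")
  gap <- abs(ensE$mean - ensA$mean)
  seDiff <- sqrt(ensE$stderr^2 + ensA$stderr^2)
  list(exact = ensE, approx = ensA, maxGap = max(gap),
       gapOverStderr = max(gap / pmax(seDiff, 1e-12)),
       withinBand = all(gap <= pmax(3 * seDiff, 1e-12)))
}

#' Snapshot run of the stochastic process
#'
#' Runs the simulator keeping the full per-node state at the requested
#' steps; for periodic-lattice networks the snapshots can be indexed by
#' (row, col) for external visualisation.
#'
#' @param network the network.
#' @param model probability-form model.
#' @param steps horizon.
#' @param snapshotSteps steps at which to keep per-node states.
#' @param seed integer seed.
#' @param latticeDims optional c(rows, cols) to attach grid coordinates.
#' @return list with the \linkS4class{SimulationRun} and a list of snapshot
#'   data frames (node, state, and optionally row, col).
#' @export
snapshotRun <- function(network, model, steps, snapshotSteps, seed = 1,
                        latticeDims = NULL) {
  set.seed(seed)
  init <- randomStateAssignment(network, model)
  run <- simulateRun(init, model, network, steps, seed = seed,
                     snapshotSteps = snapshotSteps)
  frames <- lapply(run@snapshots, function(s) {
    df <- data.frame(node = seq_along(s) - 1L,
                     state = model@states[s])
    if (!is.null(latticeDims)) {
      df$row <- (df$node %% latticeDims[1])
      df$col <- (df$node %/% latticeDims[1])
    }
    df
  })
  list(run = run, frames = frames)
}

#' Generate the canned fixture set
#'
#' Writes a deterministic set of small graphs (complete, star and ring on 6
#' nodes, the 3 x 3 and 32 x 32 periodic lattices, a two-layer multiplex
#' toy), model configs (the presets plus the synthetic three-innovation
#' matrix), and three seeded random initial assignments per graph.
#' Regeneration with the same seed is idempotent.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the initial assignments.
#' @return the directory, invisibly.
#' @export
makeFixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graphs <- list(
    complete6 = makeGraph("complete", 6),
    star6 = makeGraph("star", 6),
    ring6 = makeGraph("ring", 6),
    lattice3x3 = makeGraph("lattice2d_periodic", rows = 3, cols = 3),
    lattice32x32 = makeGraph("lattice2d_periodic", rows = 32, cols = 32))
  for (nm in names(graphs))
    writeEdgeList(graphs[[nm]], file.path(dir, paste0(nm, ".edges")))
  mx <- makeMultiplex(list(makeGraph("ring", 6), makeGraph("star", 6)))
  writeEdgeList(mx, file.path(dir, "multiplex_toy.edges"))
  writeModelConfig(presetSIS(0.4, 0.2), file.path(dir, "sis.yaml"))
  writeModelConfig(presetSI1I2S(0.5, 0.4, 0.2, 0.2),
                   file.path(dir, "si1i2s.yaml"))
  writeModelConfig(presetMakiThompson(0.3, 0.2, 0.1),
                   file.path(dir, "maki_thompson.yaml"))
  writeModelConfig(presetThreeInnovations(),
                   file.path(dir, "three_innovations_synthetic.yaml"))
  set.seed(seed)
  model3 <- presetSI1I2S(0.5, 0.4, 0.2, 0.2)
  for (nm in names(graphs)) {
    inits <- vapply(1:3, function(r)
      randomStateAssignment(graphs[[nm]], model3), integer(graphs[[nm]]@N))
    write.table(inits, file.path(dir, paste0(nm, "_inits.csv")),
                row.names = FALSE, col.names = c("init1", "init2", "init3"),
                sep = ",", quote = FALSE)
  }
  invisible(dir)
}
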