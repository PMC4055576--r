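# Model parameter containers, validation, probability<->rate conversion and
# the preset model zoo.

identityTheta <- function(m) {
  th <- array(0, c(m, m, m))
  for (k in seq_len(m)) for (r in seq_len(m)) th[k, r, r] <- 1
  th
}

#' Construct a contagion model
#'
#' @param states character vector of state labels.
#' @param gamma m x m transmission matrix (row = receiver state, column =
#'   sender state).
#' @param delta m x m spontaneous-transition matrix.  In probability form the
#'   diagonal is filled automatically with \code{1 - sum(off-diagonal)} when
#'   left at zero; in rate form the diagonal must be zero.
#' @param theta either an m x m x m 0/1 array, or \code{NULL} for the identity
#'   tensor (exposure to state r adopts state r), or a data frame / matrix of
#'   sparse triplets with columns \code{k, r, l} (state labels or indices)
#'   overriding identity rows.
#' @param form \code{"probability"} (default) or \code{"rate"}.
#' @return a validated \linkS4class{ContagionModel}.
#' @export
contagionModel <- function(states, gamma, delta = NULL, theta = NULL,
                           form = c("probability", "rate")) {
  form <- match.arg(form)
  m <- length(states)
  gamma <- matrix(as.numeric(gamma), m, m,
                  dimnames = list(states, states))
  if (is.null(delta)) delta <- matrix(0, m, m)
  delta <- matrix(as.numeric(delta), m, m, dimnames = list(states, states))
  if (form == "probability") {
    off <- delta; diag(off) <- 0
    if (all(diag(delta) == 0)) diag(delta) <- 1 - rowSums(off)
  }
  theta <- buildTheta(theta, states)
  new("ContagionModel", states = states, gamma = gamma, delta = delta,
      theta = theta, form = form)
}

buildTheta <- function(theta, states) {
  m <- length(states)
  if (is.null(theta)) return(identityTheta(m))
  if (is.array(theta) && length(dim(theta)) == 3L) return(theta * 1)
  trip <- as.data.frame(theta)
  idx <- function(x) if (is.numeric(x)) as.integer(x) else match(x, states)
  th <- identityTheta(m)
  for (i in seq_len(nrow(trip))) {
    k <- idx(trip[[1]][i]); r <- idx(trip[[2]][i]); l <- idx(trip[[3]][i])
    th[k, r, ] <- 0
    th[k, r, l] <- 1
  }
  th
}

#' Validate a model specification
#'
#' Checks every structural invariant of the parameter triple and returns a
#' character vector of human-readable violations (empty when the model is
#' valid).  Never throws.
#'
#' @param model a \linkS4class{ContagionModel}.
#' @return character vector of violations.
#' @export
validateModel <- function(model) {
  v <- character()
  m <- length(model@states)
  if (m < 1L) v <- c(v, "need at least one state")
  for (slot in c("gamma", "delta")) {
    M <- slot(model, slot)
    if (!all(dim(M) == c(m, m)))
      v <- c(v, sprintf("%s must be %d x %d", slot, m, m))
  }
  if (length(v)) return(v)
  G <- model@gamma; D <- model@delta
  if (any(!is.finite(G)) || any(G < 0))
    v <- c(v, "gamma entries must be finite and >= 0")
  if (any(!is.finite(D)) || any(D - diag(diag(D)) < 0))
    v <- c(v, "off-diagonal delta entries must be finite and >= 0")
  if (model@form == "probability") {
    if (any(G > 1)) v <- c(v, "gamma entries must be <= 1 in probability form")
    off <- D; diag(off) <- 0
    if (any(rowSums(off) > 1 + 1e-12))
      v <- c(v, "off-diagonal delta row sums must be <= 1")
    if (any(abs(rowSums(D) - 1) > 1e-12))
      v <- c(v, "delta rows (including diagonal) must sum to 1")
  } else {
    if (any(diag(D) != 0)) v <- c(v, "rate-form delta diagonal must be 0")
  }
  th <- model@theta
  if (!all(dim(th) == c(m, m, m))) {
    v <- c(v, sprintf("theta must be %d x %d x %d", m, m, m))
  } else {
    if (!all(th %in% c(0, 1))) v <- c(v, "theta entries must be 0 or 1")
    s <- apply(th, c(1, 2), sum)
    if (any(s != 1))
      v <- c(v, "theta must have exactly one adopted state per (k, r) exposure")
  }
  if (is(model, "MultiplexContagionModel")) {
    for (a in seq_along(model@gammaLayers)) {
      Ga <- model@gammaLayers[[a]]
      if (!all(dim(Ga) == c(m, m)))
        v <- c(v, sprintf("layer %d gamma must be %d x %d", a, m, m))
      else if (any(!is.finite(Ga)) || any(Ga < 0) ||
               (model@form == "probability" && any(Ga > 1)))
        v <- c(v, sprintf("layer %d gamma entries out of range", a))
    }
  }
  v
}

#' Number of model states
#' @param model a \linkS4class{ContagionModel}.
#' @return integer m.
#' @export
numStates <- function(model) length(model@states)

#' State labels
#' @param model a \linkS4class{ContagionModel}.
#' @return character vector of labels.
#' @export
stateLabels <- function(model) model@states

#' Transmission matrix
#' @param model a \linkS4class{ContagionModel}.
#' @param layer optional layer index for multiplex models.
#' @return the m x m transmission matrix.
#' @export
transmissionMatrix <- function(model, layer = NULL) {
  if (is(model, "MultiplexContagionModel") && !is.null(layer))
    model@gammaLayers[[layer]] else model@gamma
}

#' Spontaneous-transition matrix
#' @param model a \linkS4class{ContagionModel}.
#' @return the m x m spontaneous matrix.
#' @export
spontaneousMatrix <- function(model) model@delta

#' Stimulation tensor
#' @param model a \linkS4class{ContagionModel}.
#' @return the m x m x m 0/1 array.
#' @export
stimulationTensor <- function(model) model@theta

# target[k, r] = the state adopted by a node in state k exposed to state r
thetaTargets <- function(model) {
  m <- length(model@states)
  t(vapply(seq_len(m),
           function(k) apply(model@theta[k, , , drop = FALSE][1, , ], 1,
                             which.max),
           integer(m)))
}

gammaCube <- function(model) {
  m <- length(model@states)
  if (is(model, "MultiplexContagionModel")) {
    L <- length(model@gammaLayers)
    array(unlist(model@gammaLayers), c(m, m, L))
  } else {
    array(model@gamma, c(m, m, 1))
  }
}

#' Convert a probability-form model to rates
#'
#' Each probability parameter is divided by the time-step length \code{dt}
#' (the probability of an event in a step of length dt being rate * dt).
#'
#' @param model a probability-form \linkS4class{ContagionModel}.
#' @param dt time step length (> 0).
#' @return the corresponding rate-form model.
#' @export
toRates <- function(model, dt) {
  stopifnot(dt > 0)
  if (model@form != "probability") stop("model is already in rate form")
  out <- model
  out@gamma <- model@gamma / dt
  D <- model@delta / dt
  diag(D) <- 0
  out@delta <- D
  if (is(model, "MultiplexContagionModel"))
    out@gammaLayers <- lapply(model@gammaLayers, function(G) G / dt)
  out@form <- "rate"
  validObject(out)
  out
}

#' Convert a rate-form model to step probabilities
#'
#' Multiplies every rate by \code{dt}; rejects any conversion that would
#' produce a probability above 1 (naming the offending entry).
#'
#' @param model a rate-form \linkS4class{ContagionModel}.
#' @param dt time step length (> 0).
#' @return the corresponding probability-form model.
#' @export
toProbabilities <- function(model, dt) {
  stopifnot(dt > 0)
  if (model@form != "rate") stop("model is already in probability form")
  checkMat <- function(M, what) {
    P <- M * dt
    if (any(P > 1)) {
      bad <- which(P > 1, arr.ind = TRUE)[1, ]
      stop(sprintf("%s[%s, %s] * dt = %.4g exceeds 1; use a smaller dt",
                   what, model@states[bad[1]], model@states[bad[2]],
                   P[bad[1], bad[2]]))
    }
    P
  }
  out <- model
  out@gamma <- checkMat(model@gamma, "gamma")
  D <- checkMat(model@delta, "delta")
  if (any(rowSums(D) > 1))
    stop("delta row sum * dt exceeds 1; use a smaller dt")
  diag(D) <- 1 - rowSums(D)
  out@delta <- D
  if (is(model, "MultiplexContagionModel"))
    out@gammaLayers <- lapply(seq_along(model@gammaLayers), function(a)
      checkMat(model@gammaLayers[[a]], sprintf("gamma layer %d", a)))
  out@form <- "probability"
  validObject(out)
  out
}

#' SIS preset
#'
#' Two states (S, I); susceptible nodes are infected by infected neighbors
#' with probability \code{beta}, infected nodes recover spontaneously with
#' probability \code{delta}.
#'
#' @param beta transmission probability.
#' @param delta spontaneous recovery probability.
#' @param form "probability" or "rate".
#' @return a \linkS4class{ContagionModel}.
#' @export
presetSIS <- function(beta, delta, form = "probability") {
  G <- matrix(0, 2, 2); G[1, 2] <- beta
  D <- matrix(0, 2, 2); D[2, 1] <- delta
  contagionModel(c("S", "I"), G, D, form = form)
}

#' SIR preset
#'
#' Three states (S, I, R); infection as in SIS, but recovery confers permanent
#' immunity (spontaneous I -> R, no exit from R).
#'
#' @inheritParams presetSIS
#' @return a \linkS4class{ContagionModel}.
#' @export
presetSIR <- function(beta, delta, form = "probability") {
  G <- matrix(0, 3, 3); G[1, 2] <- beta
  D <- matrix(0, 3, 3); D[2, 3] <- delta
  contagionModel(c("S", "I", "R"), G, D, form = form)
}

#' SIRS preset
#'
#' As SIR, plus loss of immunity: a spontaneous R -> S transition with
#' probability \code{xi}.
#'
#' @inheritParams presetSIS
#' @param xi immunity-loss probability.
#' @return a \linkS4class{ContagionModel}.
#' @export
presetSIRS <- function(beta, delta, xi, form = "probability") {
  G <- matrix(0, 3, 3); G[1, 2] <- beta
  D <- matrix(0, 3, 3); D[2, 3] <- delta; D[3, 1] <- xi
  contagionModel(c("S", "I", "R"), G, D, form = form)
}

#' Maki-Thompson rumor model preset (with forgetting)
#'
#' Three states: ignorant (I), spreader (S), stifler (R).  An ignorant
#' contacting a spreader becomes a spreader (lambda).  A spreader contacting a
#' spreader or a stifler becomes a stifler (alpha) -- exposure to the S state
#' stimulates adoption of R via the Theta tensor.  Spreaders also forget
#' spontaneously with probability \code{sigma}; \code{sigma = 0} recovers the
#' original model.
#'
#' @param lambda spreading parameter.
#' @param alpha stifling parameter.
#' @param sigma spontaneous forgetting parameter.
#' @param form "probability" or "rate".
#' @return a \linkS4class{ContagionModel}.
#' @export
presetMakiThompson <- function(lambda, alpha, sigma = 0, form = "probability") {
  st <- c("I", "S", "R")
  G <- matrix(0, 3, 3, dimnames = list(st, st))
  G["I", "S"] <- lambda
  G["S", "S"] <- alpha
  G["S", "R"] <- alpha
  D <- matrix(0, 3, 3, dimnames = list(st, st))
  D["S", "R"] <- sigma
  theta <- data.frame(k = "S", r = "S", l = "R")
  contagionModel(st, G, D, theta = theta, form = form)
}

#' Two-contagion competition preset
#'
#' Three states (S, I1, I2): two SIS-type contagions compete for susceptible
#' nodes with transmission probabilities \code{beta1}, \code{beta2} and
#' spontaneous recovery probabilities \code{delta1}, \code{delta2}.
#'
#' @param beta1,beta2 transmission probabilities of the two contagions.
#' @param delta1,delta2 spontaneous recovery probabilities.
#' @param form "probability" or "rate".
#' @return a \linkS4class{ContagionModel}.
#' @export
presetSI1I2S <- function(beta1, beta2, delta1, delta2, form = "probability") {
  st <- c("S", "I1", "I2")
  G <- matrix(0, 3, 3, dimnames = list(st, st))
  G["S", "I1"] <- beta1
  G["S", "I2"] <- beta2
  D <- matrix(0, 3, 3, dimnames = list(st, st))
  D["I1", "S"] <- delta1
  D["I2", "S"] <- delta2
  contagionModel(st, G, D, form = form)
}

#' Contact-only two-contagion competition preset
#'
#' The competition model with the spontaneous recoveries replaced by
#' contact-induced ones: an infected node reverts to S by contacting
#' susceptible neighbors (with probability \code{delta1} or \code{delta2}).
#' The spontaneous matrix is the identity.
#'
#' @inheritParams presetSI1I2S
#' @return a \linkS4class{ContagionModel}.
#' @export
presetSI1I2SContactOnly <- function(beta1, beta2, delta1, delta2,
                                    form = "probability") {
  st <- c("S", "I1", "I2")
  G <- matrix(0, 3, 3, dimnames = list(st, st))
  G["S", "I1"] <- beta1
  G["S", "I2"] <- beta2
  G["I1", "S"] <- delta1
  G["I2", "S"] <- delta2
  contagionModel(st, G, delta = NULL, form = form)
}

#' Three-innovation cyclic-competition preset
#'
#' Every node holds one of three innovations (no susceptible state); all
#' transitions are contact-induced and every ordered state pair, including a
#' state to itself, has its own transmission probability.  The default matrix
#' is a synthetic parameter set chosen so that the largest entry of each row
#' forms a 3-cycle (1 -> 2 -> 3 -> 1) with relatively large probabilities,
#' which drives sustained cyclic, oscillatory macroscopic behavior.
#'
#' @param gamma full 3 x 3 transmission matrix (diagonal entries meaningful).
#' @param form "probability" or "rate".
#' @return a \linkS4class{ContagionModel}.
#' @export
presetThreeInnovations <- function(gamma = threeInnovationsGammaSynthetic(),
                                   form = "probability") {
  stopifnot(all(dim(gamma) == c(3, 3)))
  contagionModel(c("A", "B", "C"), gamma, delta = NULL, form = form)
}

#' Synthetic default parameter matrix for the three-innovation model
#'
#' A synthetic stand-in (not taken from any published table) with the
#' structural features the three-innovation example calls for: relatively
#' large values, meaningful diagonal entries, and row maxima forming the
#' cycle A -> B -> C -> A.
#'
#' @return a 3 x 3 numeric matrix.
#' @export
threeInnovationsGammaSynthetic <- function() {
  matrix(c(0.16, 0.84, 0.21,
           0.13, 0.44, 0.90,
           0.88, 0.07, 0.35), 3, 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

#' Multiplex two-contagion competition preset
#'
#' The competition model on a two-layer multiplex network where each contagion
#' spreads only on its own layer: layer 1 carries the S -> I1 transmission,
#' layer 2 the S -> I2 transmission; recoveries are spontaneous as in the
#' single-layer model.
#'
#' @inheritParams presetSI1I2S
#' @return a \linkS4class{MultiplexContagionModel} with two layers.
#' @export
presetMultiplexSI1I2S <- function(beta1, beta2, delta1, delta2,
                                  form = "probability") {
  st <- c("S", "I1", "I2")
  G1 <- matrix(0, 3, 3, dimnames = list(st, st)); G1["S", "I1"] <- beta1
  G2 <- matrix(0, 3, 3, dimnames = list(st, st)); G2["S", "I2"] <- beta2
  D <- matrix(0, 3, 3, dimnames = list(st, st))
  D["I1", "S"] <- delta1
  D["I2", "S"] <- delta2
  base <- contagionModel(st, G1 + G2, D, form = form)
  new("MultiplexContagionModel", states = base@states, gamma = G1 + G2,
      delta = base@delta, theta = base@theta, form = base@form,
      gammaLayers = list(G1, G2))
}

#' Read a model from a YAML config file
#'
#' The config declares \code{states}, \code{gamma} (list of rows), optional
#' \code{delta}, optional sparse \code{theta} triplets (list of \code{[k, r,
#' l]} label triples), and optional \code{form}.  Alternatively a
#' \code{preset} name plus \code{parameters} may be given.
#'
#' @param path YAML file.
#' @return a \linkS4class{ContagionModel}.
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    fn <- switch(cfg$preset,
      SIS = presetSIS, SIR = presetSIR, SIRS = presetSIRS,
      MakiThompson = presetMakiThompson, SI1I2S = presetSI1I2S,
      SI1I2SContactOnly = presetSI1I2SContactOnly,
      ThreeInnovations = presetThreeInnovations,
      MultiplexSI1I2S = presetMultiplexSI1I2S,
      stop("unknown preset: ", cfg$preset))
    return(do.call(fn, as.list(cfg$parameters)))
  }
  states <- as.character(cfg$states)
  m <- length(states)
  gamma <- do.call(rbind, lapply(cfg$gamma, as.numeric))
  delta <- if (is.null(cfg$delta)) NULL else
    do.call(rbind, lapply(cfg$delta, as.numeric))
  theta <- if (is.null(cfg$theta)) NULL else
    do.call(rbind.data.frame, lapply(cfg$theta, function(tr)
      stats::setNames(as.list(tr), c("k", "r", "l"))))
  contagionModel(states, gamma, delta, theta,
                 form = if (is.null(cfg$form)) "probability" else cfg$form)
}

#' Write a model to a YAML config file
#'
#' @param model a \linkS4class{ContagionModel}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
writeModelConfig <- function(model, path) {
  m <- length(model@states)
  tt <- thetaTargets(model)
  trips <- list()
  for (k in seq_len(m)) for (r in seq_len(m)) if (tt[k, r] != r)
    trips[[length(trips) + 1L]] <-
      c(model@states[k], model@states[r], model@states[tt[k, r]])
  cfg <- list(states = as.list(model@states),
              gamma = lapply(seq_len(m), function(i) as.list(model@gamma[i, ])),
              delta = lapply(seq_len(m), function(i) as.list(model@delta[i, ])),
              form = model@form)
  if (length(trips)) cfg$theta <- trips
  yaml::write_yaml(cfg, path)
  invisible(path)
}
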