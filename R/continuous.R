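# Continuous-time deterministic equations: the rate-form limit of the
# discrete-time solver, integrated by fixed-step RK4, plus the homogeneous
# mean-field reduction of the rumor model.

layerAdjacency <- function(network) {
  if (is(network, "MultiplexContagionNetwork"))
    lapply(network@layers, function(l) l@adjacency)
  else list(network@adjacency)
}

rateCube <- function(model) gammaCube(model)

#' Right-hand side of the continuous-time equations
#'
#' For the identity stimulation tensor the rate of change of \code{p_i^k}
#' is
#' \deqn{\dot p_i^k = \sum_{l \ne k} [\tilde\delta_{lk} p_i^l -
#'   \tilde\delta_{kl} p_i^k] + \sum_{l \ne k} [\tilde\gamma_{lk} p_i^l
#'   (A p^k)_i - \tilde\gamma_{kl} p_i^k (A p^l)_i];}
#' the contact gain for state k depends only on the neighbors' state-k
#' components, because an infinitesimal time step admits at most one
#' transmission event.  A general Theta routes the contact gain of an
#' exposure to its stimulated target state instead.  Rows of the result sum
#' to zero exactly.
#'
#' @param P N x m probability field.
#' @param model a rate-form \linkS4class{ContagionModel}.
#' @param network the matching network.
#' @return N x m matrix dP/dt.
#' @export
odeRHS <- function(P, model, network) {
  if (model@form != "rate")
    stop("continuous-time equations require a rate-form model; use toRates()")
  checkModelNetwork(model, network)
  P <- rbind(P)
  m <- length(model@states)
  As <- layerAdjacency(network)
  gc <- rateCube(model)
  tt <- thetaTargets(model)
  Dt <- model@delta
  dP <- P %*% Dt - sweep(P, 2, rowSums(Dt), "*")
  for (a in seq_along(As)) {
    FA <- as.matrix(As[[a]] %*% P)
    for (l in seq_len(m)) for (r in seq_len(m)) {
      g <- gc[l, r, a]
      if (g == 0) next
      flux <- g * P[, l] * FA[, r]
      tgt <- tt[l, r]
      if (tgt != l) {
        dP[, tgt] <- dP[, tgt] + flux
        dP[, l] <- dP[, l] - flux
      }
    }
  }
  dP
}

#' Fixed-step RK4 integration of the continuous-time equations
#'
#' @inheritParams odeRHS
#' @param tEnd integration horizon.
#' @param dt fixed step size.
#' @param times optional explicit output times (default \code{seq(0, tEnd,
#'   by = dt)}).
#' @return list with \code{times}, \code{fields} (list of N x m matrices),
#'   \code{fractions} (times x m matrix) and \code{final}.
#' @export
integrateODE <- function(P, model, network, tEnd, dt = 0.01, times = NULL) {
  if (model@form != "rate")
    stop("continuous-time integration requires a rate-form model")
  checkModelNetwork(model, network)
  P <- rbind(P)
  N <- nrow(P)
  m <- ncol(P)
  if (is.null(times)) times <- seq(0, tEnd, by = dt)
  rhs <- function(t, y, parms) {
    list(as.vector(odeRHS(matrix(y, N, m), model, network)))
  }
  sol <- deSolve::ode(y = as.vector(P), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  fields <- lapply(seq_len(nrow(sol)), function(i)
    matrix(sol[i, -1], N, m))
  fractions <- t(vapply(fields, colMeans, numeric(m)))
  colnames(fractions) <- model@states
  list(times = sol[, 1], fields = fields, fractions = fractions,
       final = fields[[length(fields)]])
}

#' Consistency of the discrete solver with its continuous-time limit
#'
#' Converts the rate model to step probabilities at a sequence of shrinking
#' time steps, runs the discrete deterministic solver to \code{tEnd}, and
#' measures the maximum absolute deviation of the final field from a
#' reference RK4 solution.  First-order consistency shows as deviations
#' shrinking linearly in dt; the fitted log-log slope is returned.
#'
#' @param model a rate-form \linkS4class{ContagionModel}.
#' @param network the network.
#' @param P0 initial N x m field.
#' @param tEnd horizon.
#' @param dts decreasing sequence of discrete step sizes.
#' @param refDt step size of the RK4 reference.
#' @return list with \code{dts}, \code{deviations} and the fitted
#'   \code{slope}.
#' @export
discreteContinuousConsistency <- function(model, network, P0, tEnd,
                                          dts = c(0.1, 0.05, 0.025, 0.0125),
                                          refDt = 0.005) {
  if (model@form != "rate") stop("supply the model in rate form")
  ref <- integrateODE(P0, model, network, tEnd, dt = refDt)$final
  devs <- vapply(dts, function(dt) {
    pm <- toProbabilities(model, dt)
    P <- P0
    for (s in seq_len(round(tEnd / dt))) P <- stepField(P, pm, network)
    max(abs(P - ref))
  }, numeric(1))
  slope <- unname(coef(lm(log(devs) ~ log(dts)))[2])
  list(dts = dts, deviations = devs, slope = slope)
}

#' Homogeneous mean-field rumor model
#'
#' The three scalar equations of the rumor model with forgetting under the
#' homogeneous mean-field assumption (every node has degree k): with
#' ignorant/spreader/stifler fractions (i, s, r),
#' \deqn{\dot i = -\tilde\lambda k\, i s, \quad
#'   \dot s = \tilde\lambda k\, i s - \tilde\alpha k\, s (s + r) -
#'   \tilde\sigma s, \quad
#'   \dot r = \tilde\alpha k\, s (s + r) + \tilde\sigma s.}
#' On a k-regular graph with uniform initial conditions the full per-node
#' system collapses onto these equations node-for-node.
#'
#' @param kDegree common node degree.
#' @param lambda,alpha,sigma spreading, stifling and forgetting rates.
#' @param y0 initial (i, s, r) fractions (sum to 1).
#' @param tEnd horizon.
#' @param dt RK4 step size.
#' @return matrix with columns \code{time, I, S, R}.
#' @export
makiThompsonHomogeneous <- function(kDegree, lambda, alpha, sigma, y0, tEnd,
                                    dt = 0.01) {
  stopifnot(length(y0) == 3, abs(sum(y0) - 1) < 1e-9)
  rhs <- function(t, y, parms) {
    i <- y[1]; s <- y[2]; r <- y[3]
    list(c(-lambda * kDegree * i * s,
           lambda * kDegree * i * s - alpha * kDegree * s * (s + r) -
             sigma * s,
           alpha * kDegree * s * (s + r) + sigma * s))
  }
  sol <- deSolve::ode(y = as.numeric(y0), times = seq(0, tEnd, by = dt),
                      func = rhs, parms = NULL, method = "rk4")
  colnames(sol) <- c("time", "I", "S", "R")
  unclass(sol)
}
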