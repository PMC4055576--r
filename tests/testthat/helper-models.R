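# Shared fixtures built in code.

# a valid random model: random Gamma, random sub-stochastic Delta, random
# one-hot Theta (identity rows with probability idProb)
randomModel <- function(m = 3, gammaMax = 1, idProb = 0.5) {
  G <- matrix(runif(m * m, 0, gammaMax), m, m)
  D <- matrix(0, m, m)
  for (k in seq_len(m)) {
    off <- runif(m - 1, 0, 1 / m)
    D[k, -k] <- off
  }
  tt <- matrix(0L, m, m)
  theta <- NULL
  trips <- NULL
  for (k in seq_len(m)) for (r in seq_len(m)) {
    l <- if (runif(1) < idProb) r else sample.int(m, 1)
    if (l != r) trips <- rbind(trips, data.frame(k = k, r = r, l = l))
  }
  contagionModel(paste0("s", seq_len(m)), G, D, theta = trips)
}

randomField <- function(N, m) {
  P <- matrix(runif(N * m), N, m)
  P / rowSums(P)
}

# random connected graph on n nodes: random spanning tree plus extra edges
randomConnectedGraph <- function(n, extra = n) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  more <- t(replicate(extra, sample.int(n, 2)))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  multicontagion:::newNetwork(n, rbind(edges, more), warnDisconnected = FALSE)
}

# hand-coded one-step references for the preset reductions (independent
# transcriptions of the per-model printed update equations; approximation-free
# product forms wherever only one state can be adopted per receiver)
handStepSIS <- function(P, beta, delta, A) {
  pS <- P[, 1]; pI <- P[, 2]
  qI <- 1 - apply(1 - beta * (A * rep(pI, each = nrow(A))), 1, prod)
  pI2 <- (1 - delta) * pI + pS * qI
  cbind(1 - pI2, pI2)
}

handStepSIR <- function(P, beta, delta, A) {
  pS <- P[, 1]; pI <- P[, 2]; pR <- P[, 3]
  qI <- 1 - apply(1 - beta * (A * rep(pI, each = nrow(A))), 1, prod)
  pI2 <- (1 - delta) * pI + pS * qI
  pR2 <- pR + delta * pI
  cbind(1 - pI2 - pR2, pI2, pR2)
}

handStepSIRS <- function(P, beta, delta, xi, A) {
  pS <- P[, 1]; pI <- P[, 2]; pR <- P[, 3]
  qI <- 1 - apply(1 - beta * (A * rep(pI, each = nrow(A))), 1, prod)
  pI2 <- (1 - delta) * pI + pS * qI
  pR2 <- (1 - xi) * pR + delta * pI
  cbind(1 - pI2 - pR2, pI2, pR2)
}

# states (I, S, R) = ignorant, spreader, stifler
handStepMT <- function(P, lambda, alpha, sigma, A) {
  pI <- P[, 1]; pS <- P[, 2]; pR <- P[, 3]
  qS <- 1 - apply(1 - lambda * (A * rep(pS, each = nrow(A))), 1, prod)
  qR <- 1 - apply(1 - alpha * (A * rep(pS + pR, each = nrow(A))), 1, prod)
  pI2 <- pI * (1 - qS)
  pS2 <- pI * qS + (1 - sigma) * pS * (1 - qR)
  pR2 <- pR + sigma * pS + (1 - sigma) * pS * qR
  cbind(pI2, pS2, pR2)
}

# states (S, I1, I2); the susceptible receiver needs the competition
# approximation: mass 1 - h split proportionally to the per-state weights
handStepSI1I2S <- function(P, beta1, beta2, delta1, delta2, A) {
  N <- nrow(P)
  p1 <- P[, 2]; p2 <- P[, 3]
  q1 <- numeric(N); q2 <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] > 0)
    v <- beta1 * p1[nb] + beta2 * p2[nb]
    h <- prod(1 - v)
    u1 <- beta1 * sum(p1[nb] / (1 - v / 2))
    u2 <- beta2 * sum(p2[nb] / (1 - v / 2))
    tot <- u1 + u2
    if (tot > 0) {
      q1[i] <- u1 / tot * (1 - h)
      q2[i] <- u2 / tot * (1 - h)
    }
  }
  pI1 <- (1 - delta1) * P[, 2] + P[, 1] * q1
  pI2 <- (1 - delta2) * P[, 3] + P[, 1] * q2
  cbind(1 - pI1 - pI2, pI1, pI2)
}

# multiplex competition, each contagion on its own layer: per-layer product
# forms with the pooled no-adoption probability and proportional splitting
handStepMultiplexSI1I2S <- function(P, beta1, beta2, delta1, delta2, A1, A2) {
  N <- nrow(P)
  p1 <- P[, 2]; p2 <- P[, 3]
  q1 <- numeric(N); q2 <- numeric(N)
  for (i in seq_len(N)) {
    nb1 <- which(A1[i, ] > 0); nb2 <- which(A2[i, ] > 0)
    v1 <- beta1 * p1[nb1]; v2 <- beta2 * p2[nb2]
    h <- prod(1 - v1) * prod(1 - v2)
    u1 <- beta1 * sum(p1[nb1] / (1 - v1 / 2))
    u2 <- beta2 * sum(p2[nb2] / (1 - v2 / 2))
    tot <- u1 + u2
    if (tot > 0) {
      q1[i] <- u1 / tot * (1 - h)
      q2[i] <- u2 / tot * (1 - h)
    }
  }
  pI1 <- (1 - delta1) * P[, 2] + P[, 1] * q1
  pI2 <- (1 - delta2) * P[, 3] + P[, 1] * q2
  cbind(1 - pI1 - pI2, pI1, pI2)
}

denseAdj <- function(network) as.matrix(network@adjacency)
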