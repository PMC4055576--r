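# Exact and approximate one-step adoption probabilities.
#
# A node in state k with n neighbors receives, on each link independently, a
# transmission with probability gamma[k, state_of_neighbor].  If at least one
# link is infectious the node picks one infectious link uniformly at random
# and adopts the state dictated by the Theta tensor; otherwise it keeps its
# state (probability h).  q[l] below is always the probability that state l
# is the *chosen transmission* (before Theta); use applyTheta for the adopted
# state.

adoptionResult <- function(q, h, thetaSlice = NULL) {
  qhat <- if (is.null(thetaSlice)) q else applyTheta(q, thetaSlice)
  new("AdoptionResult", q = as.numeric(q), qhat = as.numeric(qhat),
      h = as.numeric(h))
}

#' Theta-stimulated redistribution of adoption mass
#'
#' Composes raw chosen-transmission probabilities with one receiver-state
#' slice of the stimulation tensor: \code{qhat[l] = sum_r theta[r, l] q[r]}.
#' Mass-preserving; the identity slice returns \code{q} unchanged.
#'
#' @param q length-m vector of chosen-transmission probabilities.
#' @param thetaSlice m x m 0/1 matrix, row r giving the state adopted upon
#'   exposure to transmitted state r (i.e. \code{theta[k, , ]} for receiver
#'   state k).
#' @return length-m vector \code{qhat}.
#' @export
applyTheta <- function(q, thetaSlice) {
  as.numeric(crossprod(thetaSlice, q))
}

#' No-adoption probability
#'
#' Probability that no link becomes infectious in one step.  With integer
#' neighbor counts this is \code{prod((1 - gamma)^counts)}; with per-neighbor
#' probability vectors it is \code{prod_j (1 - sum_l gamma[l] p_j[l])}.  This
#' quantity is always computed exactly, including in the approximate adoption
#' path.
#'
#' @param x either an integer length-m vector of neighbor state counts, or a
#'   k x m matrix whose rows are neighbor state-probability vectors.
#' @param gammaRow length-m vector: row of the transmission matrix for the
#'   receiver's state.
#' @return scalar probability in [0, 1].
#' @export
noAdoptionProb <- function(x, gammaRow) {
  if (is.matrix(x)) {
    v <- as.numeric(x %*% gammaRow)
    prod(1 - v)
  } else {
    prod((1 - gammaRow)^x)
  }
}

#' Exact adoption probabilities for fixed neighbor states
#'
#' Computes the exact distribution of the chosen transmission for a node
#' whose neighbors occupy fixed states (given as per-state counts), by one of
#' two interchangeable exact backends: enumeration of all 2^n infectious-link
#' events (the defining sum), or the polynomial-integral identity
#' \deqn{E[s_l/S; S \ge 1] = \int_0^1 n_l \gamma_l (1-\gamma_l+\gamma_l
#' x)^{n_l - 1} \prod_{j \ne l} (1-\gamma_j+\gamma_j x)^{n_j} \, dx,}
#' where \eqn{s_j ~ Binomial(n_j, \gamma_j)} are the per-state success counts
#' and \eqn{S} their total; the integrand is a polynomial of degree n - 1 and
#' is integrated exactly by Gauss-Legendre quadrature.  The two backends
#' agree to machine precision and satisfy \code{sum(q) + h == 1} exactly.
#'
#' @param counts integer length-m vector of neighbor counts per state.
#' @param gammaRow length-m transmission probabilities for the receiver.
#' @param method \code{"auto"} (enumeration up to \code{enumGuard} links,
#'   polynomial beyond), \code{"enumeration"}, or \code{"polynomial"}.
#' @param thetaSlice optional m x m Theta slice for the receiver state.
#' @param enumGuard largest total neighbor count for the 2^n enumeration.
#' @return an \linkS4class{AdoptionResult}.
#' @examples
#' adoptionExact(c(1, 1), c(0.5, 0.5))  # q = (0.375, 0.375), h = 0.25
#' @export
adoptionExact <- function(counts, gammaRow,
                          method = c("auto", "enumeration", "polynomial"),
                          thetaSlice = NULL, enumGuard = 20L) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(gammaRow), all(counts >= 0))
  n <- sum(counts)
  if (method == "auto")
    method <- if (n <= enumGuard) "enumeration" else "polynomial"
  if (method == "enumeration" && n > 25L)
    stop("enumeration over 2^", n, " events exceeds the guard; ",
         "use the polynomial backend or the approximation")
  h <- prod((1 - gammaRow)^counts)
  if (n == 0L || all(gammaRow * counts == 0)) {
    return(adoptionResult(rep(0, length(counts)), h, thetaSlice))
  }
  q <- if (method == "enumeration") {
    exactByEnumeration(counts, gammaRow)
  } else {
    exactByPolynomial(counts, gammaRow)
  }
  adoptionResult(q, h, thetaSlice)
}

# Defining sum over all 2^n infectious-link events; uniform choice among the
# successful links splits the event mass s_l / S.
exactByEnumeration <- function(counts, gammaRow) {
  m <- length(counts)
  linkState <- rep(seq_len(m), counts)
  g <- gammaRow[linkState]
  n <- length(g)
  nev <- 2^n
  # event w has bit j = 1 iff link j infectious; last link = least
  # significant bit, so event index equals the binary reading of the vector
  bits <- matrix(0L, nev, n)
  w <- 0:(nev - 1)
  for (j in n:1) {
    bits[, j] <- w %% 2L
    w <- w %/% 2L
  }
  p <- rep(1, nev)
  for (j in seq_len(n)) p <- p * ifelse(bits[, j] == 1L, g[j], 1 - g[j])
  S <- rowSums(bits)
  q <- numeric(m)
  pos <- S > 0
  for (l in seq_len(m)) {
    sl <- bits[, linkState == l, drop = FALSE]
    sl <- if (ncol(sl)) rowSums(sl) else numeric(nev)
    q[l] <- sum(p[pos] * sl[pos] / S[pos])
  }
  q
}

# Exact polynomial-integral backend, O(m^2 n); valid for n in the thousands.
exactByPolynomial <- function(counts, gammaRow) {
  m <- length(counts)
  n <- sum(counts)
  gl <- pracma::gaussLegendre(max(2L, floor(n / 2) + 1L), 0, 1)
  x <- gl$x
  base <- vapply(seq_len(m), function(j) (1 - gammaRow[j] + gammaRow[j] * x)^counts[j],
                 numeric(length(x)))
  q <- numeric(m)
  for (l in seq_len(m)) {
    if (counts[l] == 0L || gammaRow[l] == 0) next
    f <- counts[l] * gammaRow[l] *
      (1 - gammaRow[l] + gammaRow[l] * x)^(counts[l] - 1)
    others <- base[, -l, drop = FALSE]
    if (ncol(others)) f <- f * apply(others, 1, prod)
    q[l] <- sum(gl$w * f)
  }
  q
}

#' Exact adoption probabilities for probabilistic neighbor states
#'
#' The deterministic-counterpart version of \code{\link{adoptionExact}}: each
#' neighbor j is in state l with probability \code{P[j, l]} independently,
#' and the full sum over every neighbor-state configuration (weighted by
#' \code{prod_j P[j, c_j]}) of the exact event enumeration is taken.  The
#' cost grows as m^k 2^k in the degree k and is guarded; this backend exists
#' for validation at small degree, with \code{\link{adoptionApprox}} as the
#' tractable path.
#'
#' @param P k x m matrix of neighbor state-probability vectors (rows).
#' @param gammaRow length-m transmission probabilities for the receiver.
#' @param thetaSlice optional m x m Theta slice.
#' @param budget maximum admissible m^k * 2^k elementary terms.
#' @return an \linkS4class{AdoptionResult}.
#' @export
adoptionExactField <- function(P, gammaRow, thetaSlice = NULL, budget = 1e7) {
  P <- rbind(P)
  k <- nrow(P)
  m <- ncol(P)
  stopifnot(length(gammaRow) == m)
  if (m^k * 2^k > budget)
    stop("exact configuration sum needs m^k * 2^k = ", m^k * 2^k,
         " terms, over the budget of ", budget,
         "; use adoptionApprox for high-degree nodes")
  h <- noAdoptionProb(P, gammaRow)
  if (k == 0L) return(adoptionResult(rep(0, m), 1, thetaSlice))
  memo <- new.env(parent = emptyenv())
  q <- rep(0, m)
  counts <- integer(m)
  recurse <- function(j, wgt) {
    if (wgt == 0) return()
    if (j > k) {
      key <- paste(counts, collapse = ",")
      qc <- memo[[key]]
      if (is.null(qc)) {
        qc <- adoptionExact(counts, gammaRow)@q
        memo[[key]] <- qc
      }
      q <<- q + wgt * qc
      return()
    }
    for (l in seq_len(m)) {
      counts[l] <<- counts[l] + 1L
      recurse(j + 1L, wgt * P[j, l])
      counts[l] <<- counts[l] - 1L
    }
  }
  recurse(1L, 1)
  adoptionResult(q, h, thetaSlice)
}

#' Approximate adoption probabilities
#'
#' The tractable O(mk) approximation of the exact adoption distribution.  It
#' follows from the integral identity behind the exact computation by a
#' one-point (midpoint) quadrature of the tie-breaking integral, normalised
#' so that \code{sum(q) + h = 1} with \code{h} kept exact:
#' \deqn{q_l \propto \gamma_l \sum_j \frac{p_j^l}{1 - v_j/2}, \qquad
#'       v_j = \sum_r \gamma_r p_j^r,}
#' scaled to total \eqn{1 - h}.  With integer counts this reduces to
#' \eqn{q_l \propto n_l \gamma_l / (1 - \gamma_l/2)}.  The approximation is
#' exact when only one state is transmissible, when all transmission
#' probabilities are equal, and for nodes of degree at most 1; its worst-case
#' absolute error stays at the 1e-2 level for moderate transmission
#' probabilities, and it tends to overestimate states with high transmission
#' probability when they compete with weakly transmitting states.
#'
#' @param x integer counts (length m) or a k x m matrix of neighbor
#'   probability vectors.
#' @param gammaRow length-m transmission probabilities for the receiver.
#' @param thetaSlice optional m x m Theta slice.
#' @return an \linkS4class{AdoptionResult}.
#' @export
adoptionApprox <- function(x, gammaRow, thetaSlice = NULL) {
  m <- length(gammaRow)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == m)
    v <- as.numeric(x %*% gammaRow)
    h <- prod(1 - v)
    u <- as.numeric(gammaRow * colSums(x / (1 - v / 2)))
  } else {
    stopifnot(length(x) == m)
    h <- prod((1 - gammaRow)^x)
    u <- x * gammaRow / (1 - gammaRow / 2)
  }
  tot <- sum(u)
  q <- if (tot > 0) u / tot * (1 - h) else rep(0, m)
  adoptionResult(q, h, thetaSlice)
}

# Monte-Carlo frequency estimate of the chosen-transmission distribution for
# fixed neighbor counts; used as the third corner of the oracle triangle.
adoptionMonteCarlo <- function(counts, gammaRow, nsim = 1e5) {
  m <- length(counts)
  s <- vapply(seq_len(m), function(l)
    if (counts[l] > 0) stats::rbinom(nsim, counts[l], gammaRow[l])
    else integer(nsim), integer(nsim))
  S <- rowSums(s)
  pick <- rep(0L, nsim)
  pos <- which(S > 0)
  if (length(pos)) {
    u <- stats::runif(length(pos)) * S[pos]
    cum <- t(apply(s[pos, , drop = FALSE], 1, cumsum))
    pick[pos] <- max.col(cum >= u, ties.method = "first")
  }
  q <- tabulate(pick[pick > 0], nbins = m) / nsim
  list(q = q, h = mean(S == 0))
}
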