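test_that("exact adoption matches hand-derived small cases", {
  # no transmission possible
  r <- adoptionExact(c(3, 2), c(0, 0))
  expect_equal(r@q, c(0, 0))
  expect_equal(r@h, 1)
  # single Bernoulli link
  r <- adoptionExact(c(1, 0), c(0.3, 0.9))
  expect_equal(r@q, c(0.3, 0), tolerance = 1e-15)
  expect_equal(r@h, 0.7)
  # one neighbor of each of two states, equal gamma 0.5: ties split evenly
  r <- adoptionExact(c(1, 1), c(0.5, 0.5))
  expect_equal(r@q, c(0.375, 0.375), tolerance = 1e-15)
  expect_equal(r@h, 0.25)
  # gamma_B = 1: only the A link is uncertain
  r <- adoptionExact(c(1, 1), c(0.5, 1))
  expect_equal(r@q, c(0.25, 0.75), tolerance = 1e-15)
  expect_equal(r@h, 0)
  # equal gamma closed form (n_l / n) (1 - (1 - g)^n)
  counts <- c(4, 2, 1); g <- 0.37
  r <- adoptionExact(counts, rep(g, 3))
  expect_equal(r@q, counts / 7 * (1 - (1 - g)^7), tolerance = 1e-14)
  # single-state product form at high degree via the polynomial backend
  r <- adoptionExact(c(1000, 0), c(0.003, 0.8), method = "polynomial")
  expect_equal(r@q[1], 1 - 0.997^1000, tolerance = 1e-12)
})

test_that("enumeration and polynomial backends agree to 1e-12 with exact conservation", {
  set.seed(11)
  for (i in 1:300) {
    m <- sample(2:4, 1)
    n <- sample(0:12, 1)
    counts <- as.vector(rmultinom(1, n, runif(m) + 0.05))
    gam <- runif(m)
    a <- adoptionExact(counts, gam, method = "enumeration")
    b <- adoptionExact(counts, gam, method = "polynomial")
    expect_lt(max(abs(a@q - b@q)), 1e-12)
    expect_lt(abs(sum(a@q) + a@h - 1), 1e-12)
    expect_lt(abs(sum(b@q) + b@h - 1), 1e-12)
  }
})

test_that("Monte-Carlo frequencies agree with the exact distribution", {
  set.seed(12)
  for (i in 1:5) {
    counts <- as.vector(rmultinom(1, sample(2:8, 1), c(1, 1, 1)))
    gam <- runif(3)
    ex <- adoptionExact(counts, gam)
    mc <- multicontagion:::adoptionMonteCarlo(counts, gam, nsim = 1e5)
    sig <- sqrt(pmax(ex@q * (1 - ex@q), 1e-12) / 1e5)
    expect_true(all(abs(mc$q - ex@q) <= 3.5 * sig))
  }
})

test_that("field (probabilistic-neighbor) exact sum reduces and extends correctly", {
  set.seed(13)
  gam <- c(0.6, 0.3, 0.8)
  # degenerate rows reproduce the counts form
  counts <- c(2, 1, 1)
  P <- rbind(diag(3)[c(1, 1, 2, 3), ])
  a <- adoptionExactField(P, gam)
  b <- adoptionExact(counts, gam)
  expect_equal(a@q, b@q, tolerance = 1e-13)
  expect_equal(a@h, b@h, tolerance = 1e-14)
  # one half/half neighbor with equal gammas: q = g/2 each
  r <- adoptionExactField(rbind(c(0.5, 0.5)), c(0.4, 0.4))
  expect_equal(r@q, c(0.2, 0.2), tolerance = 1e-15)
  # law of total probability: expectation over sampled configurations
  P <- randomField(4, 3)
  fa <- adoptionExactField(P, gam)
  nsim <- 2e4
  qacc <- matrix(0, nsim, 3)
  for (s in seq_len(nsim)) {
    conf <- apply(P, 1, function(p) sample.int(3, 1, prob = p))
    qacc[s, ] <- adoptionExact(tabulate(conf, 3), gam)@q
  }
  se <- apply(qacc, 2, sd) / sqrt(nsim)
  expect_true(all(abs(colMeans(qacc) - fa@q) <= 3.5 * se))
  # the guard refuses oversized configuration sums
  expect_error(adoptionExactField(randomField(12, 4), runif(4), budget = 1e5),
               "budget")
})

test_that("approximation is exact in its three limits", {
  set.seed(14)
  for (i in 1:50) {
    m <- sample(2:4, 1)
    gam <- runif(m)
    # (a) only one transmissible state
    g1 <- numeric(m); g1[sample.int(m, 1)] <- runif(1)
    counts <- as.vector(rmultinom(1, sample(0:10, 1), rep(1, m)))
    expect_equal(adoptionApprox(counts, g1)@q,
                 adoptionExact(counts, g1)@q, tolerance = 1e-12)
    P <- randomField(sample(1:5, 1), m)
    expect_equal(adoptionApprox(P, g1)@q,
                 adoptionExactField(P, g1)@q, tolerance = 1e-12)
    # (b) all gammas equal
    ge <- rep(runif(1), m)
    expect_equal(adoptionApprox(counts, ge)@q,
                 adoptionExact(counts, ge)@q, tolerance = 1e-12)
    expect_equal(adoptionApprox(P, ge)@q,
                 adoptionExactField(P, ge)@q, tolerance = 1e-12)
    # (c) degree <= 1
    n1 <- numeric(m); if (runif(1) < 0.9) n1[sample.int(m, 1)] <- 1
    expect_equal(adoptionApprox(n1, gam)@q,
                 adoptionExact(n1, gam)@q, tolerance = 1e-12)
    expect_equal(adoptionApprox(P[1, , drop = FALSE], gam)@q,
                 adoptionExactField(P[1, , drop = FALSE], gam)@q,
                 tolerance = 1e-12)
  }
})

test_that("approximation accuracy bounds hold over count sweeps", {
  set.seed(15)
  worst03 <- 0
  worst10 <- 0
  for (i in 1:400) {
    m <- sample(2:4, 1)
    counts <- as.vector(rmultinom(1, sample(1:10, 1), runif(m) + 0.1))
    ex3 <- adoptionExact(counts, g3 <- runif(m, 0, 0.3))
    ap3 <- adoptionApprox(counts, g3)
    worst03 <- max(worst03, max(abs(ex3@q - ap3@q)))
    ex1 <- adoptionExact(counts, g1 <- runif(m, 0, 1))
    ap1 <- adoptionApprox(counts, g1)
    worst10 <- max(worst10, max(abs(ex1@q - ap1@q)))
  }
  expect_lt(worst03, 0.02)
  expect_lt(worst10, 0.1)
})

test_that("no-adoption probability forms agree and stay exact in the approximation", {
  expect_equal(noAdoptionProb(c(2, 0), c(0.5, 0.9)), 0.25)
  expect_equal(noAdoptionProb(c(0, 0), c(0, 0)), 1)
  set.seed(16)
  gam <- runif(3)
  counts <- c(2, 1, 2)
  P <- rbind(diag(3)[c(1, 1, 2, 3, 3), ])
  expect_equal(noAdoptionProb(P, gam), noAdoptionProb(counts, gam),
               tolerance = 1e-14)
  ap <- adoptionApprox(counts, gam)
  expect_equal(ap@h, noAdoptionProb(counts, gam))
  expect_equal(sum(ap@q) + ap@h, 1, tolerance = 1e-14)
})

test_that("Theta redistribution is mass-preserving and matches the rumor case", {
  q <- c(0, 0.3, 0.2)
  # spreader slice of the rumor model: exposures to S and to R both adopt R
  th <- diag(3); th[2, ] <- c(0, 0, 1)
  expect_equal(applyTheta(q, th), c(0, 0, 0.5))
  expect_equal(applyTheta(q, diag(3)), q)
  set.seed(17)
  for (i in 1:20) {
    q <- runif(4)
    tt <- sample.int(4, 4, replace = TRUE)
    th <- matrix(0, 4, 4); th[cbind(1:4, tt)] <- 1
    expect_equal(sum(applyTheta(q, th)), sum(q), tolerance = 1e-14)
  }
})
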