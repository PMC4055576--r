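test_that("trivial fields are fixed and rows stay stochastic", {
  g <- makeGraph("star", 6)
  frozen <- contagionModel(c("A", "B", "C"), matrix(0, 3, 3))
  P <- randomField(6, 3)
  expect_equal(stepField(P, frozen, g, "approx"), P)
  expect_equal(stepField(P, frozen, g, "exact"), P)
  set.seed(31)
  presets <- list(presetSIS(0.4, 0.2), presetSIR(0.4, 0.2),
                  presetSIRS(0.4, 0.2, 0.1), presetMakiThompson(0.3, 0.2, 0.1),
                  presetSI1I2S(0.5, 0.4, 0.2, 0.2),
                  presetSI1I2SContactOnly(0.5, 0.4, 0.2, 0.2),
                  presetThreeInnovations())
  for (mod in presets) {
    m <- numStates(mod)
    P <- randomField(6, m)
    for (backend in c("approx", "exact")) {
      P2 <- stepField(P, mod, g, backend)
      expect_lt(max(abs(rowSums(P2) - 1)), 1e-9)
      expect_true(all(P2 >= -1e-12))
    }
  }
})

test_that("the SIS stationary point on a two-node path is reproduced", {
  g <- makeGraph("ring", 2)
  sis <- presetSIS(0.4, 0.2)
  P <- matrix(0.5, 2, 2)
  expect_equal(stepField(P, sis, g, "exact"), P, tolerance = 1e-14)
})

test_that("generic engine reproduces hand-coded preset equations to 1e-12", {
  set.seed(32)
  graphs <- list(makeGraph("star", 6),
                 makeGraph("lattice2d_periodic", rows = 3, cols = 3))
  for (g in graphs) {
    A <- denseAdj(g)
    N <- numNodes(g)
    checks <- list(
      list(mod = presetSIS(0.43, 0.21), m = 2,
           hand = function(P) handStepSIS(P, 0.43, 0.21, A)),
      list(mod = presetSIR(0.38, 0.17), m = 3,
           hand = function(P) handStepSIR(P, 0.38, 0.17, A)),
      list(mod = presetSIRS(0.38, 0.17, 0.09), m = 3,
           hand = function(P) handStepSIRS(P, 0.38, 0.17, 0.09, A)),
      list(mod = presetMakiThompson(0.33, 0.27, 0.11), m = 3,
           hand = function(P) handStepMT(P, 0.33, 0.27, 0.11, A)),
      list(mod = presetSI1I2S(0.52, 0.35, 0.2, 0.25), m = 3,
           hand = function(P) handStepSI1I2S(P, 0.52, 0.35, 0.2, 0.25, A)))
    for (ck in checks) {
      P <- randomField(N, ck$m)
      Pg <- P
      worst <- 0
      for (t in 1:100) {
        Pg <- stepField(Pg, ck$mod, g, "approx")
        P <- ck$hand(P)
        worst <- max(worst, max(abs(Pg - P)))
      }
      expect_lt(worst, 1e-12)
    }
  }
})

test_that("exact and approximate backends agree within the adoption tolerances", {
  set.seed(33)
  g <- makeGraph("star", 6)  # max degree 5
  for (i in 1:5) {
    mod <- randomModel(3, gammaMax = 1)
    P <- randomField(6, 3)
    d <- abs(stepField(P, mod, g, "exact") - stepField(P, mod, g, "approx"))
    expect_lt(max(d), 0.1)
    modLow <- randomModel(3, gammaMax = 0.3)
    d <- abs(stepField(P, modLow, g, "exact") -
               stepField(P, modLow, g, "approx"))
    expect_lt(max(d), 0.02)
  }
})

test_that("degenerate fields give the stochastic one-step distribution", {
  set.seed(34)
  g <- randomConnectedGraph(5, extra = 3)
  mod <- presetMakiThompson(0.5, 0.4, 0.15)
  init <- c(2L, 1L, 3L, 2L, 1L)
  P1 <- stepField(fieldFromAssignment(init, mod), mod, g, "exact")
  nrep <- 3e4
  tab <- matrix(0L, 5, 3)
  for (r in seq_len(nrep)) {
    s <- simulateStep(init, mod, g)
    tab[cbind(1:5, s)] <- tab[cbind(1:5, s)] + 1L
  }
  # chi-square per node against the exact one-step distribution
  for (i in 1:5) {
    keep <- P1[i, ] > 0
    stat <- sum((tab[i, keep] - nrep * P1[i, keep])^2 / (nrep * P1[i, keep]))
    pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 1e-4)
  }
})

test_that("SIR observables are monotone along deterministic iterations", {
  g <- makeGraph("lattice2d_periodic", rows = 3, cols = 3)
  sir <- presetSIR(0.45, 0.2)
  set.seed(35)
  P <- randomField(9, 3)
  for (t in 1:60) {
    P2 <- stepField(P, sir, g, "approx")
    expect_true(all(P2[, 3] >= P[, 3] - 1e-12))
    expect_true(all(P2[, 1] <= P[, 1] + 1e-12))
    P <- P2
  }
})

test_that("fixed points: subcritical SIS dies out, competition has one winner", {
  g <- makeGraph("star", 6)
  fp <- iterateFixedPoint(fieldFromAssignment(c(2L, 1L, 1L, 1L, 1L, 2L),
                                              presetSIS(0.05, 0.5)),
                          presetSIS(0.05, 0.5), g, "exact")
  expect_true(fp@converged)
  expect_lt(fp@fractions[2], 1e-8)

  mod <- presetSI1I2S(0.6, 0.3, 0.2, 0.2)
  P0 <- fieldFromAssignment(c(1L, 2L, 3L, 1L, 2L, 3L), mod)
  for (backend in c("approx", "exact")) {
    fp <- iterateFixedPoint(P0, mod, g, backend)
    expect_true(fp@converged)
    expect_lt(fp@fractions["I2"], 1e-6)
    expect_gt(fp@fractions["I1"], 0.1)
  }
})

test_that("unconverged oscillatory transients are flagged, not raised", {
  # the cyclic three-innovation dynamics oscillate for hundreds of steps
  # before damping; inside that window the iterator must report
  # non-convergence with a bounded residual instead of failing
  g <- makeGraph("lattice2d_periodic", rows = 6, cols = 6)
  mod <- presetThreeInnovations()
  set.seed(36)
  init <- randomStateAssignment(g, mod)
  fp <- iterateFixedPoint(fieldFromAssignment(init, mod), mod, g, "approx",
                          tol = 1e-10, maxIter = 150)
  expect_false(fp@converged)
  expect_true(is.finite(fp@residual))
  expect_lt(fp@residual, 1)
  expect_gt(length(fp@residualHistory), 10)
  # left to run, the same system settles and reports convergence
  fp2 <- iterateFixedPoint(fieldFromAssignment(init, mod), mod, g, "approx",
                           tol = 1e-10, maxIter = 5000)
  expect_true(fp2@converged)
})

test_that("multiplex step: single layer degenerates, empty layer reduces to SIS", {
  ring <- makeGraph("ring", 6)
  empty <- multicontagion:::newNetwork(6, matrix(integer(), 0, 2),
                                       warnDisconnected = FALSE)
  # L = 1 multiplex equals the single-layer engine
  mx1 <- makeMultiplex(list(ring))
  m1 <- presetMultiplexSI1I2S(0.5, 0.4, 0.2, 0.25)
  m1@gammaLayers <- list(m1@gamma)
  single <- presetSI1I2S(0.5, 0.4, 0.2, 0.25)
  set.seed(37)
  P <- randomField(6, 3)
  expect_equal(stepField(P, m1, mx1, "approx"),
               stepField(P, single, ring, "approx"), tolerance = 1e-14)
  expect_equal(stepField(P, m1, mx1, "exact"),
               stepField(P, single, ring, "exact"), tolerance = 1e-14)

  # an edgeless second layer: contagion 2 cannot move, I1 follows SIS
  mx <- makeMultiplex(list(ring, empty))
  mod <- presetMultiplexSI1I2S(0.5, 0.4, 0.2, 0.25)
  P <- cbind(randomField(6, 2), 0)
  sis <- presetSIS(0.5, 0.2)
  P2 <- stepField(P, mod, mx, "approx")
  Psis <- stepField(P[, 1:2], sis, ring, "approx")
  expect_equal(P2[, 2], Psis[, 2], tolerance = 1e-13)
  expect_true(all(P2[, 3] == 0))
})

test_that("multiplex competition matches the hand-coded per-layer product form", {
  set.seed(38)
  l1 <- randomConnectedGraph(6, extra = 2)
  l2 <- randomConnectedGraph(6, extra = 2)
  mx <- makeMultiplex(list(l1, l2))
  mod <- presetMultiplexSI1I2S(0.55, 0.4, 0.2, 0.3)
  A1 <- denseAdj(l1); A2 <- denseAdj(l2)
  P <- randomField(6, 3)
  Pg <- P
  worst <- 0
  for (t in 1:50) {
    Pg <- stepField(Pg, mod, mx, "approx")
    P <- handStepMultiplexSI1I2S(P, 0.55, 0.4, 0.2, 0.3, A1, A2)
    worst <- max(worst, max(abs(Pg - P)))
  }
  expect_lt(worst, 1e-12)
})

test_that("invalid fields and rate-form models are rejected", {
  g <- makeGraph("ring", 4)
  sis <- presetSIS(0.4, 0.2)
  expect_error(stepField(matrix(0.5, 4, 2), presetSIS(0.4, 0.2, form = "rate"),
                         g), "probability-form")
  expect_error(stepField(matrix(c(0.7, 0.6), 4, 2), sis, g), "sum to 1")
})
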