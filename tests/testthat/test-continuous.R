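test_that("the rate equations conserve probability and vanish for zero rates", {
  g <- makeGraph("star", 6)
  zero <- contagionModel(c("A", "B", "C"), matrix(0, 3, 3), form = "rate")
  set.seed(41)
  P <- randomField(6, 3)
  expect_equal(odeRHS(P, zero, g), matrix(0, 6, 3), ignore_attr = TRUE)
  for (i in 1:10) {
    mod <- randomModel(3)
    modR <- toRates(mod, 0.1)
    rhs <- odeRHS(P, modR, g)
    expect_lt(max(abs(rowSums(rhs))), 1e-12)
  }
  expect_error(odeRHS(P, presetSIS(0.4, 0.2), g), "rate-form")
})

test_that("SIS rhs on a shared-probability edge matches the textbook form", {
  g <- makeGraph("ring", 2)
  sisR <- presetSIS(0.6, 0.3, form = "rate")
  p <- c(0.7, 0.3)
  rhs <- odeRHS(rbind(p, p), sisR, g)
  expect_equal(rhs[1, 2], -0.3 * 0.3 + 0.6 * 0.7 * 0.3, tolerance = 1e-14)
  expect_equal(rhs[1, 1], -rhs[1, 2])
})

test_that("contact gain for a state depends only on neighbors' same-state mass", {
  # gamma with a single nonzero column k: perturbing neighbor components
  # other than k must leave dp^k/dt unchanged
  g <- makeGraph("star", 5)
  G <- matrix(0, 3, 3); G[, 2] <- c(0.5, 0, 0.4)
  mod <- contagionModel(c("A", "B", "C"), G, form = "rate")
  set.seed(42)
  P <- randomField(5, 3)
  base <- odeRHS(P, mod, g)[1, 2]
  P2 <- P
  # move neighbor mass between states A and C only
  shift <- 0.1 * pmin(P2[2:5, 1], P2[2:5, 3])
  P2[2:5, 1] <- P2[2:5, 1] - shift
  P2[2:5, 3] <- P2[2:5, 3] + shift
  expect_equal(odeRHS(P2, mod, g)[1, 2], base, tolerance = 1e-14)
})

test_that("RK4 integration: exact exponential decay and fourth-order error decay", {
  solo <- multicontagion:::newNetwork(1, matrix(integer(), 0, 2),
                                      warnDisconnected = FALSE)
  sisR <- presetSIS(0.6, 0.3, form = "rate")
  tr <- integrateODE(matrix(c(0.2, 0.8), 1, 2), sisR, solo, tEnd = 2)
  expect_lt(abs(tr$final[2] - 0.8 * exp(-0.3 * 2)), 1e-9)
  expect_true(all(abs(rowSums(tr$fractions) - 1) < 1e-7))

  # halving dt shrinks the endpoint error ~16x on a coupled system
  g <- makeGraph("ring", 4)
  set.seed(43)
  P0 <- randomField(4, 2)
  ref <- integrateODE(P0, sisR, g, 2, dt = 0.0005)$final
  e1 <- max(abs(integrateODE(P0, sisR, g, 2, dt = 0.08)$final - ref))
  e2 <- max(abs(integrateODE(P0, sisR, g, 2, dt = 0.04)$final - ref))
  expect_gt(e1 / e2, 8)
})

test_that("SIR mass is conserved and immunity grows monotonically", {
  g <- makeGraph("complete", 5)
  sirR <- presetSIR(0.5, 0.25, form = "rate")
  set.seed(44)
  P0 <- randomField(5, 3)
  tr <- integrateODE(P0, sirR, g, 4, dt = 0.02)
  expect_true(all(abs(rowSums(tr$fractions) - 1) < 1e-7))
  expect_true(all(diff(tr$fractions[, 3]) >= -1e-10))
  expect_true(all(vapply(tr$fields, min, 0) > -1e-9))
})

test_that("competition rhs agrees with an independent specialised implementation", {
  set.seed(45)
  g <- randomConnectedGraph(6)
  A <- denseAdj(g)
  b1 <- 0.5; b2 <- 0.35; d1 <- 0.2; d2 <- 0.3
  mod <- presetSI1I2S(b1, b2, d1, d2, form = "rate")
  for (i in 1:10) {
    P <- randomField(6, 3)
    rhs <- odeRHS(P, mod, g)
    # per-contagion logistic-type growth minus recovery, coupling only
    # through the shared susceptible mass
    f1 <- b1 * P[, 1] * as.vector(A %*% P[, 2]) - d1 * P[, 2]
    f2 <- b2 * P[, 1] * as.vector(A %*% P[, 3]) - d2 * P[, 3]
    expect_equal(rhs[, 2], f1, tolerance = 1e-12)
    expect_equal(rhs[, 3], f2, tolerance = 1e-12)
    expect_equal(rhs[, 1], -f1 - f2, tolerance = 1e-12)
  }
})

test_that("multiplex rhs with one layer equals the single-layer rhs", {
  ring <- makeGraph("ring", 6)
  mx1 <- makeMultiplex(list(ring))
  m1 <- presetMultiplexSI1I2S(0.5, 0.4, 0.2, 0.25, form = "rate")
  m1@gammaLayers <- list(m1@gamma)
  single <- presetSI1I2S(0.5, 0.4, 0.2, 0.25, form = "rate")
  set.seed(46)
  P <- randomField(6, 3)
  expect_equal(odeRHS(P, m1, mx1), odeRHS(P, single, ring),
               tolerance = 1e-14)
})

test_that("the discrete solver converges to the rate equations at first order", {
  g <- makeGraph("star", 6)
  set.seed(47)
  P0 <- randomField(6, 2)
  cc <- discreteContinuousConsistency(presetSIS(0.6, 0.3, form = "rate"),
                                      g, P0, tEnd = 3)
  expect_true(all(diff(cc$deviations) < 0))
  expect_lt(abs(cc$slope - 1), 0.3)
})

test_that("homogeneous mean-field rumor equations collapse the regular-graph system", {
  ring <- makeGraph("ring", 50)
  mtR <- presetMakiThompson(0.3, 0.2, 0.1, form = "rate")
  y0 <- c(0.8, 0.2, 0)
  P0 <- matrix(rep(y0, each = 50), 50, 3)
  full <- integrateODE(P0, mtR, ring, tEnd = 5, dt = 0.01)
  hom <- makiThompsonHomogeneous(2, 0.3, 0.2, 0.1, y0, tEnd = 5, dt = 0.01)
  expect_lt(max(abs(full$final -
                      matrix(rep(hom[nrow(hom), 2:4], each = 50), 50, 3))),
            1e-8)
  expect_true(all(abs(rowSums(hom[, 2:4]) - 1) < 1e-9))
  # zero contact rates freeze the scalar system
  hom0 <- makiThompsonHomogeneous(4, 0, 0, 0, y0, tEnd = 2)
  expect_equal(unname(hom0[nrow(hom0), 2:4]), y0)
})
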