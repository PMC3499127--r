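test_that("the Weber turning response is antisymmetric, bounded and thresholded", {
  wp <- weberParams(A = 30.80, T0 = 10.53)
  expect_equal(weberTurn(50, 50, wp), 0)
  expect_equal(weberTurn(100, 50, wp), 30.80 * 50 / 160.53)
  expect_equal(weberTurn(100, 50, wp), 9.5933, tolerance = 1e-4)
  expect_equal(weberTurn(50, 100, wp), -weberTurn(100, 50, wp))
  expect_equal(weberTurn(0, 0, weberParams(A = 30, T0 = 0)), 0)

  withr::with_seed(1, {
    L <- runif(200, 0, 1000)
    R <- runif(200, 0, 1000)
  })
  expect_true(all(abs(weberTurn(L, R, wp)) <= wp$A))
  # shrinking the threshold can only strengthen the response
  a1 <- abs(weberTurn(L, R, weberParams(A = 30.8, T0 = 10)))
  a2 <- abs(weberTurn(L, R, weberParams(A = 30.8, T0 = 2)))
  expect_true(all(a2 >= a1))
})

test_that("sector integration is symmetric, lateralised and rotation equivariant", {
  g <- pheromoneGrid(matrix(1, 20, 20), cellSize = 1, origin = c(0, 0))
  lr <- sectorConcentrations(g, list(x = 10, y = 10, heading = 0.3))
  expect_equal(lr[["L"]], lr[["R"]])

  # all mass strictly left of an eastward heading: R = 0
  v <- matrix(0, 20, 20)
  v[8:12, 14:16] <- 3
  gl <- pheromoneGrid(v, 1, c(0, 0))
  lr2 <- sectorConcentrations(gl, list(x = 10, y = 10, heading = 0),
                              sectorSpec(radius = 8))
  expect_gt(lr2[["L"]], 0)
  expect_equal(lr2[["R"]], 0)

  # rotating grid and ant together by 90 degrees leaves (L, R) unchanged
  v90 <- t(v)[, rev(seq_len(nrow(v)))] # clockwise quarter turn about the centre
  g90 <- pheromoneGrid(v90, 1, c(0, 0))
  lr3 <- sectorConcentrations(g90, list(x = 10, y = 10, heading = 3 * pi / 2),
                              sectorSpec(radius = 8))
  expect_equal(unname(lr3), unname(lr2))

  expect_error(sectorConcentrations(g, list(x = 40, y = 10, heading = 0)),
               "boundary error")
})

test_that("pheromone maps conserve deposited mass", {
  still <- planarTrajectory(x = matrix(5.5, 1, 10), y = matrix(5.5, 1, 10),
                            heading = matrix(0, 1, 10))
  g <- buildPheromoneMap(still, cellSize = 1, depositPerPassage = 2)
  expect_equal(totalMass(g), 20)
  expect_equal(sum(gridValues(g) > 0), 1)

  tr <- planarTrajectory(x = rbind(seq(0.5, 9.5, 1), seq(0.5, 9.5, 1)),
                         y = rbind(rep(2.5, 10), rep(7.5, 10)),
                         heading = matrix(0, 2, 10))
  g2 <- buildPheromoneMap(tr, cellSize = 1, depositPerPassage = 1,
                          origin = c(0, 0), dims = c(10, 10))
  expect_equal(totalMass(g2), 20) # deposit x total samples, exactly
  # straight crossings stay in the swept rows
  expect_true(all(which(gridValues(g2) > 0, arr.ind = TRUE)[, 2] %in% c(3, 8)))
})

test_that("trail simulation matches the deposit/evaporation balance exactly", {
  e <- 0.07
  res <- simulateTrail(nAnts = 3, T = 45, deposit = 2, evaporation = e,
                       weber = weberParams(A = 0, T0 = 10, noiseSd = 30),
                       seed = 3)
  expect_equal(totalMass(res$grid), 2 * 3 * (1 - (1 - e)^45) / e,
               tolerance = 1e-9)
  # deterministic given the seed
  res2 <- simulateTrail(nAnts = 3, T = 45, deposit = 2, evaporation = e,
                        weber = weberParams(A = 0, T0 = 10, noiseSd = 30),
                        seed = 3)
  expect_identical(gridValues(res$grid), gridValues(res2$grid))
})

test_that("the loop metric separates rings, segments and empty fields", {
  expect_equal(loopMetric(pheromoneGrid(matrix(0, 10, 10))), 0)
  ring <- matrix(0, 12, 12)
  ring[3:9, 3] <- 1; ring[3:9, 9] <- 1; ring[3, 3:9] <- 1; ring[9, 3:9] <- 1
  expect_equal(loopMetric(pheromoneGrid(ring)), 1)
  seg <- matrix(0, 12, 12)
  seg[3:9, 5] <- 1
  expect_equal(loopMetric(pheromoneGrid(seg)), 0)
})

test_that("a pre-seeded trail recruits Weber followers but not the A = 0 control", {
  g <- matrix(0, 40, 40)
  g[, 20] <- 50
  init <- pheromoneGrid(g, 1, c(0, 0))
  nearTrail <- function(res) mean(abs(as.vector(coordsY(res$traj)) - 19.5) <= 2)
  ctl <- simulateTrail(nAnts = 8, T = 120, weber = weberParams(0, 10.53, 10),
                       evaporation = 0, initGrid = init, seed = 4)
  fol <- simulateTrail(nAnts = 8, T = 120, weber = weberParams(30.80, 10.53, 10),
                       evaporation = 0, initGrid = init, seed = 4)
  expect_gt(nearTrail(fol), nearTrail(ctl) + 0.2)
})

test_that("double-bridge dynamics preserve symmetry and obey linear stability", {
  sym <- doubleBridge(flow = 10, n = 1, k = 20, rho = 0.02, c0 = c(5, 5), T = 200)
  expect_equal(max(abs(sym$cA - sym$cB)), 0, tolerance = 1e-8)
  # symmetry is an invariant of the flow at any exponent
  sym2 <- doubleBridge(flow = 10, n = 2, k = 20, rho = 0.02, c0 = c(3, 3), T = 200)
  expect_equal(max(abs(sym2$cA - sym2$cB)), 0, tolerance = 1e-8)

  # numerical linear-stability oracle at the symmetric fixed point
  growthRate <- function(flow, n, k, rho) {
    cstar <- flow / (2 * rho)
    rhs <- function(s) {
      uA <- (k + s[1])^n
      uB <- (k + s[2])^n
      pA <- uA / (uA + uB)
      c(flow * pA - rho * s[1], flow * (1 - pA) - rho * s[2])
    }
    J <- pracma::jacobian(rhs, c(cstar, cstar))
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  # high flow: unstable symmetric state, one branch takes > 90 percent
  expect_gt(growthRate(10, 2, 20, 0.02), 0)
  asym <- doubleBridge(flow = 10, n = 2, k = 20, rho = 0.02,
                       c0 = c(251, 250), T = 2000)
  share <- asym$cA[nrow(asym)] / (asym$cA[nrow(asym)] + asym$cB[nrow(asym)])
  expect_gt(share, 0.9)
  # low flow: stable, the perturbation decays back to symmetry
  expect_lt(growthRate(0.5, 2, 20, 0.02), 0)
  dec <- doubleBridge(flow = 0.5, n = 2, k = 20, rho = 0.02,
                      c0 = c(13.5, 11.5), T = 2000)
  expect_lt(abs(dec$cA[nrow(dec)] - dec$cB[nrow(dec)]), 0.01)
})

test_that("the junction choice is symmetric at ratio 1 and monotone in ratio", {
  cc <- effectiveChoiceCurve(weberParams(30.80, 10.53, 20),
                             ratios = c(1, 1.5, 2, 4), nCrossings = 1,
                             nReps = 4000, seed = 5)
  expect_true(cc$lower[1] <= 0.5 && cc$upper[1] >= 0.5)
  expect_true(all(diff(cc$p) > -0.02))
  expect_true(all(cc$p >= cc$lower & cc$p <= cc$upper))
})
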