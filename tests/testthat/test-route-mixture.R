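straightPath <- function(offset = 0, n = 40) {
  cbind(seq(0, 10, length.out = n), offset)
}

test_that("route distributions summarise repeated paths station-wise", {
  # identical paths: mean = the path, sd at the floor
  same <- replicate(4, straightPath(), simplify = FALSE)
  d <- fitRouteDistribution(same, nStations = 50, sdFloor = 1e-3)
  expect_equal(stations(d)[, 2], rep(0, 50))
  expect_equal(crossTrackSd(d), rep(1e-3, 50))

  # two parallel paths offset +/- d: mean midway, cross-track sd = d
  two <- list(straightPath(0.8), straightPath(-0.8))
  d2 <- fitRouteDistribution(two, nStations = 30, endpointTol = 10)
  expect_equal(stations(d2)[, 2], rep(0, 30), tolerance = 1e-12)
  expect_equal(crossTrackSd(d2), rep(0.8, 30), tolerance = 1e-12)

  # station sd converges to the generating sigma
  paths <- simulateRoutePaths(straightPath(), sd = 0.7, nPaths = 200,
                              nStations = 60, seed = 50)
  d3 <- fitRouteDistribution(paths, nStations = 60)
  interior <- 5:56
  expect_equal(mean(crossTrackSd(d3)[interior]), 0.7, tolerance = 0.07)

  expect_error(fitRouteDistribution(same[1]), "at least 2")
  apart <- list(straightPath(), straightPath() + 50)
  expect_error(fitRouteDistribution(apart, endpointTol = 1),
               "endpoint mismatch")
})

test_that("path log-likelihood is maximal on the mean and drops n/2 per sd", {
  two <- list(straightPath(0.5, 60), straightPath(-0.5, 60))
  d <- fitRouteDistribution(two, nStations = 60, endpointTol = 10)
  base <- pathLogLik(stations(d), d)
  disp <- stations(d) +
    crossTrackSd(d) * swarmfit:::.stationNormals(stations(d))
  expect_equal(base - pathLogLik(disp, d), 60 / 2)
  # monotone decay with uniform displacement magnitude
  lls <- vapply(c(0.2, 0.5, 1, 2), function(m) {
    pathLogLik(stations(d) + m * swarmfit:::.stationNormals(stations(d)), d)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_lt(max(lls), base + 1e-12)
})

test_that("the pair mixture degenerates, symmetrises and stays concave", {
  d1 <- fitRouteDistribution(simulateRoutePaths(straightPath(), 0.5, 10,
                                                nStations = 40, seed = 51),
                             nStations = 40)
  d2 <- fitRouteDistribution(
    lapply(simulateRoutePaths(straightPath(), 0.5, 10, nStations = 40,
                              seed = 52), function(m) sweep(m, 2, c(0, -2), "-")),
    nStations = 40
  )
  path <- simulatePairedPath(d1, d2, 0.6, seed = 53)
  expect_equal(pairMixtureLogLik(path, d1, d2, 1), pathLogLik(path, d1))
  expect_equal(pairMixtureLogLik(path, d1, d2, 0), pathLogLik(path, d2))
  # identical distributions: the weight is irrelevant
  expect_equal(pairMixtureLogLik(path, d1, d1, 0.2),
               pairMixtureLogLik(path, d1, d1, 0.9))
  # swap symmetry
  expect_equal(pairMixtureLogLik(path, d1, d2, 0.3),
               pairMixtureLogLik(path, d2, d1, 0.7))
  # the 1-D fit matches a dense grid maximum (concave objective)
  fit <- fitPairWeight(list(path), d1, d2, "constant")
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  gll <- vapply(grid, function(w) pairMixtureLogLik(path, d1, d2, w),
                numeric(1))
  expect_lt(abs(fit$params[["w"]] - grid[which.max(gll)]), 2e-3)
})

test_that("mixture weights are recovered and collapse to the dominant bird", {
  d1 <- fitRouteDistribution(simulateRoutePaths(straightPath(), 0.4, 12,
                                                nStations = 50, seed = 54),
                             nStations = 50)
  d2 <- fitRouteDistribution(
    lapply(simulateRoutePaths(straightPath(), 0.4, 12, nStations = 50,
                              seed = 55), function(m) sweep(m, 2, c(0, -3), "-")),
    nStations = 50
  )
  paired <- lapply(1:25, function(i) simulatePairedPath(d1, d2, 0.7,
                                                        seed = 560 + i))
  fit <- fitPairWeight(paired, d1, d2, "constant")
  expect_lt(abs(fit$params[["w"]] - 0.7), 0.08)

  # a path lying on bird 1's mean route pushes the weight to 1
  onMean <- fitPairWeight(list(stations(d1)), d1, d2, "constant")
  expect_gt(onMean$params[["w"]], 0.95)
})

test_that("route fidelity is the inverse mean cross-track sd", {
  two <- function(d) list(straightPath(d, 50), straightPath(-d, 50))
  f1 <- routeFidelity(two(0.5), nStations = 40, endpointTol = 10)
  f2 <- routeFidelity(two(1.0), nStations = 40, endpointTol = 10)
  expect_equal(f1, 1 / 0.5)
  expect_equal(f1 / f2, 2) # doubling the spread halves fidelity
  # rigid rotation leaves fidelity unchanged
  rot <- function(m, a) m %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  fr <- routeFidelity(lapply(two(0.5), rot, a = 0.7), nStations = 40,
                      endpointTol = 10)
  expect_equal(fr, f1, tolerance = 1e-9)
  # identical paths: fidelity limited by the sd floor
  fmax <- routeFidelity(replicate(3, straightPath(), simplify = FALSE),
                        sdFloor = 1e-3)
  expect_equal(fmax, 1000)
})
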