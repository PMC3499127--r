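test_that("trajectory CSV round trips are bit-exact and sort-invariant", {
  tr <- quickRing(N = 5, T = 20, params = c(p0 = 0.3), seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(tr, f)
  back <- readTrajectory(f, "ring")
  expect_identical(angles(back), angles(tr))
  expect_identical(directions(back), directions(tr))
  expect_identical(timePoints(back), timePoints(tr))

  # shuffled rows give the identical object
  raw <- read.csv(f, colClasses = "character")
  shuf <- withr::with_seed(1, raw[sample(nrow(raw)), ])
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuf, f2, row.names = FALSE, quote = FALSE)
  back2 <- readTrajectory(f2, "ring")
  expect_identical(angles(back2), angles(back))
  expect_identical(directions(back2), directions(back))

  # planar with speeds
  pl <- planarTrajectory(
    x = matrix(runif(8), 2), y = matrix(runif(8), 2),
    heading = matrix(runif(8, 0, 6), 2), speed = matrix(runif(8), 2),
    dt = 0.5
  )
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(pl, f3)
  pb <- readTrajectory(f3, "planar")
  expect_identical(coordsX(pb), coordsX(pl))
  expect_identical(speeds(pb), speeds(pl))

  # empty trajectory round-trips
  e <- ringTrajectory(matrix(0, 0, 0), matrix(0, 0, 0), times = numeric(0))
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(e, f4)
  eb <- readTrajectory(f4, "ring")
  expect_equal(nAgents(eb), 0L)
  expect_equal(length(timePoints(eb)), 0L)
})

test_that("CW/CCW labels code to -1/+1 and bad inputs raise named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,agent,theta,dir",
               "0,a1,0,CCW", "0.4,a1,0.1,CCW",
               "0,a2,3,CW", "0.4,a2,2.9,CW"), f)
  tr <- readTrajectory(f, "ring")
  expect_equal(unname(directions(tr)[, 1]), c(1, -1))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,agent,theta", "0,a1,0"), f2)
  expect_error(readTrajectory(f2, "ring"), "schema error.*dir")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,agent,theta,dir",
               "0,a1,0,1", "0.4,a1,0.1,1", "1.4,a1,0.2,1"), f3)
  expect_error(readTrajectory(f3, "ring"), "timing error")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,agent,theta,dir", "0,a1,0,left"), f4)
  expect_error(readTrajectory(f4, "ring"), "value error")
})

test_that("extractEvents encodes sign changes with the context at time t", {
  const <- ringTrajectory(matrix(runif(6), 2), matrix(1, 2, 3))
  expect_true(all(eventRecords(extractEvents(const))$y == 0))

  tr <- ringTrajectory(matrix(0.1, 1, 4), matrix(c(1, -1, -1, 1), 1))
  expect_equal(eventRecords(extractEvents(tr))$y, c(1L, 0L, 1L))

  # switch count equals an independent one-line scan; N*(T-1) records
  for (seed in 1:5) {
    tr <- quickRing(N = 6, T = 40, params = c(p0 = 0.2), seed = seed)
    ev <- extractEvents(tr)
    d <- directions(tr)
    expect_equal(sum(eventRecords(ev)$y),
                 sum(d[, -1, drop = FALSE] != d[, -ncol(d), drop = FALSE]))
    expect_equal(nEvents(ev), 6 * 39)
  }

  one <- ringTrajectory(matrix(0, 2, 1), matrix(1, 2, 1))
  expect_error(extractEvents(one), "no transitions")

  # forced switching: p = 1 at every step
  forced <- quickRing(N = 3, T = 30, params = c(p0 = 1), seed = 2)
  expect_true(all(eventRecords(extractEvents(forced))$y == 1))
})

test_that("angularSeparation follows the forward-positive convention", {
  expect_equal(angularSeparation(0, 0, 1), 0)
  expect_equal(angularSeparation(0, pi / 2, 1), pi / 2)
  expect_equal(angularSeparation(0, pi / 2, -1), -pi / 2)

  withr::with_seed(3, {
    a <- runif(300, 0, 2 * pi)
    b <- runif(300, 0, 2 * pi)
    s <- angularSeparation(a, b, 1)
    expect_true(all(s > -pi & s <= pi))
    # antisymmetric under swapping the two agents (same direction)
    interior <- abs(abs(s) - pi) > 1e-9
    expect_equal(angularSeparation(b, a, 1)[interior], -s[interior])
    # negating the focal direction flips the sign
    expect_equal(angularSeparation(a, b, -1)[interior], -s[interior])
  })
})

test_that("trajectory validity rejects out-of-range values", {
  expect_error(ringTrajectory(matrix(7, 1, 2), matrix(1, 1, 2)), "theta")
  expect_error(ringTrajectory(matrix(1, 1, 2), matrix(2, 1, 2)), "dir")
  expect_error(planarTrajectory(matrix(0, 1, 2), matrix(0, 1, 2),
                                matrix(-1, 1, 2)), "heading")
})
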