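# Pheromone trail system: map construction from passages, the Weber's-law
# turning response, a spatially explicit trail-formation simulation with
# deposition and evaporation, double-bridge mean-field choice dynamics, and
# the effective nonlinearity that emerges from repeated interactions with
# the trail.

#' Weber's-law turning parameters
#'
#' @param A Turning gain in degrees per sensing window.
#' @param T0 Detection threshold in pheromone units: concentrations well
#'   below `T0` produce little directed turning.
#' @param noiseSd Angular noise standard deviation in degrees, added when
#'   sampling turns.
#' @return A list of class `weberParams`.
#' @export
weberParams <- function(A = 30.80, T0 = 10.53, noiseSd = 20) {
  stopifnot(is.finite(A), T0 >= 0, noiseSd >= 0)
  structure(list(A = A, T0 = T0, noiseSd = noiseSd), class = "weberParams")
}

#' Sensing-sector geometry
#'
#' Front-left and front-right sectors around an ant's heading. Each sector
#' spans relative bearings `(0, 2 * halfAngle]` (left) and
#' `[-2 * halfAngle, 0)` (right) out to `radius`, so the default
#' `halfAngle = pi/4` makes the two sectors cover the frontal half-plane,
#' split at the heading line.
#'
#' @param radius Sensing radius in arena units.
#' @param halfAngle Sector half-angle in radians, in `(0, pi/2]`.
#' @return A list of class `sectorSpec`.
#' @export
sectorSpec <- function(radius = 5, halfAngle = pi / 4) {
  stopifnot(radius > 0, halfAngle > 0, halfAngle <= pi / 2)
  structure(list(radius = radius, halfAngle = halfAngle), class = "sectorSpec")
}

#' Pheromone mass in the front-left and front-right sectors
#'
#' Sums the grid values of all cells whose centres fall inside the
#' front-left (`L`) and front-right (`R`) sensing sectors of an ant.
#' Rotating the grid and the ant together leaves `(L, R)` unchanged.
#'
#' @param grid A [PheromoneGrid-class].
#' @param ant List or numeric vector with `x`, `y` (world coordinates) and
#'   `heading` (radians).
#' @param spec A [sectorSpec()].
#' @return Named numeric vector `c(L = ..., R = ...)`, both nonnegative.
#' @export
sectorConcentrations <- function(grid, ant, spec = sectorSpec()) {
  v <- gridValues(grid)
  cs <- cellSize(grid)
  org <- gridOrigin(grid)
  x <- ant[["x"]]
  y <- ant[["y"]]
  heading <- ant[["heading"]]
  xmax <- org[1] + nrow(v) * cs
  ymax <- org[2] + ncol(v) * cs
  if (x < org[1] || x > xmax || y < org[2] || y > ymax) {
    stop("boundary error: ant position is outside the grid")
  }
  ri <- ceiling(spec$radius / cs) + 1L
  i0 <- floor((x - org[1]) / cs) + 1L
  j0 <- floor((y - org[2]) / cs) + 1L
  is <- max(1L, i0 - ri):min(nrow(v), i0 + ri)
  js <- max(1L, j0 - ri):min(ncol(v), j0 + ri)
  cx <- org[1] + (is - 0.5) * cs
  cy <- org[2] + (js - 0.5) * cs
  dx <- outer(cx - x, rep(1, length(js)))
  dy <- outer(rep(1, length(is)), cy - y)
  dist <- sqrt(dx^2 + dy^2)
  inside <- dist <= spec$radius & dist > 1e-12
  rel <- .wrapPi(atan2(dy, dx) - heading)
  sub <- v[is, js, drop = FALSE]
  wide <- 2 * spec$halfAngle
  L <- sum(sub[inside & rel > 0 & rel <= wide])
  R <- sum(sub[inside & rel < 0 & rel >= -wide])
  c(L = L, R = R)
}

#' Weber's-law turning angle
#'
#' The deterministic turning response to a left/right pheromone contrast:
#' `alpha = A * (L - R) / (L + R + T0)` degrees, positive towards the left
#' sector. The perceived difference scales inversely with the total
#' stimulus, and `T0` suppresses the response when both concentrations are
#' below the detection threshold. The magnitude never exceeds `A`. When
#' `T0 = 0` and `L = R = 0` the turn is defined as 0.
#'
#' @param L,R Nonnegative pheromone concentrations in the left and right
#'   sectors (vectorised).
#' @param params A [weberParams()].
#' @return Turning angle(s) in degrees.
#' @examples
#' weberTurn(100, 50, weberParams(A = 30.80, T0 = 10.53)) # about 9.59 deg
#' @export
weberTurn <- function(L, R, params = weberParams()) {
  stopifnot(all(L >= 0), all(R >= 0))
  denom <- L + R + params$T0
  ifelse(denom == 0, 0, params$A * (L - R) / denom)
}

#' Build a pheromone map from passages
#'
#' Estimates a pheromone field by accumulating the passages of animals over
#' a lattice: every time-sample of every trajectory deposits
#' `depositPerPassage` into the cell containing it, so total grid mass is
#' exactly `depositPerPassage` times the number of samples. This is the
#' deposit-only (no evaporation) map construction.
#'
#' @param traj A [PlanarTrajectory-class] of one or more animals.
#' @param cellSize Lattice cell edge length in arena units.
#' @param depositPerPassage Mass deposited per time-sample.
#' @param origin Optional world coordinate of the grid corner; defaults to
#'   the floor of the data extent.
#' @param dims Optional integer `c(nx, ny)` grid size; defaults to covering
#'   the data extent.
#' @return A [PheromoneGrid-class].
#' @export
buildPheromoneMap <- function(traj, cellSize = 1, depositPerPassage = 1,
                              origin = NULL, dims = NULL) {
  x <- as.vector(coordsX(traj))
  y <- as.vector(coordsY(traj))
  if (!length(x)) stop("trajectory has no samples")
  if (is.null(origin)) {
    origin <- c(floor(min(x) / cellSize) * cellSize,
                floor(min(y) / cellSize) * cellSize)
  }
  ii <- floor((x - origin[1]) / cellSize) + 1L
  jj <- floor((y - origin[2]) / cellSize) + 1L
  if (is.null(dims)) dims <- c(max(ii), max(jj))
  stopifnot(all(ii >= 1), all(jj >= 1), all(ii <= dims[1]), all(jj <= dims[2]))
  v <- matrix(0, dims[1], dims[2])
  tab <- table(factor(ii, levels = seq_len(dims[1])),
               factor(jj, levels = seq_len(dims[2])))
  v <- v + as.numeric(tab) * depositPerPassage
  dim(v) <- dims
  pheromoneGrid(v, cellSize = cellSize, origin = origin)
}

#' Spatially explicit trail-formation simulation
#'
#' Ants follow Weber's Law on a shared pheromone field: each sensing step
#' (one timestep) an ant integrates the pheromone in its front-left and
#' front-right sectors, turns by [weberTurn()] plus Gaussian angular noise,
#' advances one step length, and deposits pheromone on the cell it occupies;
#' the whole field decays by `1 - evaporation` each step before deposition.
#' Walls reflect. With gain `A = 0` the ants perform noise-driven random
#' walks, the no-interaction control.
#'
#' @param nAnts Number of ants.
#' @param T Number of timesteps.
#' @param weber A [weberParams()].
#' @param sector A [sectorSpec()].
#' @param deposit Pheromone deposited per ant per step.
#' @param evaporation Fraction of the field lost per step, in `[0, 1]`.
#' @param arenaSize Side length of the square arena (arena units).
#' @param cellSize Lattice cell size.
#' @param stepLength Distance advanced per step; defaults to one cell.
#' @param dt Timestep duration in seconds (one sensing window).
#' @param initGrid Optional [PheromoneGrid-class] to start from (e.g. a
#'   pre-seeded trail); defaults to an empty field.
#' @param seed Integer seed.
#' @return List with elements `traj` (a [PlanarTrajectory-class]) and `grid`
#'   (the final [PheromoneGrid-class]).
#' @export
simulateTrail <- function(nAnts = 5, T = 200, weber = weberParams(),
                          sector = sectorSpec(), deposit = 1,
                          evaporation = 0.01, arenaSize = 40, cellSize = 1,
                          stepLength = cellSize, dt = 0.4,
                          initGrid = NULL, seed = NULL) {
  stopifnot(evaporation >= 0, evaporation <= 1, T >= 1, nAnts >= 1)
  nc <- as.integer(ceiling(arenaSize / cellSize))
  grid <- if (is.null(initGrid)) {
    pheromoneGrid(matrix(0, nc, nc), cellSize = cellSize, origin = c(0, 0))
  } else {
    initGrid
  }
  .withSeed(seed, {
    x <- matrix(NA_real_, nAnts, T)
    y <- matrix(NA_real_, nAnts, T)
    h <- matrix(NA_real_, nAnts, T)
    px <- stats::runif(nAnts, 0.1 * arenaSize, 0.9 * arenaSize)
    py <- stats::runif(nAnts, 0.1 * arenaSize, 0.9 * arenaSize)
    ph <- stats::runif(nAnts, 0, 2 * pi)
    v <- gridValues(grid)
    org <- gridOrigin(grid)
    for (t in seq_len(T)) {
      gcur <- pheromoneGrid(v, cellSize = cellSize, origin = org)
      for (a in seq_len(nAnts)) {
        lr <- sectorConcentrations(gcur, list(x = px[a], y = py[a],
                                              heading = ph[a]), sector)
        turn <- weberTurn(lr[["L"]], lr[["R"]], weber) +
          stats::rnorm(1, 0, weber$noiseSd)
        ph[a] <- .wrap2pi(ph[a] + turn * pi / 180)
        nx <- px[a] + stepLength * cos(ph[a])
        ny <- py[a] + stepLength * sin(ph[a])
        if (nx < 0) { nx <- -nx; ph[a] <- .wrap2pi(pi - ph[a]) }
        if (nx > arenaSize) { nx <- 2 * arenaSize - nx; ph[a] <- .wrap2pi(pi - ph[a]) }
        if (ny < 0) { ny <- -ny; ph[a] <- .wrap2pi(-ph[a]) }
        if (ny > arenaSize) { ny <- 2 * arenaSize - ny; ph[a] <- .wrap2pi(-ph[a]) }
        px[a] <- min(max(nx, 1e-9), arenaSize - 1e-9)
        py[a] <- min(max(ny, 1e-9), arenaSize - 1e-9)
      }
      v <- v * (1 - evaporation)
      ii <- floor(px / cellSize) + 1L
      jj <- floor(py / cellSize) + 1L
      for (a in seq_len(nAnts)) v[ii[a], jj[a]] <- v[ii[a], jj[a]] + deposit
      x[, t] <- px
      y[, t] <- py
      h[, t] <- ph
    }
    list(
      traj = planarTrajectory(x, y, h, dt = dt),
      grid = pheromoneGrid(v, cellSize = cellSize, origin = org)
    )
  })
}

#' Reinforcing-loop metric of a pheromone field
#'
#' Quantifies how much of the field's mass sits on closed, re-walked loops:
#' cells strictly above the 90th percentile of cell values are connected by
#' 8-neighbour adjacency, and the metric is the fraction of total grid mass
#' carried by those cells that lie on cycles of that graph (its 2-core).
#' A drawn ring scores 1, a straight segment 0, an empty field 0.
#'
#' @param grid A [PheromoneGrid-class].
#' @param quantileLevel Threshold quantile of cell values (default 0.9).
#' @return Scalar in `[0, 1]`.
#' @export
loopMetric <- function(grid, quantileLevel = 0.9) {
  v <- gridValues(grid)
  tot <- sum(v)
  if (tot <= 0) return(0)
  thr <- stats::quantile(v, quantileLevel, names = FALSE)
  keep <- which(v > thr, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    # flat top decile (e.g. a uniform drawn structure): take the occupied top
    keep <- which(v >= thr & v > 0, arr.ind = TRUE)
  }
  if (nrow(keep) < 3) return(0)
  id <- matrix(0L, nrow(v), ncol(v))
  id[keep] <- seq_len(nrow(keep))
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    i2 <- keep[, 1] + off[1]
    j2 <- keep[, 2] + off[2]
    ok <- i2 >= 1 & i2 <= nrow(v) & j2 >= 1 & j2 <= ncol(v)
    ok[ok] <- id[cbind(i2[ok], j2[ok])] > 0
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[keep[ok, , drop = FALSE]],
                                  id[cbind(i2[ok], j2[ok])]))
    }
  }
  if (is.null(edges) || nrow(edges) == 0) return(0)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(keep) - igraph::vcount(g)))
  onCycle <- igraph::coreness(g) >= 2
  sum(v[keep[onCycle[seq_len(nrow(keep))], , drop = FALSE]]) / tot
}

#' Double-bridge choice dynamics
#'
#' Mean-field ordinary differential equations for the pheromone
#' concentrations on the two branches of a double bridge:
#' `dc_A/dt = flow * P_A - rho * c_A` (and symmetrically for B), with the
#' nonlinear choice function
#' `P_A = (k + c_A)^n / ((k + c_A)^n + (k + c_B)^n)`. With `n = 1` the
#' symmetric state is preserved; for `n = 2` and sufficient flow, positive
#' feedback amplifies any asymmetry until one branch carries nearly all the
#' trail.
#'
#' @param flow Ant flow rate onto the bridge (ants per unit time), > 0.
#' @param n Choice nonlinearity exponent, >= 1.
#' @param k Intrinsic branch attractiveness (pheromone units), > 0.
#' @param rho Pheromone evaporation rate, > 0.
#' @param c0 Initial concentrations `c(cA, cB)`.
#' @param T Integration horizon.
#' @param nOut Number of output timepoints.
#' @return Data frame with columns `time`, `cA`, `cB`.
#' @export
doubleBridge <- function(flow, n = 2, k = 20, rho = 0.05, c0 = c(0, 0),
                         T = 200, nOut = 400) {
  stopifnot(flow > 0, k > 0, rho > 0, n >= 1)
  rhs <- function(t, state, parms) {
    uA <- (k + state[1])^n
    uB <- (k + state[2])^n
    pA <- uA / (uA + uB)
    list(c(flow * pA - rho * state[1],
           flow * (1 - pA) - rho * state[2]))
  }
  out <- deSolve::ode(y = c(cA = c0[1], cB = c0[2]),
                      times = seq(0, T, length.out = nOut), func = rhs,
                      parms = NULL)
  data.frame(time = out[, "time"], cA = out[, "cA"], cB = out[, "cB"])
}

#' Effective choice probability at a Y-junction
#'
#' Monte-Carlo estimate of the probability that an ant entering a symmetric
#' Y-junction commits to the branch with the stronger pheromone deposit,
#' after `nCrossings` Weber's-law sensing steps (each contributing the
#' deterministic turn towards the stronger side plus angular noise). Although
#' a single response is essentially linear in the concentration contrast,
#' integrating over repeated interactions sharpens the choice, producing an
#' effective nonlinearity.
#'
#' @param weber A [weberParams()] (its `noiseSd` drives the stochasticity).
#' @param ratios Concentration ratios (stronger / weaker), each >= 1.
#' @param nCrossings Number of sensing steps before commitment (vectorised).
#' @param nReps Monte-Carlo replicates per combination.
#' @param baseConc Concentration of the weaker branch (pheromone units).
#' @param seed Integer seed.
#' @param conf Confidence level of the Wilson interval.
#' @return Data frame with columns `ratio`, `nCrossings`, `p`, `lower`,
#'   `upper`, `nReps`.
#' @export
effectiveChoiceCurve <- function(weber = weberParams(), ratios = c(1, 1.5, 2, 4),
                                 nCrossings = 1, nReps = 2000, baseConc = 50,
                                 seed = NULL, conf = 0.95) {
  stopifnot(all(ratios >= 1), all(nCrossings >= 1), nReps >= 1)
  combos <- expand.grid(ratio = ratios, nCrossings = nCrossings)
  .withSeed(seed, {
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      r <- combos$ratio[i]
      m <- combos$nCrossings[i]
      drift <- weberTurn(baseConc * r, baseConc, weber)
      total <- m * drift + stats::rnorm(nReps, 0, weber$noiseSd * sqrt(m))
      k <- sum(total > 0) + 0.5 * sum(total == 0)
      ci <- .wilsonCI(k, nReps, conf)
      data.frame(ratio = r, nCrossings = m, p = k / nReps,
                 lower = ci[[1]], upper = ci[[2]], nReps = nReps)
    })
    do.call(rbind, rows)
  })
}

#' Simulate Weber's-law turning observations
#'
#' Generates synthetic (L, R, alpha) triples: concentrations log-uniform on
#' `lRange`, deterministic Weber turn plus Gaussian angular noise. This is
#' the stand-in for the tracked-ant dataset used to exercise parameter
#' recovery.
#'
#' @param n Number of observations.
#' @param params A [weberParams()] (its `noiseSd` is the noise of the
#'   generated turns).
#' @param lRange Concentration range for the log-uniform draw.
#' @param seed Integer seed.
#' @return Data frame with columns `L`, `R`, `alpha` (degrees).
#' @export
simulateWeberObservations <- function(n, params = weberParams(),
                                      lRange = c(1, 1000), seed = NULL) {
  .withSeed(seed, {
    L <- exp(stats::runif(n, log(lRange[1]), log(lRange[2])))
    R <- exp(stats::runif(n, log(lRange[1]), log(lRange[2])))
    alpha <- weberTurn(L, R, params) + stats::rnorm(n, 0, params$noiseSd)
    data.frame(L = L, R = R, alpha = alpha)
  })
}

#' Fit Weber's-law parameters by nonlinear least squares
#'
#' Estimates the turning gain `A` and detection threshold `T0` of the
#' response `alpha = A * (L - R) / (L + R + T0)` from observed turning
#' angles, via Levenberg-Marquardt least squares, with optional bootstrap
#' standard errors.
#'
#' @param data Data frame with columns `L`, `R`, `alpha`.
#' @param start Named starting values for `A` and `T0`.
#' @param bootstrap Number of bootstrap resamples for standard errors
#'   (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `weberFit` with elements `coef` (named `A`, `T0`),
#'   `se` (asymptotic), `bootSe` (or `NULL`), and the underlying `fit`.
#' @export
fitWeber <- function(data, start = c(A = 10, T0 = 1), bootstrap = 0,
                     seed = NULL) {
  fitOnce <- function(d) {
    minpack.lm::nlsLM(alpha ~ A * (L - R) / (L + R + T0),
                      data = d, start = as.list(start),
                      lower = c(A = -1e6, T0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- fitOnce(data)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  bootSe <- NULL
  if (bootstrap > 0) {
    bootSe <- .withSeed(seed, {
      reps <- vapply(seq_len(bootstrap), function(b) {
        idx <- sample.int(nrow(data), replace = TRUE)
        stats::coef(fitOnce(data[idx, , drop = FALSE]))
      }, numeric(2))
      apply(reps, 1, stats::sd)
    })
    names(bootSe) <- names(est)
  }
  structure(list(coef = est, se = se, bootSe = bootSe, fit = fit),
            class = "weberFit")
}
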