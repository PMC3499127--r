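# Route distributions from repeated solo journeys and the weighted-mixture
# predictor for paired journeys: solo paths between fixed endpoints are
# summarised by a station-wise Gaussian cross-track model, paired paths are
# scored under a station-wise mixture of the two partners' distributions,
# and the mixture weight is either constant or a logistic function of route
# fidelity.

# Coerce a path (PlanarTrajectory or n x 2 matrix) to a coordinate matrix.
.pathMatrix <- function(p) {
  if (is(p, "PlanarTrajectory")) {
    cbind(as.vector(coordsX(p)[1, ]), as.vector(coordsY(p)[1, ]))
  } else {
    m <- as.matrix(p)
    stopifnot(ncol(m) == 2)
    m
  }
}

# Resample a path to n stations equally spaced in arc length (linear
# interpolation).
.resampleArc <- function(m, nStations) {
  seg <- sqrt(rowSums(diff(m)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) {
    return(matrix(rep(m[1, ], each = nStations), nStations, 2))
  }
  grid <- seq(0, s[length(s)], length.out = nStations)
  cbind(stats::approx(s, m[, 1], xout = grid, ties = "ordered")$y,
        stats::approx(s, m[, 2], xout = grid, ties = "ordered")$y)
}

# Unit normals of a station path (left of the direction of travel).
.stationNormals <- function(st) {
  n <- nrow(st)
  tx <- c(st[2, 1] - st[1, 1], st[3:n, 1] - st[1:(n - 2), 1],
          st[n, 1] - st[n - 1, 1])
  ty <- c(st[2, 2] - st[1, 2], st[3:n, 2] - st[1:(n - 2), 2],
          st[n, 2] - st[n - 1, 2])
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(-ty / len, tx / len)
}

# Cross-track deviations of a path from a station path. A path that already
# has one point per station is used as-is (stations correspond one-to-one);
# otherwise it is resampled by arc length first.
.crossTrackDev <- function(pathMat, st, normals = .stationNormals(st)) {
  res <- if (nrow(pathMat) == nrow(st)) pathMat else .resampleArc(pathMat, nrow(st))
  rowSums((res - st) * normals)
}

#' Fit a route distribution from repeated solo paths
#'
#' Resamples each path to a fixed number of stations equally spaced in arc
#' length, and summarises the ensemble by the station-wise mean path and the
#' cross-track standard deviation (deviation perpendicular to the mean
#' path's local direction). The standard deviation uses the divide-by-n
#' form and is floored at `sdFloor` so identical paths yield a proper
#' distribution.
#'
#' @param paths List of at least two paths ([PlanarTrajectory-class] or
#'   n x 2 coordinate matrices) sharing endpoints.
#' @param nStations Number of arc-length stations.
#' @param sdFloor Minimum cross-track sd (arena units).
#' @param endpointTol Maximum allowed spread of the release and home points
#'   across paths; defaults to 10 percent of the median path length.
#' @return A [RouteDistribution-class].
#' @export
fitRouteDistribution <- function(paths, nStations = 100, sdFloor = 1e-3,
                                 endpointTol = NULL) {
  if (length(paths) < 2) stop("need at least 2 paths")
  mats <- lapply(paths, .pathMatrix)
  lens <- vapply(mats, function(m) sum(sqrt(rowSums(diff(m)^2))), numeric(1))
  if (is.null(endpointTol)) endpointTol <- 0.1 * stats::median(lens)
  starts <- t(vapply(mats, function(m) m[1, ], numeric(2)))
  ends <- t(vapply(mats, function(m) m[nrow(m), ], numeric(2)))
  spread <- function(pts) max(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  if (spread(starts) > endpointTol || spread(ends) > endpointTol) {
    stop("endpoint mismatch: paths do not share release and home points ",
         "within tolerance ", signif(endpointTol, 3))
  }
  # paths already sampled at one point per station are used as-is, matching
  # the station correspondence used by the likelihood
  res <- lapply(mats, function(m) {
    if (nrow(m) == nStations) m else .resampleArc(m, nStations)
  })
  arr <- simplify2array(res) # nStations x 2 x nPaths
  st <- apply(arr, c(1, 2), mean)
  normals <- .stationNormals(st)
  dev <- vapply(res, function(r) rowSums((r - st) * normals), numeric(nStations))
  sdv <- pmax(sqrt(rowMeans(dev^2)), sdFloor)
  new("RouteDistribution", stations = st, crossTrackSd = sdv,
      nPaths = length(paths))
}

#' Log-likelihood of a path under a route distribution
#'
#' Sum over stations of the Gaussian cross-track log-density of the path's
#' deviation from the distribution's mean path. The mean path itself attains
#' the maximum achievable value; displacing a path by one standard deviation
#' at every station lowers the value by exactly `nStations / 2`.
#'
#' @param path A path ([PlanarTrajectory-class] or n x 2 matrix).
#' @param dist A [RouteDistribution-class].
#' @return The log-likelihood.
#' @export
pathLogLik <- function(path, dist) {
  dev <- .crossTrackDev(.pathMatrix(path), stations(dist))
  sum(stats::dnorm(dev, 0, crossTrackSd(dist), log = TRUE))
}

#' Log-likelihood of a path under a two-bird mixture
#'
#' Scores a paired journey as a station-wise weighted mixture of two solo
#' route distributions: the sum over stations of
#' `log(w * phi1 + (1 - w) * phi2)`, where `phi_i` is the cross-track
#' density under distribution `i`. Swapping the distributions and replacing
#' `w` by `1 - w` leaves the value unchanged, and the value is concave in
#' `w`.
#'
#' @param path A path.
#' @param dist1,dist2 [RouteDistribution-class] objects with equal station
#'   counts.
#' @param w Mixture weight on `dist1`, in `[0, 1]`.
#' @return The mixture log-likelihood.
#' @export
pairMixtureLogLik <- function(path, dist1, dist2, w) {
  stopifnot(w >= 0, w <= 1,
            nrow(stations(dist1)) == nrow(stations(dist2)))
  m <- .pathMatrix(path)
  ld1 <- stats::dnorm(.crossTrackDev(m, stations(dist1)), 0,
                      crossTrackSd(dist1), log = TRUE)
  ld2 <- stats::dnorm(.crossTrackDev(m, stations(dist2)), 0,
                      crossTrackSd(dist2), log = TRUE)
  a <- log(w) + ld1
  b <- log(1 - w) + ld2
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  sum(ifelse(is.infinite(hi) & hi < 0, lo, hi + log1p(exp(lo - hi))))
}

#' Route fidelity
#'
#' A bird's loyalty to its own route, operationalised as the reciprocal of
#' the mean station-wise cross-track standard deviation of its solo paths:
#' higher values mean more repeatable routes. Invariant under rigid motions
#' of the whole path set.
#'
#' @param paths List of at least two solo paths, or a
#'   [RouteDistribution-class].
#' @param ... Passed to [fitRouteDistribution()] when `paths` is a list.
#' @return A positive scalar.
#' @export
routeFidelity <- function(paths, ...) {
  dist <- if (is(paths, "RouteDistribution")) paths
          else fitRouteDistribution(paths, ...)
  1 / mean(crossTrackSd(dist))
}

#' Fit the pair-mixture weight model
#'
#' Maximises the summed mixture log-likelihood of paired journeys over the
#' weight model's parameters: either a single constant weight `w`, or a
#' logistic model `w_i = plogis(a + b * fidelity_i)` in which a bird's route
#' fidelity sets how strongly its own distribution dominates. The 1-D
#' constant fit uses a grid plus golden-section refinement (the objective is
#' concave in `w`); the logistic fit uses a multi-start simplex search.
#' BIC and a BIC-based log marginal are reported for comparison between the
#' two weight models.
#'
#' @param paths List of paired-journey paths.
#' @param dist1,dist2 The two partners' solo distributions: single
#'   [RouteDistribution-class] objects, or lists of them (one per path).
#' @param model `"constant"` or `"fidelity"`.
#' @param fidelity Numeric vector of per-path fidelity covariates (required
#'   for the `"fidelity"` model).
#' @param nGrid Grid size of the constant-weight scan.
#' @return List of class `pairWeightFit`: `kind`, `params`, `weights` (per
#'   path), `logLik`, `nParams`, `nObs`, `bic`, `logMarginal`, `converged`.
#' @export
fitPairWeight <- function(paths, dist1, dist2,
                          model = c("constant", "fidelity"),
                          fidelity = NULL, nGrid = 200) {
  model <- match.arg(model)
  if (!length(paths)) stop("need at least one paired path")
  d1 <- if (is(dist1, "RouteDistribution")) rep(list(dist1), length(paths)) else dist1
  d2 <- if (is(dist2, "RouteDistribution")) rep(list(dist2), length(paths)) else dist2
  stopifnot(length(d1) == length(paths), length(d2) == length(paths))
  nObs <- sum(vapply(d1, function(d) nrow(stations(d)), numeric(1)))
  sumLL <- function(wvec) {
    sum(vapply(seq_along(paths), function(i) {
      pairMixtureLogLik(paths[[i]], d1[[i]], d2[[i]], wvec[i])
    }, numeric(1)))
  }
  eps <- 1e-6
  if (model == "constant") {
    grid <- seq(eps, 1 - eps, length.out = nGrid)
    gll <- vapply(grid, function(w) sumLL(rep(w, length(paths))), numeric(1))
    gi <- which.max(gll)
    loB <- grid[max(1, gi - 1)]
    hiB <- grid[min(nGrid, gi + 1)]
    opt <- stats::optimize(function(w) sumLL(rep(w, length(paths))),
                           lower = loB, upper = hiB, maximum = TRUE,
                           tol = 1e-9)
    w <- opt$maximum
    ll <- opt$objective
    params <- c(w = w)
    weights <- rep(w, length(paths))
    converged <- TRUE
  } else {
    if (is.null(fidelity) || length(fidelity) != length(paths)) {
      stop("the fidelity model needs one fidelity value per path")
    }
    fs <- fidelity
    obj <- function(par) sumLL(stats::plogis(par[1] + par[2] * fs))
    best <- NULL
    for (st in list(c(0, 0), c(0, 1), c(0, -1), c(1, 0))) {
      res <- stats::optim(st, function(p) -obj(p), method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best) || res$value < best$value) best <- res
    }
    params <- c(a = best$par[1], b = best$par[2])
    ll <- -best$value
    weights <- stats::plogis(params[["a"]] + params[["b"]] * fs)
    converged <- best$convergence == 0
  }
  k <- length(params)
  structure(list(kind = model, params = params, weights = weights,
                 logLik = ll, nParams = k, nObs = nObs,
                 bic = k * log(nObs) - 2 * ll,
                 logMarginal = ll - (k / 2) * log(nObs),
                 converged = converged),
            class = "pairWeightFit")
}

#' Simulate solo route paths
#'
#' Generates repeated solo journeys as a base path plus independent Gaussian
#' cross-track noise at each station; the release and home endpoints are
#' held fixed. The synthetic stand-in for repeated homing flights.
#'
#' @param basePath n x 2 matrix (or [PlanarTrajectory-class]) of the bird's
#'   habitual route.
#' @param sd Cross-track noise standard deviation (scalar or per station).
#' @param nPaths Number of paths.
#' @param nStations Stations for resampling the base path.
#' @param seed Integer seed.
#' @return List of `nStations x 2` path matrices.
#' @export
simulateRoutePaths <- function(basePath, sd, nPaths, nStations = 100,
                               seed = NULL) {
  st <- .resampleArc(.pathMatrix(basePath), nStations)
  normals <- .stationNormals(st)
  sdv <- rep_len(sd, nStations)
  .withSeed(seed, {
    lapply(seq_len(nPaths), function(i) {
      dev <- stats::rnorm(nStations, 0, sdv)
      dev[c(1, nStations)] <- 0
      st + dev * normals
    })
  })
}

#' Simulate a paired journey from a two-bird mixture
#'
#' Draws a paired path station-by-station: with probability `w` the
#' cross-track position follows bird 1's distribution, otherwise bird 2's.
#'
#' @param dist1,dist2 [RouteDistribution-class] objects (equal station
#'   counts).
#' @param w Mixture weight on `dist1`.
#' @param seed Integer seed.
#' @return An `nStations x 2` path matrix.
#' @export
simulatePairedPath <- function(dist1, dist2, w, seed = NULL) {
  n <- nrow(stations(dist1))
  stopifnot(n == nrow(stations(dist2)))
  .withSeed(seed, {
    pick <- stats::runif(n) < w
    z1 <- stats::rnorm(n, 0, crossTrackSd(dist1))
    z2 <- stats::rnorm(n, 0, crossTrackSd(dist2))
    p1 <- stations(dist1) + z1 * .stationNormals(stations(dist1))
    p2 <- stations(dist2) + z2 * .stationNormals(stations(dist2))
    ifelse(cbind(pick, pick), p1, p2)
  })
}
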