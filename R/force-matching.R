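# Least-squares "force matching" for planar interaction models: candidate
# laws map the neighbour configuration to a predicted heading change and are
# linear in their parameters, so fitting is exact linear algebra and the
# generating law can be told apart from incorrect alternatives with few
# observations.

# Min-image displacements for an optionally periodic box.
.pairDisp <- function(x, y, box = NULL) {
  dx <- outer(x, x, function(a, b) b - a)
  dy <- outer(y, y, function(a, b) b - a)
  if (!is.null(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
  }
  list(dx = dx, dy = dy, dist = sqrt(dx^2 + dy^2))
}

#' Alignment force feature
#'
#' Returns a feature function for [forceMatchingFit()]: the sine of the
#' difference between the circular-mean heading of the neighbours within
#' `radius` and the focal heading (0 with no neighbours). A heading change
#' proportional to this feature turns the focal agent towards the group
#' direction.
#'
#' @param radius Interaction radius (arena units).
#' @return A function `f(state, box)` returning one feature per agent.
#' @export
forceLawAlignment <- function(radius = 2) {
  force(radius)
  function(state, box = NULL) {
    pd <- .pairDisp(state$x, state$y, box)
    nb <- pd$dist <= radius & pd$dist > 0
    vapply(seq_along(state$x), function(i) {
      j <- which(nb[i, ])
      if (!length(j)) return(0)
      mh <- atan2(mean(sin(state$heading[j])), mean(cos(state$heading[j])))
      sin(mh - state$heading[i])
    }, numeric(1))
  }
}

#' Attraction force feature
#'
#' Feature function: the sine of the bearing from the focal agent to the
#' centroid of its neighbours within `radius`, relative to the focal heading
#' (0 with no neighbours). A positive coefficient turns agents towards their
#' neighbours.
#'
#' @param radius Interaction radius (arena units).
#' @return A function `f(state, box)` returning one feature per agent.
#' @export
forceLawAttraction <- function(radius = 2) {
  force(radius)
  function(state, box = NULL) {
    pd <- .pairDisp(state$x, state$y, box)
    nb <- pd$dist <= radius & pd$dist > 0
    vapply(seq_along(state$x), function(i) {
      j <- which(nb[i, ])
      if (!length(j)) return(0)
      sin(atan2(mean(pd$dy[i, j]), mean(pd$dx[i, j])) - state$heading[i])
    }, numeric(1))
  }
}

#' Simulate planar agents under linear-in-parameter turning laws
#'
#' Generates a [PlanarTrajectory-class] in a periodic square: each step the
#' heading change of every agent is the coefficient-weighted sum of the
#' supplied features plus Gaussian noise, and positions advance at constant
#' speed along the new heading.
#'
#' @param N,T Agents and timesteps.
#' @param laws Named list of feature functions (e.g. from
#'   [forceLawAlignment()]).
#' @param coefs Named numeric coefficients matching `laws` (radians per
#'   unit feature).
#' @param noiseSd Heading noise standard deviation (radians).
#' @param L Periodic box side.
#' @param v Speed.
#' @param dt Timestep (seconds).
#' @param seed Integer seed.
#' @return A [PlanarTrajectory-class].
#' @export
simulatePlanarInteraction <- function(N = 10, T = 100, laws, coefs,
                                      noiseSd = 0.05, L = 10, v = 0.2,
                                      dt = 1, seed = NULL) {
  stopifnot(identical(sort(names(laws)), sort(names(coefs))))
  .withSeed(seed, {
    x <- matrix(NA_real_, N, T)
    y <- matrix(NA_real_, N, T)
    h <- matrix(NA_real_, N, T)
    x[, 1] <- stats::runif(N, 0, L)
    y[, 1] <- stats::runif(N, 0, L)
    h[, 1] <- stats::runif(N, 0, 2 * pi)
    for (t in seq_len(T - 1)) {
      state <- list(x = x[, t], y = y[, t], heading = h[, t])
      dtheta <- numeric(N)
      for (nm in names(laws)) {
        dtheta <- dtheta + coefs[[nm]] * laws[[nm]](state, box = L)
      }
      if (noiseSd > 0) dtheta <- dtheta + stats::rnorm(N, 0, noiseSd)
      h[, t + 1] <- .wrap2pi(h[, t] + dtheta)
      x[, t + 1] <- (x[, t] + v * dt * cos(h[, t + 1])) %% L
      y[, t + 1] <- (y[, t] + v * dt * sin(h[, t + 1])) %% L
    }
    planarTrajectory(x, y, h, dt = dt)
  })
}

#' Least-squares force matching of candidate interaction laws
#'
#' Fits each candidate model (a set of linear-in-parameter features) to the
#' observed per-step heading changes of a planar trajectory by ordinary
#' least squares, and reports coefficients, residual sum of squares and
#' residual degrees of freedom per model. A rank-deficient design is solved
#' by the minimum-norm solution and flagged.
#'
#' @param traj A [PlanarTrajectory-class] with at least 3 timepoints.
#' @param candidates Named list of candidate models; each candidate is a
#'   feature function or a named list of feature functions.
#' @param box Periodic box side, or `NULL` for an open plane.
#' @return Named list per candidate: `coef`, `rss`, `df`, `rank`,
#'   `rankDeficient`.
#' @export
forceMatchingFit <- function(traj, candidates, box = NULL) {
  stopifnot(nSteps(traj) >= 3)
  X <- coordsX(traj)
  Y <- coordsY(traj)
  H <- headings(traj)
  nT <- ncol(H)
  resp <- as.vector(.wrapPi(H[, -1, drop = FALSE] - H[, -nT, drop = FALSE]))
  states <- lapply(seq_len(nT - 1), function(t) {
    list(x = X[, t], y = Y[, t], heading = H[, t])
  })
  out <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    if (is.function(cand)) cand <- stats::setNames(list(cand), nm)
    design <- do.call(cbind, lapply(cand, function(fl) {
      as.vector(vapply(states, fl, numeric(nrow(H)), box = box))
    }))
    colnames(design) <- names(cand)
    qrd <- qr(design)
    rankDef <- qrd$rank < ncol(design)
    coef <- if (!rankDef) {
      qr.coef(qrd, resp)
    } else {
      sv <- svd(design)
      pos <- sv$d > max(sv$d) * 1e-10
      drop(sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% resp) / sv$d[pos]))
    }
    names(coef) <- colnames(design)
    rss <- sum((resp - design %*% coef)^2)
    out[[nm]] <- list(coef = coef, rss = rss,
                      df = length(resp) - qrd$rank, rank = qrd$rank,
                      rankDeficient = rankDef)
  }
  out
}
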