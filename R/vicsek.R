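# Minimal alignment-in-radius self-propelled particle model (the classic
# angular-noise variant): each particle adopts the circular mean heading of
# all particles within a fixed radius (itself included) plus uniform angular
# noise, then advances at constant speed on a periodic square. This is the
# theory-driven reference model for the order-parameter phase transition.

#' Assemble an alignment-model configuration
#'
#' @param N Number of particles.
#' @param L Side length of the periodic square arena.
#' @param v Particle speed (arena units per second).
#' @param r Interaction radius.
#' @param eta Angular noise amplitude in `[0, 2*pi]`: noise is uniform on
#'   `[-eta/2, +eta/2]`.
#' @param dt Timestep (seconds).
#' @param T Number of timesteps.
#' @param seed Integer seed; `NULL` draws from the current stream.
#' @return A list of class `vicsekConfig`.
#' @export
vicsekConfig <- function(N = 100, L = 10, v = 0.5, r = 1, eta = 2,
                         dt = 1, T = 200, seed = NULL) {
  stopifnot(N >= 1, L > 0, v > 0, r > 0, eta >= 0, eta <= 2 * pi, T >= 1)
  structure(list(N = as.integer(N), L = L, v = v, r = r, eta = eta,
                 dt = dt, T = as.integer(T), seed = seed),
            class = "vicsekConfig")
}

#' One synchronous update of the alignment model
#'
#' Each particle's new heading is the circular mean (vector sum) of the
#' headings of all particles within distance `r` under the periodic metric,
#' itself included, plus uniform noise on `[-eta/2, +eta/2]`; ties (a zero
#' resultant) retain the particle's previous heading. The position then
#' advances by `v * dt` along the new heading, wrapped periodically.
#'
#' @param state List with numeric vectors `x`, `y`, `heading`.
#' @param config A [vicsekConfig()].
#' @return The updated state list.
#' @export
vicsekStep <- function(state, config) {
  L <- config$L
  dx <- outer(state$x, state$x, "-")
  dy <- outer(state$y, state$y, "-")
  dx <- dx - L * round(dx / L)
  dy <- dy - L * round(dy / L)
  nb <- (dx^2 + dy^2) <= config$r^2
  C <- nb %*% cos(state$heading)
  S <- nb %*% sin(state$heading)
  newh <- ifelse(abs(C) < 1e-12 & abs(S) < 1e-12,
                 state$heading, atan2(S, C))
  if (config$eta > 0) {
    newh <- newh + stats::runif(length(newh), -config$eta / 2, config$eta / 2)
  }
  newh <- .wrap2pi(as.numeric(newh))
  list(
    x = (state$x + config$v * config$dt * cos(newh)) %% L,
    y = (state$y + config$v * config$dt * sin(newh)) %% L,
    heading = newh
  )
}

#' Simulate the alignment model
#'
#' @param config A [vicsekConfig()]; alternatively pass its arguments via
#'   `...`.
#' @param init Optional initial state list (`x`, `y`, `heading`); by default
#'   positions are uniform on the arena and headings uniform on `[0, 2*pi)`.
#' @param ... Arguments forwarded to [vicsekConfig()] when `config` is
#'   missing.
#' @return A [PlanarTrajectory-class] with a constant-speed `speed` assay.
#' @export
simulateVicsek <- function(config = NULL, init = NULL, ...) {
  if (is.null(config)) config <- vicsekConfig(...)
  N <- config$N
  nT <- config$T
  .withSeed(config$seed, {
    state <- if (is.null(init)) {
      list(x = stats::runif(N, 0, config$L), y = stats::runif(N, 0, config$L),
           heading = stats::runif(N, 0, 2 * pi))
    } else {
      init
    }
    x <- matrix(NA_real_, N, nT)
    y <- matrix(NA_real_, N, nT)
    h <- matrix(NA_real_, N, nT)
    x[, 1] <- state$x
    y[, 1] <- state$y
    h[, 1] <- .wrap2pi(state$heading)
    for (t in seq_len(nT - 1)) {
      state <- vicsekStep(state, config)
      x[, t + 1] <- state$x
      y[, t + 1] <- state$y
      h[, t + 1] <- state$heading
    }
    planarTrajectory(x, y, h, dt = config$dt,
                     speed = matrix(config$v, N, nT))
  })
}

#' Polar order parameter
#'
#' The magnitude of the mean unit heading vector,
#' `|sum_i (cos theta_i, sin theta_i)| / N`: 0 for a fully disordered group,
#' 1 for perfect alignment. For `N` independent uniform headings the expected
#' value is approximately `sqrt(pi) / (2 sqrt(N))`.
#'
#' @param x A numeric vector of headings (radians), or a
#'   [PlanarTrajectory-class], in which case one value per timepoint is
#'   returned.
#' @return Scalar in `[0, 1]`, or a vector of them.
#' @export
orderParameter <- function(x) {
  if (is(x, "PlanarTrajectory")) {
    h <- headings(x)
    return(sqrt(colMeans(cos(h))^2 + colMeans(sin(h))^2))
  }
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

#' Scan the order parameter across noise or density
#'
#' Runs replicate simulations over a grid of noise amplitudes (or particle
#' counts, i.e. densities at fixed arena size) and reports the time-averaged
#' post-burn-in order parameter with its standard error across replicates.
#'
#' @param config Base [vicsekConfig()]; its `seed` anchors replicate seeds.
#' @param etaGrid Numeric vector of noise amplitudes to scan, or `NULL`.
#' @param densityGrid Integer vector of particle counts to scan (density
#'   `N / L^2` at fixed `L`), or `NULL`. Exactly one grid must be given.
#' @param burnIn Timesteps discarded before averaging (`burnIn < T`).
#' @param nReps Replicates per grid point.
#' @return Data frame with columns `eta` or `N`, `mean`, `se`, `nReps`.
#' @export
scanTransition <- function(config, etaGrid = NULL, densityGrid = NULL,
                           burnIn = 50, nReps = 5) {
  if (is.null(etaGrid) == is.null(densityGrid)) {
    stop("supply exactly one of etaGrid or densityGrid")
  }
  stopifnot(burnIn < config$T, nReps >= 1)
  grid <- if (is.null(etaGrid)) densityGrid else etaGrid
  var <- if (is.null(etaGrid)) "N" else "eta"
  baseSeed <- if (is.null(config$seed)) stats::runif(1, 1, 2^30) else config$seed
  out <- lapply(seq_along(grid), function(g) {
    cfg <- config
    cfg[[var]] <- if (var == "N") as.integer(grid[g]) else grid[g]
    vals <- vapply(seq_len(nReps), function(rep) {
      cfg$seed <- deriveSeed(baseSeed, paste0("scan-", var, "-", g), rep)
      phi <- orderParameter(simulateVicsek(cfg))
      mean(phi[(burnIn + 1):length(phi)])
    }, numeric(1))
    data.frame(grid = grid[g], mean = mean(vals),
               se = stats::sd(vals) / sqrt(nReps), nReps = nReps)
  })
  res <- do.call(rbind, out)
  names(res)[1] <- var
  res
}
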