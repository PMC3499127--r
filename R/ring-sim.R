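# Stochastic simulator of N agents moving on a ring with pluggable
# direction-switching rules. The update is synchronous: all switch decisions
# at step t read the configuration at step t, matching the factorisation of
# the sequence likelihood used by the inference engine. Agents are points and
# pass through one another; interactions act only through the switch
# probability.

#' Assemble a ring-simulation configuration
#'
#' @param N Number of agents.
#' @param T Number of timesteps (at least 2).
#' @param dt Timestep duration in seconds. The default 0.4 s matches the
#'   sensing window used throughout the package.
#' @param omega Angular speed (radians per second). The default completes a
#'   lap of the ring in about 200 steps.
#' @param model Name of a registered switching model (see
#'   [switchingModels()]).
#' @param params Named numeric vector of model parameters.
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param init Initial direction scheme: `"random"` (independent fair coin),
#'   `"all_cw"` (every agent clockwise) or `"half"` (first half clockwise,
#'   rest counter-clockwise).
#' @return A list of class `ringSimConfig`.
#' @export
ringSimConfig <- function(N = 8, T = 500, dt = 0.4, omega = 2 * pi / (200 * dt),
                          model = "zone",
                          params = c(p0 = 0.02, p1 = 0.2, w = pi),
                          seed = NULL, init = c("random", "all_cw", "half")) {
  init <- match.arg(init)
  stopifnot(N >= 1, T >= 2, omega > 0, dt > 0)
  getSwitchingModel(model) # registry error surfaces here
  structure(list(N = as.integer(N), T = as.integer(T), dt = dt, omega = omega,
                 model = model, params = params, seed = seed, init = init),
            class = "ringSimConfig")
}

# Per-step switch probabilities with memory threading for the built-in
# non-Markovian rules. `mem` is the per-agent memory vector (refractory
# counter for d1, encounter trace for d2); returns list(p, mem).
.ringStepProb <- function(model, params, ctx, mem) {
  rec <- as.data.frame(ctx, stringsAsFactors = FALSE)
  if (!model@requiresMemory) {
    return(list(p = model@probFn(params, rec), mem = mem))
  }
  enc <- .zoneTrigger(rec, params[["w"]])
  if (model@name == "d1") {
    mem <- ifelse(enc, params[["tau"]], pmax(mem - 1, 0))
    p <- .clipProb(ifelse(mem > 0, params[["p1"]], params[["p0"]]))
  } else if (model@name == "d2") {
    mem <- (1 - params[["lam"]]) * mem + as.numeric(enc)
    p <- .clipProb(params[["p0"]] + params[["k"]] * mem)
  } else {
    stop("simulation of custom memory model ", sQuote(model@name),
         " is not supported")
  }
  list(p = p, mem = mem)
}

#' Simulate ring agents with a switching model
#'
#' Advances `N` point agents on a circle: positions follow
#' `theta <- (theta + dir * omega * dt) mod 2*pi` and each agent
#' independently reverses its travel direction with the probability its
#' switching model assigns to the current configuration. Identical
#' configuration and seed give a bit-identical trajectory.
#'
#' @param config A [ringSimConfig()] list; alternatively pass the same
#'   arguments directly through `...`.
#' @param ... Arguments forwarded to [ringSimConfig()] when `config` is
#'   missing.
#' @return A [RingTrajectory-class].
#' @examples
#' tr <- simulateRing(ringSimConfig(N = 4, T = 50, seed = 1))
#' clockwiseCount(tr)[1:5]
#' @export
simulateRing <- function(config = NULL, ...) {
  if (is.null(config)) config <- ringSimConfig(...)
  model <- getSwitchingModel(config$model)
  N <- config$N
  nT <- config$T
  .withSeed(config$seed, {
    theta <- matrix(NA_real_, N, nT)
    dirs <- matrix(NA_real_, N, nT)
    theta[, 1] <- stats::runif(N, 0, 2 * pi)
    dirs[, 1] <- switch(config$init,
      random = sample(c(-1, 1), N, replace = TRUE),
      all_cw = rep(-1, N),
      half = rep(c(-1, 1), c(ceiling(N / 2), floor(N / 2)))
    )
    mem <- numeric(N)
    for (t in seq_len(nT - 1)) {
      ctx <- ringContext(theta[, t], dirs[, t])
      sp <- .ringStepProb(model, config$params, ctx, mem)
      mem <- sp$mem
      switch_now <- stats::runif(N) < sp$p
      dirs[, t + 1] <- ifelse(switch_now, -dirs[, t], dirs[, t])
      theta[, t + 1] <- .wrap2pi(theta[, t] + dirs[, t] * config$omega * config$dt)
    }
    ringTrajectory(theta, dirs, dt = config$dt)
  })
}

#' Number of clockwise agents over time
#'
#' @param traj A [RingTrajectory-class].
#' @return Integer vector: at each timepoint, how many agents travel
#'   clockwise (`dir = -1`).
#' @export
clockwiseCount <- function(traj) {
  stopifnot(is(traj, "RingTrajectory"))
  as.integer(colSums(directions(traj) == -1))
}

#' Ring alignment order parameter
#'
#' `|2 f_cw - 1|` per timepoint, where `f_cw` is the clockwise fraction:
#' 0 for a perfectly mixed group, 1 for full alignment in either rotational
#' sense.
#'
#' @param traj A [RingTrajectory-class] with at least one agent.
#' @return Numeric vector in `[0, 1]`, one value per timepoint.
#' @export
alignmentOrder <- function(traj) {
  n <- nAgents(traj)
  stopifnot(n >= 1)
  abs(2 * clockwiseCount(traj) / n - 1)
}

#' Ensemble distribution of the clockwise count
#'
#' Repeats a ring simulation `nRuns` times (with per-run seeds derived from
#' the configuration seed) and tabulates, for every timepoint, the
#' distribution of the number of clockwise agents across runs.
#'
#' @param config A [ringSimConfig()]; its `seed` anchors the per-run seeds.
#' @param nRuns Number of replicate runs (at least 1).
#' @return A `T x (N + 1)` matrix; row `t`, column `k + 1` holds the fraction
#'   of runs with exactly `k` clockwise agents at timepoint `t`. Rows sum
#'   to 1.
#' @export
ensembleHistogram <- function(config, nRuns) {
  stopifnot(nRuns >= 1)
  N <- config$N
  counts <- matrix(0, config$T, N + 1,
                   dimnames = list(NULL, as.character(0:N)))
  baseSeed <- if (is.null(config$seed)) stats::runif(1, 1, 2^30) else config$seed
  for (run in seq_len(nRuns)) {
    cfg <- config
    cfg$seed <- deriveSeed(baseSeed, "ensemble", run)
    cw <- clockwiseCount(simulateRing(cfg))
    idx <- cbind(seq_along(cw), cw + 1L)
    counts[idx] <- counts[idx] + 1
  }
  counts / nRuns
}
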