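# The candidate family of direction-switching rules. Each rule maps the
# neighbour context of a focal ring agent to a per-timestep probability of
# reversing travel direction; non-Markovian rules additionally thread a
# per-agent memory state through time. All probabilities are clipped to
# [1e-9, 1 - 1e-9] so that sequence log-likelihoods stay finite.

.modelRegistry <- new.env(parent = emptyenv())

#' Register a switching model
#'
#' Adds a [SwitchingModel-class] to the package registry under its name,
#' making it available to [simulateRing()], [fitMLE()] and [rankModels()].
#' The registry is pluggable: alternative memory mechanisms can be added
#' without touching the fitting engine.
#'
#' @param model A [SwitchingModel-class] object.
#' @return The model, invisibly.
#' @export
registerSwitchingModel <- function(model) {
  stopifnot(is(model, "SwitchingModel"))
  validObject(model)
  .modelRegistry[[model@name]] <- model
  invisible(model)
}

#' List registered switching models
#'
#' @return Character vector of registered model names.
#' @export
switchingModels <- function() sort(ls(.modelRegistry))

#' Look up a switching model by name
#'
#' @param name Model name, or a [SwitchingModel-class] (returned unchanged).
#' @return A [SwitchingModel-class].
#' @export
getSwitchingModel <- function(name) {
  if (is(name, "SwitchingModel")) return(name)
  m <- .modelRegistry[[name]]
  if (is.null(m)) {
    stop("unknown switching model ", sQuote(name), "; registered models: ",
         paste(switchingModels(), collapse = ", "))
  }
  m
}

# Coerce a context argument (SwitchEvents, data.frame or list) to a record
# data frame.
.ctxRecords <- function(context) {
  if (is(context, "SwitchEvents")) return(eventRecords(context))
  if (is.data.frame(context)) return(context)
  as.data.frame(context, stringsAsFactors = FALSE)
}

# Contiguous per-agent index blocks of an ordered record table.
.agentBlocks <- function(agent) {
  if (!length(agent)) return(list())
  r <- rle(as.character(agent))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(seq.int, starts, ends)
}

# Zone membership: is there an opposite-direction agent within the zone?
# Forward-only by default (the zone extends ahead of the focal agent);
# symmetric = TRUE uses a +/- w zone around the focal agent.
.zoneTrigger <- function(rec, w, symmetric = FALSE) {
  if (symmetric) {
    !is.na(rec$s_near) & abs(rec$s_near) <= w
  } else {
    is.finite(rec$s_fwd) & rec$s_fwd <= w
  }
}

# Per-record time since the last encounter within each agent block.
.timeSinceEncounter <- function(enc, blocks) {
  n <- length(enc)
  u <- integer(n)
  ever <- logical(n)
  for (b in blocks) {
    idx <- seq_along(b)
    last <- cummax(ifelse(enc[b], idx, 0L))
    u[b] <- idx - last
    ever[b] <- last > 0L
  }
  list(u = u, ever = ever)
}

# Recursive exponential trace M_t = (1 - lam) M_{t-1} + enc_t, reset per agent.
.encounterTrace <- function(enc, lam, blocks) {
  m <- numeric(length(enc))
  for (b in blocks) {
    m[b] <- as.numeric(stats::filter(as.numeric(enc[b]), 1 - lam,
                                     method = "recursive"))
  }
  m
}

#' Mean-field switching probability
#'
#' The global-configuration baseline: the switch probability rises linearly
#' with the fraction of all other agents travelling opposite to the focal
#' agent, `p = clip(p0 + k * f_opp)`. With no other agents `f_opp` is 0.
#'
#' @param params Named numeric vector with `p0` (baseline switch probability)
#'   and `k` (coupling).
#' @param context A [SwitchEvents-class], data frame or list providing
#'   `f_opp`.
#' @return Vector of switch probabilities in `[1e-9, 1 - 1e-9]`.
#' @examples
#' pMeanField(c(p0 = 0.01, k = 0.1), list(f_opp = 0.5)) # 0.06
#' @export
pMeanField <- function(params, context) {
  rec <- .ctxRecords(context)
  .clipProb(params[["p0"]] + params[["k"]] * rec$f_opp)
}

#' Markovian zone switching probability
#'
#' Returns the elevated probability `p1` when any opposite-direction agent
#' lies within the interaction zone of half-width `w` ahead of the focal
#' agent (forward separation in `[0, w]`), and the baseline `p0` otherwise.
#' With `w = pi` any opposite-direction agent anywhere ahead triggers the
#' elevated rate: the non-local variant.
#'
#' @param params Named numeric vector with `p0`, `p1` and `w` (zone
#'   half-width, radians, `0 < w <= pi`).
#' @param context A [SwitchEvents-class], data frame or list providing
#'   `s_fwd` (and `s_near` when `symmetric = TRUE`).
#' @param symmetric Use a symmetric `+/- w` zone instead of forward-only.
#' @return Vector of switch probabilities.
#' @export
pZone <- function(params, context, symmetric = FALSE) {
  rec <- .ctxRecords(context)
  tr <- .zoneTrigger(rec, params[["w"]], symmetric)
  .clipProb(ifelse(tr, params[["p1"]], params[["p0"]]))
}

#' Refractory memory switching probability (D1)
#'
#' Non-Markovian rule with a refractory elevated-probability window: an
#' encounter (an opposite-direction agent within the forward zone of
#' half-width `w`) sets a per-agent counter to `tau`; the counter decrements
#' on encounter-free steps. The switch probability is `p1` while the counter
#' is positive and `p0` otherwise.
#'
#' When `context` covers multiple timesteps (a [SwitchEvents-class] or a
#' record table ordered by agent and time), the counter is threaded through
#' each agent's records starting from an empty memory. For explicit
#' single-step use, pass a one-row `context` together with the current
#' counter in `state`; a list `(p, state)` with the updated counter is then
#' returned.
#'
#' @param params Named numeric vector with `p0`, `p1`, `w`, `tau` (memory
#'   duration in timesteps, `tau >= 1`).
#' @param context Event records or a single-timestep context.
#' @param state Optional current refractory counter (single-step mode).
#' @param symmetric Use a symmetric zone for encounter detection.
#' @return Vector of probabilities, or `list(p, state)` in single-step mode.
#' @export
pMemoryD1 <- function(params, context, state = NULL, symmetric = FALSE) {
  rec <- .ctxRecords(context)
  enc <- .zoneTrigger(rec, params[["w"]], symmetric)
  p0 <- params[["p0"]]
  p1 <- params[["p1"]]
  tau <- params[["tau"]]
  if (!is.null(state)) {
    stopifnot(nrow(rec) == 1L)
    newState <- if (enc) tau else max(state - 1, 0)
    return(list(p = .clipProb(if (newState > 0) p1 else p0), state = newState))
  }
  tse <- .timeSinceEncounter(enc, .agentBlocks(rec$agent))
  .clipProb(ifelse(tse$ever & tse$u < tau, p1, p0))
}

#' Decaying-trace memory switching probability (D2)
#'
#' Non-Markovian rule with an exponentially decaying encounter trace: each
#' step the per-agent memory updates `M <- (1 - lam) * M + 1{encounter}` and
#' the switch probability is `clip(p0 + k * M)`. With `lam = 1` the trace
#' reduces to the instantaneous encounter indicator and the rule coincides
#' with the Markovian zone model at `p1 = p0 + k`.
#'
#' @param params Named numeric vector with `p0`, `k`, `w`, `lam` (trace decay
#'   in `(0, 1]`).
#' @param context Event records or a single-timestep context (see
#'   [pMemoryD1()]).
#' @param state Optional current trace value (single-step mode); returns
#'   `list(p, state)` when supplied.
#' @param symmetric Use a symmetric zone for encounter detection.
#' @return Vector of probabilities, or `list(p, state)` in single-step mode.
#' @export
pMemoryD2 <- function(params, context, state = NULL, symmetric = FALSE) {
  rec <- .ctxRecords(context)
  enc <- .zoneTrigger(rec, params[["w"]], symmetric)
  p0 <- params[["p0"]]
  k <- params[["k"]]
  lam <- params[["lam"]]
  if (!is.null(state)) {
    stopifnot(nrow(rec) == 1L)
    newState <- (1 - lam) * state + as.numeric(enc)
    return(list(p = .clipProb(p0 + k * newState), state = newState))
  }
  m <- .encounterTrace(enc, lam, .agentBlocks(rec$agent))
  .clipProb(p0 + k * m)
}

# --- default registry -------------------------------------------------------

.defaultModels <- function() {
  list(
    new("SwitchingModel",
      name = "bernoulli", params = "p0",
      lower = c(p0 = 0), upper = c(p0 = 1),
      integerParams = character(), markovian = TRUE, requiresMemory = FALSE,
      probFn = function(params, rec) .clipProb(rep(params[["p0"]], nrow(rec))),
      fitFn = NULL
    ),
    new("SwitchingModel",
      name = "meanfield", params = c("p0", "k"),
      lower = c(p0 = 0, k = 0), upper = c(p0 = 1, k = 1),
      integerParams = character(), markovian = TRUE, requiresMemory = FALSE,
      probFn = function(params, rec) pMeanField(params, rec),
      fitFn = NULL
    ),
    new("SwitchingModel",
      name = "zone", params = c("p0", "p1", "w"),
      lower = c(p0 = 0, p1 = 0, w = 0.001), upper = c(p0 = 1, p1 = 1, w = pi),
      integerParams = character(), markovian = TRUE, requiresMemory = FALSE,
      probFn = function(params, rec) pZone(params, rec),
      fitFn = function(model, events, nStarts, seed) .fitZoneProfile(model, events)
    ),
    new("SwitchingModel",
      name = "d1", params = c("p0", "p1", "w", "tau"),
      lower = c(p0 = 0, p1 = 0, w = 0.001, tau = 1),
      upper = c(p0 = 1, p1 = 1, w = pi, tau = 12),
      integerParams = "tau", markovian = FALSE, requiresMemory = TRUE,
      probFn = function(params, rec) pMemoryD1(params, rec),
      fitFn = function(model, events, nStarts, seed) .fitD1Profile(model, events)
    ),
    new("SwitchingModel",
      name = "d2", params = c("p0", "k", "w", "lam"),
      lower = c(p0 = 0, k = 0, w = 0.001, lam = 0.01),
      upper = c(p0 = 1, k = 2, w = pi, lam = 1),
      integerParams = character(), markovian = FALSE, requiresMemory = TRUE,
      probFn = function(params, rec) pMemoryD2(params, rec),
      fitFn = function(model, events, nStarts, seed) {
        .fitD2Profile(model, events, nStarts = nStarts, seed = seed)
      }
    )
  )
}
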