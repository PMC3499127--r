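#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

.TIME_RTOL <- 1e-9

# Shared timing check: strictly increasing, constant spacing within relative
# tolerance; trivially true for fewer than three points.
.checkTimes <- function(times) {
  if (length(times) >= 2) {
    d <- diff(times)
    if (any(d <= 0)) return("timestamps must be strictly increasing")
    if (length(d) >= 2) {
      dt <- stats::median(d)
      if (any(abs(d - dt) > .TIME_RTOL * max(dt, 1))) {
        return("timestamps must be evenly spaced (constant dt)")
      }
    }
  }
  NULL
}

#' RingTrajectory: angular positions and travel directions on an annulus
#'
#' An agents-by-timepoints container for movement in a ring-shaped arena,
#' reduced to its angular coordinate. Extends
#' [SummarizedExperiment::SummarizedExperiment] with two assays: `theta`
#' (angular position, radians in `[0, 2*pi)`, counter-clockwise positive) and
#' `dir` (travel direction, `+1` counter-clockwise, `-1` clockwise). Times are
#' stored in `colData(x)$time` and must be evenly spaced; the timestep is
#' available via `timeStep(x)`.
#'
#' @aliases timeStep timePoints nAgents nSteps angles directions
#' @seealso [ringTrajectory()], [readTrajectory()], [simulateRing()]
#' @export
setClass("RingTrajectory", contains = "SummarizedExperiment")

setValidity("RingTrajectory", function(object) {
  msgs <- character()
  if (!all(c("theta", "dir") %in% assayNames(object))) {
    return("assays 'theta' and 'dir' are required")
  }
  th <- assay(object, "theta")
  dd <- assay(object, "dir")
  if (length(th) && (any(th < 0) || any(th >= 2 * pi))) {
    msgs <- c(msgs, "theta values must lie in [0, 2*pi)")
  }
  if (length(dd) && !all(dd %in% c(-1, 1))) {
    msgs <- c(msgs, "dir values must be exactly +1 or -1")
  }
  if (!"time" %in% colnames(colData(object))) {
    msgs <- c(msgs, "colData must contain a 'time' column")
  } else {
    msgs <- c(msgs, .checkTimes(colData(object)$time))
  }
  if (length(msgs)) msgs else TRUE
})

#' PlanarTrajectory: 2-D positions and headings over time
#'
#' An agents-by-timepoints container for planar movement (self-propelled
#' particles, ants, route paths). Extends
#' [SummarizedExperiment::SummarizedExperiment] with assays `x`, `y`
#' (positions, arena units), `heading` (radians in `[0, 2*pi)`) and optionally
#' `speed`. Times live in `colData(x)$time` and must be evenly spaced.
#'
#' @aliases coordsX coordsY headings speeds
#' @seealso [planarTrajectory()], [readTrajectory()], [simulateTrail()]
#' @export
setClass("PlanarTrajectory", contains = "SummarizedExperiment")

setValidity("PlanarTrajectory", function(object) {
  msgs <- character()
  if (!all(c("x", "y", "heading") %in% assayNames(object))) {
    return("assays 'x', 'y' and 'heading' are required")
  }
  h <- assay(object, "heading")
  if (length(h) && (any(h < 0) || any(h >= 2 * pi))) {
    msgs <- c(msgs, "headings must lie in [0, 2*pi)")
  }
  if (!"time" %in% colnames(colData(object))) {
    msgs <- c(msgs, "colData must contain a 'time' column")
  } else {
    msgs <- c(msgs, .checkTimes(colData(object)$time))
  }
  if (length(msgs)) msgs else TRUE
})

#' PheromoneGrid: nonnegative lattice of pheromone concentration
#'
#' A dense rectangular lattice holding pheromone concentration (or,
#' equivalently, cumulative passage counts) in arbitrary pheromone units.
#' `values[i, j]` covers the cell whose lower-left corner is
#' `origin + (i - 1, j - 1) * cellSize` in world coordinates, with `i`
#' indexing the world x axis and `j` the world y axis.
#'
#' @aliases gridValues cellSize gridOrigin totalMass
#' @seealso [pheromoneGrid()], [buildPheromoneMap()], [simulateTrail()]
#' @export
setClass("PheromoneGrid",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric")
)

setValidity("PheromoneGrid", function(object) {
  msgs <- character()
  if (length(object@cellSize) != 1 || object@cellSize <= 0) {
    msgs <- c(msgs, "cellSize must be a single positive number")
  }
  if (length(object@origin) != 2) {
    msgs <- c(msgs, "origin must be a length-2 world coordinate")
  }
  if (length(object@values) && any(object@values < 0)) {
    msgs <- c(msgs, "all grid values must be nonnegative")
  }
  if (length(object@values) && !is.finite(sum(object@values))) {
    msgs <- c(msgs, "total grid mass must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' SwitchEvents: per-agent, per-timestep direction-change observations
#'
#' The event sequence that every switching model is scored against: one record
#' per (agent, time index) pair holding the binary switch indicator `y`
#' (`1` when the agent's travel direction at the next timepoint differs from
#' the current one) together with the neighbour context evaluated at the
#' current timepoint. The default context summarises the configuration through
#' `f_opp` (fraction of the other agents travelling opposite to the focal
#' agent), `s_fwd` (smallest forward angular separation to an
#' opposite-direction agent ahead; `Inf` when none) and `s_near` (signed
#' separation of the nearest opposite-direction agent in `(-pi, pi]`; `NA`
#' when none). Records are ordered by agent and time index so that memory
#' states can be threaded through them.
#'
#' @aliases eventRecords nEvents
#' @seealso [extractEvents()], [sequenceLogLik()], [fitMLE()]
#' @export
setClass("SwitchEvents",
  representation(records = "data.frame", dt = "numeric", nAgents = "integer")
)

setValidity("SwitchEvents", function(object) {
  msgs <- character()
  rec <- object@records
  needed <- c("agent", "step", "y")
  if (!all(needed %in% names(rec))) {
    return(paste("records must contain columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(rec)) {
    if (!all(rec$y %in% c(0, 1))) msgs <- c(msgs, "y must be 0 or 1")
    if (anyDuplicated(rec[, c("agent", "step")])) {
      msgs <- c(msgs, "duplicate (agent, step) records")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SwitchingModel: a candidate direction-switching rule
#'
#' A registered model of the per-timestep probability that a ring agent
#' reverses its travel direction. Each model declares named parameters with
#' finite box bounds (consumed by the fitting engine and by the uniform
#' priors of the marginal-likelihood approximation), whether it is Markovian
#' (probability depends only on the current configuration) or carries a
#' memory state, and a vectorised probability function over a
#' [SwitchEvents-class] record table.
#'
#' @seealso [switchingModels()], [getSwitchingModel()], [registerSwitchingModel()]
#' @export
setClass("SwitchingModel",
  representation(
    name = "character", params = "character",
    lower = "numeric", upper = "numeric",
    integerParams = "character",
    markovian = "logical", requiresMemory = "logical",
    probFn = "function", fitFn = "ANY"
  )
)

setValidity("SwitchingModel", function(object) {
  msgs <- character()
  p <- object@params
  if (!identical(names(object@lower), p) || !identical(names(object@upper), p)) {
    msgs <- c(msgs, "lower/upper bounds must be named exactly as params")
  } else {
    if (!all(is.finite(object@lower)) || !all(is.finite(object@upper))) {
      msgs <- c(msgs, "parameter bounds must be finite")
    }
    if (any(object@lower > object@upper)) {
      msgs <- c(msgs, "each bound interval must contain at least one point")
    }
  }
  if (identical(object@markovian, object@requiresMemory)) {
    msgs <- c(msgs, "markovian must be FALSE exactly when requiresMemory is TRUE")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelFitResult: one fitted switching model on one event sequence
#'
#' Holds the fitted parameters, maximised log-likelihood, information
#' criteria and (when available) the Laplace-approximate log marginal
#' likelihood for a candidate model, plus convergence information. The
#' criteria are recomputable from the stored fields:
#' `AIC = 2 k - 2 logLik`, `BIC = k log(n) - 2 logLik`.
#'
#' @aliases modelName fittedParams
#' @seealso [fitMLE()], [logMarginalLaplace()], [rankModels()]
#' @export
setClass("ModelFitResult",
  representation(
    model = "character", params = "numeric", logLik = "numeric",
    nEvents = "integer", nParams = "integer",
    aic = "numeric", bic = "numeric", logMarginal = "numeric",
    converged = "logical", flags = "character", details = "list"
  )
)

setValidity("ModelFitResult", function(object) {
  msgs <- character()
  if (object@logLik > 1e-6) {
    msgs <- c(msgs, "log-likelihood of a probability sequence cannot exceed 0")
  }
  if (abs(object@aic - (2 * object@nParams - 2 * object@logLik)) > 1e-6) {
    msgs <- c(msgs, "AIC is not consistent with logLik and nParams")
  }
  if (object@nEvents > 0 &&
      abs(object@bic - (object@nParams * log(object@nEvents) - 2 * object@logLik)) > 1e-6) {
    msgs <- c(msgs, "BIC is not consistent with logLik, nParams and nEvents")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelRanking: an ordered comparison of candidate models
#'
#' The result of fitting a set of switching models to the same event sequence
#' and ordering them by a selection criterion (descending; ties broken by
#' fewer parameters). Includes log Bayes factors of each model against the
#' mean-field baseline when that model is in the candidate set.
#'
#' @seealso [rankModels()]
#' @export
setClass("ModelRanking",
  representation(
    results = "list", criterion = "character",
    table = "data.frame", logBF = "numeric"
  )
)

#' RouteDistribution: a station-wise model of repeated journeys
#'
#' Summarises repeated solo paths between fixed endpoints by an
#' arc-length-parameterised mean path (ordered 2-D stations from release
#' point to home) with a Gaussian cross-track standard deviation per station.
#'
#' @aliases stations crossTrackSd
#' @seealso [fitRouteDistribution()], [pathLogLik()], [pairMixtureLogLik()]
#' @export
setClass("RouteDistribution",
  representation(
    stations = "matrix", crossTrackSd = "numeric", nPaths = "integer"
  )
)

setValidity("RouteDistribution", function(object) {
  msgs <- character()
  if (nrow(object@stations) < 2 || ncol(object@stations) != 2) {
    msgs <- c(msgs, "stations must be an n x 2 matrix with n >= 2")
  }
  if (length(object@crossTrackSd) != nrow(object@stations)) {
    msgs <- c(msgs, "one cross-track sd per station is required")
  }
  if (any(object@crossTrackSd <= 0)) {
    msgs <- c(msgs, "cross-track sd must be positive at every station")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PheromoneGrid", function(object) {
  v <- object@values
  cat(sprintf(
    "PheromoneGrid: %d x %d cells (cell size %g), total mass %g\n",
    nrow(v), ncol(v), object@cellSize, sum(v)
  ))
})

setMethod("show", "SwitchEvents", function(object) {
  rec <- object@records
  cat(sprintf(
    "SwitchEvents: %d records, %d agents, %d switches (dt = %g s)\n",
    nrow(rec), object@nAgents, sum(rec$y), object@dt
  ))
})

setMethod("show", "SwitchingModel", function(object) {
  cat(sprintf(
    "SwitchingModel '%s' (%s): parameters %s\n",
    object@name,
    if (object@markovian) "Markovian" else "non-Markovian (memory)",
    paste(sprintf(
      "%s in [%g, %g]", object@params, object@lower, object@upper
    ), collapse = ", ")
  ))
})

setMethod("show", "ModelFitResult", function(object) {
  cat(sprintf(
    "ModelFitResult '%s': logLik %.3f on %d events (%d params)\n",
    object@model, object@logLik, object@nEvents, object@nParams
  ))
  cat("  params:", paste(sprintf("%s = %.4g", names(object@params), object@params),
    collapse = ", "
  ), "\n")
  cat(sprintf(
    "  AIC %.2f | BIC %.2f | log marginal %.2f%s | converged: %s\n",
    object@aic, object@bic, object@logMarginal,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]") else "",
    object@converged
  ))
})

setMethod("show", "ModelRanking", function(object) {
  cat(sprintf("ModelRanking by %s:\n", object@criterion))
  print(object@table, row.names = FALSE)
})

setMethod("show", "RouteDistribution", function(object) {
  cat(sprintf(
    "RouteDistribution: %d stations from %d paths, mean cross-track sd %.4g\n",
    nrow(object@stations), object@nPaths, mean(object@crossTrackSd)
  ))
})

# --- simple accessors -------------------------------------------------------

#' @rdname PheromoneGrid-class
#' @param x A `PheromoneGrid`.
#' @export
setMethod("gridValues", "PheromoneGrid", function(x) x@values)

#' @rdname PheromoneGrid-class
#' @export
setMethod("cellSize", "PheromoneGrid", function(x) x@cellSize)

#' @rdname PheromoneGrid-class
#' @export
setMethod("gridOrigin", "PheromoneGrid", function(x) x@origin)

#' @rdname PheromoneGrid-class
#' @export
setMethod("totalMass", "PheromoneGrid", function(x) sum(x@values))

#' @rdname SwitchEvents-class
#' @param x A `SwitchEvents` object.
#' @export
setMethod("eventRecords", "SwitchEvents", function(x) x@records)

#' @rdname SwitchEvents-class
#' @export
setMethod("nEvents", "SwitchEvents", function(x) nrow(x@records))

#' @rdname ModelFitResult-class
#' @param x A `ModelFitResult`.
#' @export
setMethod("modelName", "ModelFitResult", function(x) x@model)

#' @rdname ModelFitResult-class
#' @export
setMethod("fittedParams", "ModelFitResult", function(x) x@params)

#' @rdname RouteDistribution-class
#' @param x A `RouteDistribution`.
#' @export
setMethod("stations", "RouteDistribution", function(x) x@stations)

#' @rdname RouteDistribution-class
#' @export
setMethod("crossTrackSd", "RouteDistribution", function(x) x@crossTrackSd)
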