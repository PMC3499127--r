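#' Construct a RingTrajectory
#'
#' Builds the annular-arena data model from matrices of angular positions and
#' travel directions. Rows index agents and columns index timepoints.
#'
#' @param theta Numeric matrix of angular positions (radians in `[0, 2*pi)`),
#'   agents by timepoints. A vector is treated as a single agent.
#' @param dir Matrix of travel directions, `+1` (counter-clockwise) or `-1`
#'   (clockwise), same shape as `theta`.
#' @param dt Timestep duration in seconds; ignored when `times` is given.
#' @param times Optional numeric vector of timestamps (evenly spaced).
#' @param agents Optional character vector of agent identifiers.
#' @return A validated [RingTrajectory-class] object.
#' @examples
#' tr <- ringTrajectory(theta = matrix(0, 2, 3),
#'                      dir = matrix(1, 2, 3), dt = 0.4)
#' nAgents(tr)
#' @export
ringTrajectory <- function(theta, dir, dt = 0.4, times = NULL, agents = NULL) {
  theta <- .asAgentMatrix(theta)
  dir <- .asAgentMatrix(dir)
  stopifnot(identical(dim(theta), dim(dir)))
  tm <- .resolveTimes(ncol(theta), dt, times)
  rn <- .agentNames(nrow(theta), agents, rownames(theta))
  dimnames(theta) <- dimnames(dir) <- list(rn, NULL)
  se <- SummarizedExperiment(
    assays = list(theta = theta, dir = dir),
    colData = DataFrame(time = tm$times)
  )
  metadata(se)$dt <- tm$dt
  new("RingTrajectory", se)
}

#' Construct a PlanarTrajectory
#'
#' @param x,y Numeric matrices of positions (arena units), agents by
#'   timepoints. Vectors are treated as a single agent.
#' @param heading Matrix of headings (radians in `[0, 2*pi)`).
#' @param dt Timestep duration in seconds; ignored when `times` is given.
#' @param speed Optional matrix of speeds (arena units per second).
#' @param times Optional numeric vector of timestamps (evenly spaced).
#' @param agents Optional character vector of agent identifiers.
#' @return A validated [PlanarTrajectory-class] object.
#' @export
planarTrajectory <- function(x, y, heading, dt = 0.4, speed = NULL,
                             times = NULL, agents = NULL) {
  x <- .asAgentMatrix(x)
  y <- .asAgentMatrix(y)
  heading <- .asAgentMatrix(heading)
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(heading)))
  tm <- .resolveTimes(ncol(x), dt, times)
  rn <- .agentNames(nrow(x), agents, rownames(x))
  assays <- list(x = x, y = y, heading = heading)
  if (!is.null(speed)) {
    speed <- .asAgentMatrix(speed)
    stopifnot(identical(dim(x), dim(speed)))
    assays$speed <- speed
  }
  assays <- lapply(assays, function(m) {
    dimnames(m) <- list(rn, NULL)
    m
  })
  se <- SummarizedExperiment(assays = assays,
                             colData = DataFrame(time = tm$times))
  metadata(se)$dt <- tm$dt
  new("PlanarTrajectory", se)
}

#' Construct a PheromoneGrid
#'
#' @param values Nonnegative numeric matrix of concentrations; `values[i, j]`
#'   covers the cell at `origin + (i - 1, j - 1) * cellSize`.
#' @param cellSize Cell edge length in arena units.
#' @param origin World coordinate of the lower-left corner of cell `(1, 1)`.
#' @return A validated [PheromoneGrid-class].
#' @export
pheromoneGrid <- function(values, cellSize = 1, origin = c(0, 0)) {
  new("PheromoneGrid", values = as.matrix(values), cellSize = cellSize,
      origin = as.numeric(origin))
}

#' Construct a SwitchEvents object
#'
#' Normally produced by [extractEvents()]; exposed for hand-built oracles and
#' synthetic likelihood problems.
#'
#' @param records Data frame with at least columns `agent`, `step`, `y` plus
#'   any context columns; rows are reordered by `(agent, step)`.
#' @param dt Timestep duration of the source trajectory (seconds).
#' @param nAgents Number of agents in the source trajectory.
#' @return A validated [SwitchEvents-class].
#' @export
switchEvents <- function(records, dt = 0.4, nAgents = length(unique(records$agent))) {
  records <- records[order(records$agent, records$step), , drop = FALSE]
  rownames(records) <- NULL
  new("SwitchEvents", records = records, dt = dt, nAgents = as.integer(nAgents))
}

.asAgentMatrix <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  as.matrix(m)
}

.resolveTimes <- function(nT, dt, times) {
  if (!is.null(times)) {
    stopifnot(length(times) == nT)
    dt <- if (nT >= 2) times[2] - times[1] else NA_real_
  } else {
    times <- if (nT) (seq_len(nT) - 1) * dt else numeric(0)
    if (nT < 2) dt <- if (nT) dt else NA_real_
  }
  list(times = as.numeric(times), dt = dt)
}

.agentNames <- function(n, agents, existing) {
  if (!is.null(agents)) as.character(agents)
  else if (!is.null(existing)) existing
  else sprintf("a%d", seq_len(n))
}

#' @rdname RingTrajectory-class
#' @export
setMethod("timeStep", "SummarizedExperiment", function(x) metadata(x)$dt)

#' @rdname RingTrajectory-class
#' @export
setMethod("timePoints", "SummarizedExperiment", function(x) colData(x)$time)

#' @rdname RingTrajectory-class
#' @export
setMethod("nAgents", "SummarizedExperiment", function(x) nrow(x))

#' @rdname RingTrajectory-class
#' @export
setMethod("nSteps", "SummarizedExperiment", function(x) ncol(x))

#' @rdname RingTrajectory-class
#' @export
setMethod("angles", "RingTrajectory", function(x) assay(x, "theta"))

#' @rdname RingTrajectory-class
#' @export
setMethod("directions", "RingTrajectory", function(x) assay(x, "dir"))

#' @rdname PlanarTrajectory-class
#' @export
setMethod("coordsX", "PlanarTrajectory", function(x) assay(x, "x"))

#' @rdname PlanarTrajectory-class
#' @export
setMethod("coordsY", "PlanarTrajectory", function(x) assay(x, "y"))

#' @rdname PlanarTrajectory-class
#' @export
setMethod("headings", "PlanarTrajectory", function(x) assay(x, "heading"))

#' @rdname PlanarTrajectory-class
#' @export
setMethod("speeds", "PlanarTrajectory", function(x) {
  if ("speed" %in% assayNames(x)) assay(x, "speed") else NULL
})

setMethod("show", "RingTrajectory", function(object) {
  cat(sprintf(
    "RingTrajectory: %d agents x %d timepoints (dt = %g s), %d direction switches\n",
    nrow(object), ncol(object), metadata(object)$dt,
    if (ncol(object) >= 2) sum(assay(object, "dir")[, -1, drop = FALSE] !=
        assay(object, "dir")[, -ncol(object), drop = FALSE]) else 0L
  ))
})

setMethod("show", "PlanarTrajectory", function(object) {
  cat(sprintf(
    "PlanarTrajectory: %d agents x %d timepoints (dt = %g s)%s\n",
    nrow(object), ncol(object), metadata(object)$dt,
    if ("speed" %in% assayNames(object)) " with speeds" else ""
  ))
})

# --- file I/O ---------------------------------------------------------------

.RING_COLS <- c("time", "agent", "theta", "dir")
.PLANAR_COLS <- c("time", "agent", "x", "y", "heading")

#' Read a trajectory from delimited text
#'
#' Reads the package's comma-separated trajectory schema (header required,
#' UTF-8, `.` decimal separator). Ring files have columns
#' `time,agent,theta,dir`; planar files `time,agent,x,y,heading[,speed]`.
#' Rows may arrive in any order; they are sorted by `(agent, time)`. The ring
#' direction column accepts `-1`/`+1` or the labels `CW`/`CCW`, which code to
#' `-1`/`+1` respectively (clockwise is negative).
#'
#' @param path Path to an existing CSV file.
#' @param kind `"ring"` or `"planar"`, selecting the schema.
#' @return A [RingTrajectory-class] or [PlanarTrajectory-class].
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(path, kind = c("ring", "planar")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- if (kind == "ring") .RING_COLS else .PLANAR_COLS
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(sQuote(missing), collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(if (kind == "ring") {
      ringTrajectory(matrix(0, 0, 0), matrix(0, 0, 0), times = numeric(0))
    } else {
      planarTrajectory(matrix(0, 0, 0), matrix(0, 0, 0), matrix(0, 0, 0),
                       times = numeric(0))
    })
  }
  raw$time <- as.numeric(raw$time)
  raw <- raw[order(raw$agent, raw$time), , drop = FALSE]
  agents <- unique(raw$agent)
  times <- sort(unique(raw$time))
  if (nrow(raw) != length(agents) * length(times)) {
    stop("timing error: agents do not share a common set of timestamps")
  }
  err <- .checkTimes(times)
  if (!is.null(err)) stop("timing error: ", err)
  toMat <- function(v) {
    matrix(v, nrow = length(agents), ncol = length(times),
           byrow = TRUE, dimnames = list(agents, NULL))
  }
  if (kind == "ring") {
    d <- raw$dir
    d[d == "CW"] <- "-1"
    d[d == "CCW"] <- "1"
    dnum <- suppressWarnings(as.numeric(d))
    if (any(is.na(dnum)) || !all(dnum %in% c(-1, 1))) {
      bad <- unique(raw$dir[is.na(dnum) | !dnum %in% c(-1, 1)])
      stop("value error: direction must be -1, +1, 'CW' or 'CCW'; got ",
           paste(sQuote(bad), collapse = ", "))
    }
    ringTrajectory(toMat(as.numeric(raw$theta)), toMat(dnum),
                   times = times, agents = agents)
  } else {
    speed <- if ("speed" %in% names(raw)) toMat(as.numeric(raw$speed)) else NULL
    planarTrajectory(toMat(as.numeric(raw$x)), toMat(as.numeric(raw$y)),
                     toMat(as.numeric(raw$heading)),
                     speed = speed, times = times, agents = agents)
  }
}

#' Write a trajectory to delimited text
#'
#' Writes the CSV schema read by [readTrajectory()]. Numeric fields are
#' formatted with 17 significant digits so that a read/write round trip is
#' bit-exact.
#'
#' @param traj A [RingTrajectory-class] or [PlanarTrajectory-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  fmt <- function(v) sprintf("%.17g", v)
  flat <- function(m) as.vector(t(m)) # agent-major row blocks
  nT <- nSteps(traj)
  agents <- rownames(traj)
  if (is.null(agents)) agents <- character(0)
  df <- data.frame(
    time = fmt(rep(timePoints(traj), times = nAgents(traj))),
    agent = rep(agents, each = nT),
    stringsAsFactors = FALSE
  )
  if (is(traj, "RingTrajectory")) {
    df$theta <- fmt(flat(angles(traj)))
    df$dir <- fmt(flat(directions(traj)))
  } else {
    df$x <- fmt(flat(coordsX(traj)))
    df$y <- fmt(flat(coordsY(traj)))
    df$heading <- fmt(flat(headings(traj)))
    if (!is.null(speeds(traj))) df$speed <- fmt(flat(speeds(traj)))
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("I/O error: cannot open ", path))
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- geometry and event extraction -----------------------------------------

#' Signed forward angular separation on the ring
#'
#' Measures the position of agent `b` relative to a focal agent `a`, forward
#' along `a`'s direction of travel. The result lies in `(-pi, pi]`; positive
#' values mean `b` is ahead of `a`, negative behind. Reversing `dirA` flips
#' the sign (except at the antipode, which maps to `+pi` by convention).
#'
#' @param thetaA,thetaB Angular positions in `[0, 2*pi)` (recycled).
#' @param dirA Travel direction of the focal agent, `+1` or `-1`.
#' @return Signed separation(s) in radians.
#' @examples
#' angularSeparation(0, pi / 2, +1) # +pi/2, ahead
#' angularSeparation(0, pi / 2, -1) # -pi/2, behind
#' @export
angularSeparation <- function(thetaA, thetaB, dirA) {
  .wrapPi(dirA * (.wrap2pi(thetaB) - .wrap2pi(thetaA)))
}

#' Default ring neighbour context
#'
#' Summarises the configuration around each focal agent by the statistics the
#' switching-model family reads: `f_opp`, the fraction of the other agents
#' travelling opposite to the focal agent; `s_fwd`, the smallest forward
#' separation to an opposite-direction agent ahead (`Inf` when none); and
#' `s_near`, the signed separation of the nearest opposite-direction agent
#' (`NA` when none). Only opposite-direction neighbours enter the context;
#' same-direction neighbours are ignored.
#'
#' @param theta Numeric vector of angular positions at one timepoint.
#' @param dir Vector of travel directions (`+1`/`-1`), same length.
#' @return A list of numeric vectors `f_opp`, `s_fwd`, `s_near`.
#' @export
ringContext <- function(theta, dir) {
  n <- length(theta)
  f_opp <- numeric(n)
  s_fwd <- rep(Inf, n)
  s_near <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in seq_len(n)) {
      opp <- which(dir != dir[i])
      f_opp[i] <- length(opp) / (n - 1)
      if (length(opp)) {
        s <- .wrapPi(dir[i] * (theta[opp] - theta[i]))
        ahead <- s[s >= 0]
        if (length(ahead)) s_fwd[i] <- min(ahead)
        s_near[i] <- s[which.min(abs(s))]
      }
    }
  }
  list(f_opp = f_opp, s_fwd = s_fwd, s_near = s_near)
}

#' Extract direction-switch events from a ring trajectory
#'
#' Converts a [RingTrajectory-class] into the per-agent, per-timestep binary
#' observations that the likelihood engine scores: for each agent and each
#' time index `t < T`, `y = 1` exactly when the travel direction at `t + 1`
#' differs from the direction at `t`, with the neighbour context evaluated at
#' time `t`. The result has one record per (agent, time index) pair,
#' `N * (T - 1)` in total, ordered by agent then time.
#'
#' @param traj A [RingTrajectory-class] with at least two timepoints.
#' @param contextFun Context builder called as `contextFun(theta, dir)` with
#'   the configuration at one timepoint; must return a named list of numeric
#'   vectors (one value per agent). Defaults to [ringContext()].
#' @return A [SwitchEvents-class] object.
#' @export
extractEvents <- function(traj, contextFun = ringContext) {
  stopifnot(is(traj, "RingTrajectory"))
  nT <- nSteps(traj)
  if (nT < 2) stop("no transitions observable: trajectory has a single time point")
  th <- angles(traj)
  dd <- directions(traj)
  n <- nrow(th)
  ctx0 <- contextFun(th[, 1], dd[, 1])
  fields <- names(ctx0)
  store <- lapply(fields, function(f) matrix(NA_real_, n, nT - 1))
  names(store) <- fields
  y <- matrix(0L, n, nT - 1)
  for (t in seq_len(nT - 1)) {
    ctx <- if (t == 1) ctx0 else contextFun(th[, t], dd[, t])
    for (f in fields) store[[f]][, t] <- ctx[[f]]
    y[, t] <- as.integer(dd[, t + 1] != dd[, t])
  }
  agents <- rownames(th)
  rec <- data.frame(
    agent = rep(agents, each = nT - 1),
    step = rep(seq_len(nT - 1), times = n),
    y = as.vector(t(y)),
    stringsAsFactors = FALSE
  )
  for (f in fields) rec[[f]] <- as.vector(t(store[[f]]))
  switchEvents(rec, dt = timeStep(traj), nAgents = n)
}
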