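#' @import methods
NULL

#' @rdname RingTrajectory-class
#' @param x A trajectory object.
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname RingTrajectory-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname RingTrajectory-class
#' @export
setGeneric("nAgents", function(x) standardGeneric("nAgents"))

#' @rdname RingTrajectory-class
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname RingTrajectory-class
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname RingTrajectory-class
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname PlanarTrajectory-class
#' @export
setGeneric("coordsX", function(x) standardGeneric("coordsX"))

#' @rdname PlanarTrajectory-class
#' @export
setGeneric("coordsY", function(x) standardGeneric("coordsY"))

#' @rdname PlanarTrajectory-class
#' @export
setGeneric("headings", function(x) standardGeneric("headings"))

#' @rdname PlanarTrajectory-class
#' @export
setGeneric("speeds", function(x) standardGeneric("speeds"))

#' @rdname PheromoneGrid-class
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname PheromoneGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname PheromoneGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname PheromoneGrid-class
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @rdname SwitchEvents-class
#' @export
setGeneric("eventRecords", function(x) standardGeneric("eventRecords"))

#' @rdname SwitchEvents-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname ModelFitResult-class
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname ModelFitResult-class
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @rdname RouteDistribution-class
#' @export
setGeneric("stations", function(x) standardGeneric("stations"))

#' @rdname RouteDistribution-class
#' @export
setGeneric("crossTrackSd", function(x) standardGeneric("crossTrackSd"))
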