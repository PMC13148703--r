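#' @rdname PPINetwork-class
#' @param object,x a \linkS4class{PPINetwork} or
#'   \linkS4class{CentralityTable}.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname PPINetwork-class
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname PPINetwork-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname PPINetwork-class
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname PPINetwork-class
#' @export
setGeneric("nodeNeighbors", function(x, v) standardGeneric("nodeNeighbors"))

#' @rdname PPINetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PPINetwork-class
#' @export
setGeneric("diseaseScores", function(x) standardGeneric("diseaseScores"))

#' @rdname PPINetwork-class
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' @rdname CentralityTable-class
#' @param x a \linkS4class{CentralityTable}.
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname CentralityTable-class
#' @export
setGeneric("metricScores", function(x) standardGeneric("metricScores"))

#' @rdname CentralityTable-class
#' @export
setGeneric("metricRanks", function(x) standardGeneric("metricRanks"))
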