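#' @import methods
NULL

#' PPINetwork: an undirected confidence-filtered interaction network
#'
#' Container for a protein-protein interaction network assembled from a
#' disease-scored query gene list and a confidence-scored edge table.
#' The graph is simple (no self-loops, no multi-edges) and undirected;
#' genes from the query list that map into the edge vocabulary but lose
#' all edges at the chosen confidence cutoff are kept as degree-0 nodes.
#'
#' @slot nodes character vector of gene identifiers, in descending
#'   disease-score order (ties broken lexicographically).
#' @slot adjacency named list; \code{adjacency[[v]]} is the sorted
#'   character vector of neighbours of \code{v}. Exactly symmetric.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence}; one row per unordered pair, \code{gene_a <
#'   gene_b}.
#' @slot diseaseScores named numeric vector of disease scores (0-5) for
#'   every node.
#' @slot minConfidence numeric(1), the confidence cutoff applied when
#'   the network was built.
#'
#' @seealso [buildNetwork()], [networkDensity()], [connectedBiomarkers()]
#' @exportClass PPINetwork
setClass("PPINetwork",
    representation(
        nodes = "character",
        adjacency = "list",
        edges = "data.frame",
        diseaseScores = "numeric",
        minConfidence = "numeric"
    )
)

setValidity("PPINetwork", function(object) {
    msgs <- character()
    nd <- object@nodes
    adj <- object@adjacency
    if (anyDuplicated(nd)) {
        msgs <- c(msgs, "duplicate node identifiers")
    }
    if (!identical(sort(names(adj)), sort(nd))) {
        msgs <- c(msgs, "adjacency names must equal the node set")
    }
    for (v in names(adj)) {
        nb <- adj[[v]]
        if (v %in% nb) {
            msgs <- c(msgs, sprintf("self-loop at node '%s'", v))
            break
        }
        if (!all(nb %in% nd)) {
            msgs <- c(msgs, "adjacency refers to unknown nodes")
            break
        }
    }
    ## symmetry: u in adj(v) <=> v in adj(u)
    for (v in names(adj)) {
        for (u in adj[[v]]) {
            if (!(v %in% adj[[u]])) {
                msgs <- c(msgs, sprintf(
                    "asymmetric adjacency: %s->%s without %s->%s",
                    v, u, u, v
                ))
                break
            }
        }
    }
    m <- sum(lengths(adj)) / 2L
    if (nrow(object@edges) != m) {
        msgs <- c(msgs, "edge table row count disagrees with adjacency")
    }
    if (!identical(sort(names(object@diseaseScores)), sort(nd))) {
        msgs <- c(msgs, "diseaseScores names must equal the node set")
    }
    if (length(msgs)) msgs else TRUE
})

#' MetricParams: tunable parameters of the centrality measures
#'
#' Parameters that affect the stochastic or tunable centrality
#' measures. Defaults follow the cytoHubba conventions: 1000 edge
#' percolation replicates with retention threshold 0.5, and the DMNC
#' exponent epsilon = 1.7.
#'
#' @slot epcIterations integer(1), Monte-Carlo replicates for EPC.
#' @slot epcThreshold numeric(1) in [0,1]; an edge is retained in a
#'   replicate iff its uniform(0,1) draw is >= this threshold.
#' @slot dmncEpsilon numeric(1), exponent of the DMNC denominator.
#' @slot rngSeed integer(1), seed for the EPC percolation draws.
#' @slot closenessForm character(1), "harmonic" (reciprocal-sum,
#'   default) or "classic" (component-restricted 1/sum-of-distances).
#'
#' @seealso [metricParams()]
#' @exportClass MetricParams
setClass("MetricParams",
    representation(
        epcIterations = "integer",
        epcThreshold = "numeric",
        dmncEpsilon = "numeric",
        rngSeed = "integer",
        closenessForm = "character"
    )
)

setValidity("MetricParams", function(object) {
    msgs <- character()
    if (object@epcIterations < 1L) {
        msgs <- c(msgs, "epcIterations must be a positive integer")
    }
    if (object@epcThreshold < 0 || object@epcThreshold > 1) {
        msgs <- c(msgs, "epcThreshold must lie in [0, 1]")
    }
    if (!object@closenessForm %in% c("harmonic", "classic")) {
        msgs <- c(msgs, "closenessForm must be 'harmonic' or 'classic'")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a MetricParams object
#'
#' @param epcIterations number of Monte-Carlo edge-percolation
#'   replicates (default 1000).
#' @param epcThreshold retention threshold in [0,1] (default 0.5); an
#'   edge survives a replicate iff its uniform draw is >= the threshold.
#' @param dmncEpsilon DMNC denominator exponent (default 1.7).
#' @param rngSeed seed used for the EPC draws (default 1).
#' @param closenessForm "harmonic" or "classic".
#' @return A \linkS4class{MetricParams} object.
#' @examples
#' metricParams(epcIterations = 200, rngSeed = 7)
#' @export
metricParams <- function(epcIterations = 1000L, epcThreshold = 0.5,
                         dmncEpsilon = 1.7, rngSeed = 1L,
                         closenessForm = c("harmonic", "classic")) {
    closenessForm <- match.arg(closenessForm)
    new("MetricParams",
        epcIterations = as.integer(epcIterations),
        epcThreshold = as.numeric(epcThreshold),
        dmncEpsilon = as.numeric(dmncEpsilon),
        rngSeed = as.integer(rngSeed),
        closenessForm = closenessForm
    )
}

#' CentralityTable: scores and competition ranks for one measure
#'
#' Per-gene scores and "1224"-style competition ranks for a single
#' centrality measure, restricted to genes with degree >= 1. Tied
#' scores share the best rank and the next distinct score's rank counts
#' every preceding gene, so four genes tied at rank 1 are followed by
#' rank 5.
#'
#' @slot metric character(1), one of the twelve measure names.
#' @slot scores named numeric vector, gene -> score.
#' @slot ranks named integer vector, gene -> competition rank (1 = best).
#' @slot params list of metadata recording the parameters and
#'   conventions under which the scores were computed.
#'
#' @seealso [rankTable()], [centralityTable()]
#' @exportClass CentralityTable
setClass("CentralityTable",
    representation(
        metric = "character",
        scores = "numeric",
        ranks = "integer",
        params = "list"
    )
)

setValidity("CentralityTable", function(object) {
    msgs <- character()
    if (length(object@metric) != 1L) {
        msgs <- c(msgs, "metric must be a single name")
    }
    if (!identical(names(object@scores), names(object@ranks))) {
        msgs <- c(msgs, "scores and ranks must be named identically")
    }
    if (length(object@scores)) {
        expect <- competitionRank(object@scores)
        if (!identical(unname(object@ranks), unname(expect))) {
            msgs <- c(msgs, "ranks are not the competition ranking of scores")
        }
    }
    if (length(msgs)) msgs else TRUE
})
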