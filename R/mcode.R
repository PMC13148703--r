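## MCODE-style vertex weighting. Only the node score is implemented:
## the complex expansion / haircut / fluff stages of the full MCODE
## clustering algorithm are not part of this package's scope — the
## node score alone serves as the complex-formation proxy.

#' Highest k-core of an induced subgraph
#'
#' Iterative minimum-degree pruning of the subgraph induced by
#' \code{subset}: the k-core is what remains after repeatedly deleting
#' vertices of degree < k, and the highest-k core is the non-empty
#' core with maximal k. The empty subset yields \code{k = 0} with no
#' members.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param subset character vector of node ids (must be nodes of
#'   \code{net}).
#' @return A list with elements \code{k} (integer) and \code{members}
#'   (character vector).
#' @examples
#' genes <- data.frame(gene = letters[1:4], disease_score = 4:1)
#' edges <- data.frame(
#'     gene_a = c("a", "a", "a", "b", "b", "c"),
#'     gene_b = c("b", "c", "d", "c", "d", "d"), confidence = 0.9
#' )
#' net <- buildNetwork(genes, 4, edges, 0.4)
#' kCore(net, nodes(net)) # the K4: k = 3
#' @export
kCore <- function(net, subset) {
    bad <- setdiff(subset, net@nodes)
    if (length(bad)) {
        stop("subset contains non-network genes: ",
            paste(bad, collapse = ", "),
            call. = FALSE
        )
    }
    subset <- sort(unique(subset))
    if (!length(subset)) {
        return(list(k = 0L, members = character(0)))
    }
    idx <- seq_along(subset)
    names(idx) <- subset
    adj <- lapply(subset, function(v) {
        nb <- intersect(net@adjacency[[v]], subset)
        unname(idx[nb])
    })
    core <- highestKCore(adj)
    list(k = core$k, members = subset[core$members])
}

#' MCODE node score of one gene
#'
#' The score is \code{k x density} of the highest k-core of the
#' gene's closed neighbourhood (the gene plus its neighbours), with
#' density the realised fraction of the \code{V(V-1)/2} possible
#' undirected simple edges. High scores mark locally dense, clique-
#' like regions — the seed proteins of predicted complexes. Degree-0
#' genes have no score (their neighbourhood carries no edges) and
#' requesting one is an error.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param v a gene id with degree >= 1.
#' @return Numeric node score (0 <= score <= degree of \code{v}).
#' @export
nodeScore <- function(net, v) {
    if (!v %in% net@nodes) stop("unknown node '", v, "'", call. = FALSE)
    nb <- net@adjacency[[v]]
    if (length(nb) == 0L) {
        stop("node score is undefined for degree-0 gene '", v, "'",
            call. = FALSE
        )
    }
    core <- kCore(net, c(v, nb))
    members <- core$members
    nV <- length(members)
    if (nV < 2L) {
        return(0)
    }
    eH <- sum(vapply(members, function(u) {
        length(intersect(net@adjacency[[u]], members))
    }, integer(1))) / 2
    core$k * eH / (nV * (nV - 1) / 2)
}

#' MCODE node scores for every connected gene
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param degreeCutoff recorded MCODE parameter (default 2); the node
#'   score itself does not depend on it.
#' @param includeLoops recorded MCODE parameter; loops never exist in
#'   a \linkS4class{PPINetwork}, so only \code{FALSE} is supported.
#' @return A data.frame with columns \code{gene}, \code{node_score}
#'   (degree >= 1 genes only, sorted by gene id), with the parameters
#'   attached as attribute \code{"params"}.
#' @export
mcodeScores <- function(net, degreeCutoff = 2L, includeLoops = FALSE) {
    if (includeLoops) {
        stop("includeLoops = TRUE is not supported: networks are loop-free",
            call. = FALSE
        )
    }
    genes <- sort(net@nodes[lengths(net@adjacency)[net@nodes] >= 1L])
    scores <- vapply(genes, function(v) nodeScore(net, v), numeric(1))
    out <- data.frame(
        gene = genes, node_score = unname(scores),
        stringsAsFactors = FALSE
    )
    attr(out, "params") <- list(
        degree_cutoff = as.integer(degreeCutoff),
        include_loops = includeLoops
    )
    out
}
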