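## The twelve hub-ranking centrality measures, computed from scratch on
## the degree >= 1 subgraph of a PPINetwork. Distances are unweighted
## hop counts; unreachable pairs contribute 0 where a reciprocal is
## summed and are excluded from component-local quantities.
## Betweenness and Stress count unordered (s,t) pairs.

#' Names of the twelve centrality measures
#'
#' @return Character vector of the supported measure names.
#' @examples
#' centralityMetrics()
#' @export
centralityMetrics <- function() {
    c(
        "Betweenness", "BottleNeck", "ClusteringCoefficient", "Closeness",
        "Degree", "DMNC", "EcCentricity", "EPC", "MCC", "MNC",
        "Radiality", "Stress"
    )
}

## degree >= 1 nodes in lexicographic order, plus their integer
## adjacency (neighbour lists sorted, so BFS scans are lexicographic)
rankedSubgraph <- function(net) {
    keep <- sort(net@nodes[lengths(net@adjacency)[net@nodes] >= 1L])
    idx <- seq_along(keep)
    names(idx) <- keep
    adj <- lapply(keep, function(v) unname(idx[net@adjacency[[v]]]))
    list(genes = keep, adj = adj)
}

makeCentralityTable <- function(metric, scores, params = list()) {
    scores <- scores[order(names(scores))]
    new("CentralityTable",
        metric = metric, scores = scores,
        ranks = competitionRank(scores), params = params
    )
}

#' @describeIn CentralityTable-class the measure name.
#' @export
setMethod("metricName", "CentralityTable", function(x) x@metric)

#' @describeIn CentralityTable-class named numeric score vector.
#' @export
setMethod("metricScores", "CentralityTable", function(x) x@scores)

#' @describeIn CentralityTable-class named integer competition ranks.
#' @export
setMethod("metricRanks", "CentralityTable", function(x) x@ranks)

setMethod("show", "CentralityTable", function(object) {
    cat(
        "CentralityTable:", object@metric, "over",
        length(object@scores), "genes\n"
    )
    if (length(object@scores)) {
        top <- names(sort(object@ranks))[seq_len(min(5L, length(object@ranks)))]
        cat("  top genes:", paste(top, collapse = ", "), "\n")
    }
    invisible(object)
})

#' Competition ("1224") ranking of a score vector
#'
#' Builds a \linkS4class{CentralityTable} from an arbitrary named
#' score vector using competition ranking: \code{rank(v) = 1 + #\{u :
#' score(u) > score(v)\}}, so tied scores share the best rank and the
#' gene after a block of four co-leaders is ranked 5.
#'
#' @param scores named numeric vector (higher is better).
#' @param metric label for the resulting table.
#' @return A \linkS4class{CentralityTable}.
#' @examples
#' metricRanks(rankTable(c(a = 3, b = 3, c = 1)))
#' @export
rankTable <- function(scores, metric = "score") {
    if (is.null(names(scores)) || anyDuplicated(names(scores))) {
        stop("scores must carry unique names", call. = FALSE)
    }
    makeCentralityTable(metric, scores)
}

## ---- the measures -------------------------------------------------

#' Degree centrality
#'
#' Score of a gene is its number of neighbours. Like every measure
#' here, degree-0 genes are excluded from the table.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return A \linkS4class{CentralityTable}.
#' @export
degreeCentrality <- function(net) {
    g <- rankedSubgraph(net)
    scores <- as.numeric(lengths(g$adj))
    names(scores) <- g$genes
    makeCentralityTable("Degree", scores)
}

## shared pair-counting core for Betweenness and Stress; returns both
pathLoadScores <- function(g) {
    n <- length(g$adj)
    sp <- spMatrices(g$adj)
    D <- sp$D
    S <- sp$S
    bet <- numeric(n)
    str <- numeric(n)
    for (v in seq_len(n)) {
        through <- outer(D[, v], D[v, ], "+")
        onPath <- !is.na(through) & !is.na(D) & through == D
        onPath[v, ] <- FALSE
        onPath[, v] <- FALSE
        diag(onPath) <- FALSE
        if (!any(onPath)) next
        paths <- outer(S[, v], S[v, ])
        str[v] <- sum(paths[onPath]) / 2
        bet[v] <- sum(paths[onPath] / S[onPath]) / 2
    }
    list(betweenness = bet, stress = str)
}

#' Betweenness centrality
#'
#' Raw (unnormalised) shortest-path betweenness over unordered node
#' pairs: the sum over pairs (s,t) of the fraction of shortest s-t
#' paths passing through the gene.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
betweennessCentrality <- function(net) {
    g <- rankedSubgraph(net)
    scores <- pathLoadScores(g)$betweenness
    names(scores) <- g$genes
    makeCentralityTable("Betweenness", scores,
        params = list(pairs = "unordered", normalised = FALSE)
    )
}

#' Stress centrality
#'
#' Number of shortest paths (over unordered pairs) whose interior
#' contains the gene.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
stressCentrality <- function(net) {
    g <- rankedSubgraph(net)
    scores <- pathLoadScores(g)$stress
    names(scores) <- g$genes
    makeCentralityTable("Stress", scores, params = list(pairs = "unordered"))
}

#' Closeness centrality
#'
#' By default the harmonic form: the sum over other genes of the
#' reciprocal hop distance, with unreachable genes contributing 0, so
#' disconnected networks need no component restriction. The classic
#' component-restricted form (reciprocal of the summed distance to the
#' gene's component) is available via
#' \code{metricParams(closenessForm = "classic")}.
#'
#' @inheritParams degreeCentrality
#' @param params a \linkS4class{MetricParams}.
#' @return A \linkS4class{CentralityTable}.
#' @export
closenessCentrality <- function(net, params = metricParams()) {
    g <- rankedSubgraph(net)
    n <- length(g$adj)
    D <- spMatrices(g$adj)$D
    if (params@closenessForm == "harmonic") {
        R <- 1 / D
        R[is.na(D)] <- 0
        diag(R) <- 0
        scores <- rowSums(R)
    } else {
        scores <- vapply(seq_len(n), function(v) {
            d <- D[v, ]
            d <- d[!is.na(d)]
            tot <- sum(d)
            if (tot == 0) 0 else 1 / tot
        }, numeric(1))
    }
    names(scores) <- g$genes
    makeCentralityTable("Closeness", scores,
        params = list(form = params@closenessForm)
    )
}

#' Radiality centrality
#'
#' Within a gene's connected component C of size n_C and diameter
#' Delta_C, the score is the mean over other component members of
#' \code{Delta_C + 1 - d(v, w)}.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
radialityCentrality <- function(net) {
    g <- rankedSubgraph(net)
    n <- length(g$adj)
    D <- spMatrices(g$adj)$D
    comp <- componentMembership(g$adj)
    scores <- numeric(n)
    for (cid in unique(comp)) {
        members <- which(comp == cid)
        dc <- D[members, members, drop = FALSE]
        delta <- max(dc)
        nc <- length(members)
        scores[members] <- (rowSums(delta + 1 - dc) - (delta + 1)) / (nc - 1)
    }
    names(scores) <- g$genes
    makeCentralityTable("Radiality", scores)
}

#' Eccentricity centrality
#'
#' Reciprocal of the gene's eccentricity (its maximum hop distance to
#' any member of its connected component). Known for poor resolution:
#' many genes share the same score on dense networks.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
eccentricityCentrality <- function(net) {
    g <- rankedSubgraph(net)
    D <- spMatrices(g$adj)$D
    scores <- apply(D, 1L, function(d) 1 / max(d, na.rm = TRUE))
    names(scores) <- g$genes
    makeCentralityTable("EcCentricity", scores)
}

## logical adjacency matrix of the ranked subgraph
logicalAdjMatrix <- function(g) {
    n <- length(g$adj)
    A <- matrix(FALSE, n, n)
    for (v in seq_len(n)) A[v, g$adj[[v]]] <- TRUE
    A
}

#' Local clustering coefficient
#'
#' Fraction of possible edges realised among a gene's neighbours;
#' genes of degree < 2 score 0.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
clusteringCoefficient <- function(net) {
    g <- rankedSubgraph(net)
    A <- logicalAdjMatrix(g)
    scores <- vapply(seq_along(g$adj), function(v) {
        nb <- g$adj[[v]]
        k <- length(nb)
        if (k < 2L) {
            return(0)
        }
        ev <- sum(A[nb, nb]) / 2
        2 * ev / (k * (k - 1))
    }, numeric(1))
    names(scores) <- g$genes
    makeCentralityTable("ClusteringCoefficient", scores)
}

## largest connected component of the open neighbourhood of v;
## returns integer vertex ids (in the ranked subgraph indexing)
mncComponent <- function(g, v) {
    nb <- g$adj[[v]]
    sub <- inducedAdjacency(g$adj, nb)
    comp <- componentMembership(sub)
    sizes <- tabulate(comp)
    big <- which.max(sizes)
    nb[comp == big]
}

#' Maximum Neighborhood Component (MNC)
#'
#' Size of the largest connected component of the subgraph induced by
#' a gene's neighbours (the gene itself excluded).
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
mncCentrality <- function(net) {
    g <- rankedSubgraph(net)
    scores <- vapply(
        seq_along(g$adj), function(v) length(mncComponent(g, v)),
        numeric(1)
    )
    names(scores) <- g$genes
    makeCentralityTable("MNC", scores)
}

#' Density of Maximum Neighborhood Component (DMNC)
#'
#' With H the maximum neighbourhood component of a gene, the score is
#' \code{|E(H)| / |V(H)|^epsilon} (epsilon = 1.7 by default); genes
#' whose H has no edges score 0.
#'
#' @inheritParams closenessCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
dmncCentrality <- function(net, params = metricParams()) {
    g <- rankedSubgraph(net)
    A <- logicalAdjMatrix(g)
    eps <- params@dmncEpsilon
    scores <- vapply(seq_along(g$adj), function(v) {
        H <- mncComponent(g, v)
        eH <- sum(A[H, H]) / 2
        if (eH == 0) 0 else eH / length(H)^eps
    }, numeric(1))
    names(scores) <- g$genes
    makeCentralityTable("DMNC", scores, params = list(epsilon = eps))
}

#' Maximal Clique Centrality (MCC)
#'
#' Sum of \code{(|C| - 1)!} over all maximal cliques C of the network
#' that contain the gene. A gene whose neighbourhood is edgeless
#' therefore scores its degree (each edge is a maximal 2-clique).
#' Factorial terms are exact for clique sizes up to 23, far beyond
#' desk-scale interaction cliques.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
mccCentrality <- function(net) {
    g <- rankedSubgraph(net)
    scores <- numeric(length(g$adj))
    for (clique in maximalCliques(g$adj)) {
        w <- prod(seq_len(length(clique) - 1L)) # (|C|-1)!, exact to 23!
        scores[clique] <- scores[clique] + w
    }
    names(scores) <- g$genes
    makeCentralityTable("MCC", scores)
}

#' Edge Percolated Component (EPC)
#'
#' Monte-Carlo percolation centrality: over \code{epcIterations}
#' replicates, each retaining every edge independently iff a
#' uniform(0,1) draw is at least \code{epcThreshold}, the score of a
#' gene is the summed size of its connected component (itself
#' included) divided by the number of ranked genes. With threshold 0
#' (no edge removed) every gene in a connected network scores the
#' replicate count T; with threshold 1 every gene scores T/n. Seeded
#' by \code{rngSeed}, hence bit-reproducible.
#'
#' @inheritParams closenessCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
epcCentrality <- function(net, params = metricParams()) {
    g <- rankedSubgraph(net)
    n <- length(g$adj)
    scores <- numeric(n)
    names(scores) <- g$genes
    if (n == 0L) {
        return(makeCentralityTable("EPC", scores))
    }
    from <- integer(0)
    to <- integer(0)
    for (v in seq_len(n)) {
        nb <- g$adj[[v]]
        nb <- nb[nb > v]
        from <- c(from, rep.int(v, length(nb)))
        to <- c(to, nb)
    }
    m <- length(from)
    acc <- numeric(n)
    withLocalSeed(params@rngSeed, {
        for (rep in seq_len(params@epcIterations)) {
            keep <- stats::runif(m) >= params@epcThreshold
            acc <- acc + componentSizesFromEdges(n, from[keep], to[keep])
        }
    })
    scores[] <- acc / n
    makeCentralityTable("EPC", scores, params = list(
        iterations = params@epcIterations,
        threshold = params@epcThreshold,
        seed = params@rngSeed
    ))
}

#' BottleNeck centrality
#'
#' For every root gene s, a breadth-first shortest-path tree is grown
#' over s's component (neighbours visited in lexicographic gene-id
#' order, first discovery fixes the parent). A gene v (not the root)
#' is a bottleneck of that tree when more than a quarter of the
#' tree's nodes reach the root through v (v itself counted). The
#' score is the number of roots for which the gene is a bottleneck.
#'
#' @inheritParams degreeCentrality
#' @return A \linkS4class{CentralityTable}.
#' @export
bottleneckCentrality <- function(net) {
    g <- rankedSubgraph(net)
    n <- length(g$adj)
    scores <- numeric(n)
    for (s in seq_len(n)) {
        b <- bfsFrom(g$adj, s, parents = TRUE)
        tree <- b$order
        treeSize <- length(tree)
        subtree <- rep.int(1L, n)
        for (v in rev(tree)) {
            p <- b$parent[v]
            if (!is.na(p)) subtree[p] <- subtree[p] + subtree[v]
        }
        hits <- tree[tree != s & subtree[tree] > treeSize / 4]
        scores[hits] <- scores[hits] + 1
    }
    names(scores) <- g$genes
    makeCentralityTable("BottleNeck", scores, params = list(
        tie_rule = "lexicographic-first-discovery",
        threshold = "strict > |V(T)|/4, self counted"
    ))
}

## ---- dispatcher ---------------------------------------------------

#' Compute one centrality table by name
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param metric one of [centralityMetrics()].
#' @param params a \linkS4class{MetricParams}.
#' @return A \linkS4class{CentralityTable}.
#' @examples
#' genes <- data.frame(gene = c("A", "B", "C"), disease_score = c(3, 2, 1))
#' edges <- data.frame(
#'     gene_a = c("A", "B"), gene_b = c("B", "C"),
#'     confidence = c(0.9, 0.9)
#' )
#' net <- buildNetwork(genes, 3, edges, 0.4)
#' metricScores(centralityTable(net, "MCC"))
#' @export
centralityTable <- function(net, metric, params = metricParams()) {
    metric <- match.arg(metric, centralityMetrics())
    switch(metric,
        Betweenness = betweennessCentrality(net),
        BottleNeck = bottleneckCentrality(net),
        ClusteringCoefficient = clusteringCoefficient(net),
        Closeness = closenessCentrality(net, params),
        Degree = degreeCentrality(net),
        DMNC = dmncCentrality(net, params),
        EcCentricity = eccentricityCentrality(net),
        EPC = epcCentrality(net, params),
        MCC = mccCentrality(net),
        MNC = mncCentrality(net),
        Radiality = radialityCentrality(net),
        Stress = stressCentrality(net)
    )
}

#' Compute several centrality tables at once
#'
#' @inheritParams centralityTable
#' @param metrics character vector of measure names, default all 12.
#' @return Named list of \linkS4class{CentralityTable} objects.
#' @export
allCentralities <- function(net, metrics = centralityMetrics(),
                            params = metricParams()) {
    metrics <- vapply(
        metrics, function(m) match.arg(m, centralityMetrics()),
        character(1)
    )
    out <- lapply(metrics, function(m) centralityTable(net, m, params))
    names(out) <- metrics
    out
}

#' Wide score/rank matrix across measures
#'
#' @param tables named list of \linkS4class{CentralityTable} objects
#'   over the same gene set.
#' @param what "rank" or "score".
#' @return Numeric matrix, genes (rows, sorted) by measures (columns).
#' @export
centralityMatrix <- function(tables, what = c("rank", "score")) {
    what <- match.arg(what)
    genes <- sort(names(tables[[1L]]@scores))
    cols <- lapply(tables, function(tb) {
        if (!identical(sort(names(tb@scores)), genes)) {
            stop("centrality tables cover different gene sets", call. = FALSE)
        }
        if (what == "rank") as.numeric(tb@ranks[genes]) else tb@scores[genes]
    })
    out <- do.call(cbind, cols)
    rownames(out) <- genes
    colnames(out) <- vapply(tables, metricName, character(1))
    out
}
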