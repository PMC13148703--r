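## Enrichment of reference biomarkers in top-ranked sets, ranking-
## pattern comparison across measures, conservation scoring, and
## high/low-rank group contrasts.

#' Top fraction of a centrality ranking, tie-aware
#'
#' Takes the best \code{floor(q * n)} genes of a ranking. When the
#' score at the nominal boundary is shared by further genes, every
#' gene tied with the boundary score is included and the set is
#' flagged as tie-extended; enrichment rates computed from such a set
#' are later rescaled by \code{nominal_k / extended_size} so that
#' low-resolution measures (many tied scores) are not credited for an
#' oversized set.
#'
#' @param table a \linkS4class{CentralityTable}.
#' @param q fraction in (0, 1); 0.05 gives the conventional top-5% set.
#' @return A list of class \code{"TopSet"}: \code{metric},
#'   \code{nominal_k}, \code{members} (character, in rank order),
#'   \code{tie_extended}, \code{extended_size}.
#' @examples
#' tb <- rankTable(c(a = 5, b = 4, c = 3, d = 2, e = 1))
#' topFraction(tb, 0.4)$members
#' @export
topFraction <- function(table, q) {
    if (!is(table, "CentralityTable") || length(table@scores) == 0L) {
        stop("table must be a non-empty CentralityTable", call. = FALSE)
    }
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
        stop("q must lie strictly between 0 and 1", call. = FALSE)
    }
    scores <- table@scores
    n <- length(scores)
    k <- as.integer(floor(q * n))
    ord <- order(-scores, names(scores))
    if (k == 0L) {
        members <- character(0)
    } else {
        boundary <- scores[ord[k]]
        members <- names(scores)[ord][scores[ord] >= boundary]
    }
    structure(
        list(
            metric = table@metric,
            nominal_k = k,
            members = members,
            tie_extended = length(members) > k,
            extended_size = length(members)
        ),
        class = "TopSet"
    )
}

#' Biomarker inclusion rate of a top set
#'
#' Percentage of the in-network reference biomarkers found in the top
#' set. The denominator counts every reference gene present in the
#' network, degree-0 genes included. When the top set was extended
#' over a score tie, the reported rate is rescaled by
#' \code{nominal_k / extended_size} (the expected rate under random
#' tie-breaking); the raw unrescaled rate is kept alongside.
#'
#' @param top a \code{TopSet} from [topFraction()].
#' @param biomarkers character vector of reference gene ids.
#' @param net the \linkS4class{PPINetwork} the ranking came from.
#' @return A one-row data.frame: \code{metric}, \code{nominal_k},
#'   \code{extended_size}, \code{tie_extended},
#'   \code{biomarkers_in_top}, \code{biomarkers_in_network},
#'   \code{rate_percent} (tie-rescaled, rounded to one decimal) and
#'   \code{rate_percent_raw} (unrescaled, unrounded).
#' @examples
#' # the worked arithmetic: 4 of 46 in-network biomarkers -> 8.7%
#' round(4 / 46 * 100, 1)
#' @export
inclusionRate <- function(top, biomarkers, net) {
    inNet <- intersect(biomarkers, net@nodes)
    if (length(inNet) == 0L) {
        stop("no reference biomarkers present in the network", call. = FALSE)
    }
    hits <- length(intersect(top$members, inNet))
    raw <- hits / length(inNet) * 100
    rate <- raw
    if (top$tie_extended) {
        rate <- raw * top$nominal_k / top$extended_size
    }
    data.frame(
        metric = top$metric,
        nominal_k = top$nominal_k,
        extended_size = top$extended_size,
        tie_extended = top$tie_extended,
        biomarkers_in_top = hits,
        biomarkers_in_network = length(inNet),
        rate_percent = round(rate, 1),
        rate_percent_raw = raw,
        stringsAsFactors = FALSE
    )
}

#' Inclusion rates over the query-size x confidence grid
#'
#' Builds one network per (topN, minConfidence) cell, ranks its genes
#' with each requested measure, and records the biomarker inclusion
#' rate of every top-\code{q} set, together with marginal averages per
#' measure over query sizes (at fixed confidence) and over confidence
#' cutoffs (at fixed query size).
#'
#' @param genes scored gene data.frame ([readScoredGenes()] layout).
#' @param edges edge data.frame ([readEdgeTable()] layout).
#' @param biomarkers character vector of reference gene ids.
#' @param topNs integer vector of query sizes.
#' @param confidences numeric vector of confidence cutoffs.
#' @param metrics measures to evaluate (default all 12).
#' @param q top fraction (default 0.05).
#' @param params a \linkS4class{MetricParams}.
#' @return A list with data.frames \code{results} (one row per cell x
#'   measure), \code{by_confidence} and \code{by_top_n} (marginal
#'   averages of both the tie-rescaled and raw rates).
#' @export
gridEvaluate <- function(genes, edges, biomarkers, topNs, confidences,
                         metrics = centralityMetrics(), q = 0.05,
                         params = metricParams()) {
    rows <- list()
    for (topN in topNs) {
        for (conf in confidences) {
            net <- buildNetwork(genes, topN, edges, conf)
            tables <- allCentralities(net, metrics, params)
            for (tb in tables) {
                r <- inclusionRate(topFraction(tb, q), biomarkers, net)
                r <- cbind(
                    data.frame(top_n = topN, min_confidence = conf),
                    r
                )
                rows[[length(rows) + 1L]] <- r
            }
        }
    }
    results <- do.call(rbind, rows)
    rownames(results) <- NULL
    avg <- function(df, by) {
        out <- stats::aggregate(
            df[, c("rate_percent", "rate_percent_raw")],
            by = df[by], FUN = mean
        )
        names(out)[names(out) == "rate_percent"] <- "mean_rate_percent"
        names(out)[names(out) == "rate_percent_raw"] <- "mean_rate_percent_raw"
        out
    }
    list(
        results = results,
        by_confidence = avg(results, c("metric", "min_confidence")),
        by_top_n = avg(results, c("metric", "top_n"))
    )
}

#' Biomarker x measure rank matrix
#'
#' Full-network competition ranks of the connected reference
#' biomarkers under each measure. Biomarkers missing from every table
#' (absent from the network, or degree-0 and hence unranked) are
#' dropped with a message; a biomarker ranked by some measures but
#' not others indicates inconsistent tables and is an error.
#'
#' @param tables named list of \linkS4class{CentralityTable} objects.
#' @param biomarkers character vector of reference gene ids.
#' @return Integer matrix, biomarkers (rows, sorted) x measures.
#' @export
biomarkerRankMatrix <- function(tables, biomarkers) {
    ranked <- lapply(tables, function(tb) names(tb@ranks))
    inAll <- sort(Reduce(intersect, lapply(ranked, intersect, x = biomarkers)))
    inAny <- sort(Reduce(union, lapply(ranked, intersect, x = biomarkers)))
    if (!identical(inAll, inAny)) {
        stop("biomarker(s) ranked by only some measures: ",
            paste(setdiff(inAny, inAll), collapse = ", "),
            call. = FALSE
        )
    }
    dropped <- setdiff(biomarkers, inAll)
    if (length(dropped)) {
        message(
            length(dropped), " biomarker(s) not ranked ",
            "(absent or degree 0): ", paste(sort(dropped), collapse = ", ")
        )
    }
    out <- vapply(
        tables, function(tb) as.integer(tb@ranks[inAll]),
        integer(length(inAll))
    )
    out <- matrix(out,
        nrow = length(inAll),
        dimnames = list(inAll, unname(vapply(tables, metricName, character(1))))
    )
    out
}

#' Spearman correlation between measure rankings
#'
#' Pairwise Spearman's rank correlation (average-rank tie correction)
#' between the columns of a biomarker rank matrix.
#'
#' @param rankMatrix matrix from [biomarkerRankMatrix()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(rankMatrix) {
    if (nrow(rankMatrix) < 3L) {
        stop("need at least 3 biomarkers for rank correlation", call. = FALSE)
    }
    rho <- stats::cor(rankMatrix, method = "spearman")
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    rho
}

#' Ward clustering of measures at a correlation threshold
#'
#' Agglomerative clustering of the measures on distance
#' \code{d = 1 - rho} with classic Ward linkage (\code{hclust} method
#' \code{"ward.D"} on the raw distances), cutting the dendrogram at
#' height \code{1 - threshold} so that measure groups merged below a
#' correlation of \code{threshold} stay together.
#'
#' @param rho symmetric correlation matrix with unit diagonal (e.g.
#'   from [spearmanMatrix()]).
#' @param threshold correlation threshold in (-1, 1), default 0.8.
#' @return Named integer vector assigning each measure to a cluster.
#' @export
wardClusters <- function(rho, threshold = 0.8) {
    if (!isSymmetric(unname(rho), tol = 1e-8)) {
        stop("rho must be a symmetric correlation matrix", call. = FALSE)
    }
    if (any(abs(diag(rho) - 1) > 1e-8) || any(abs(rho) > 1 + 1e-8)) {
        stop("rho entries must lie in [-1, 1] with unit diagonal",
            call. = FALSE
        )
    }
    if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < -1e-6) {
        stop("rho is not positive semi-definite", call. = FALSE)
    }
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "ward.D")
    stats::cutree(hc, h = 1 - threshold)
}

#' The five-species conservation panel
#'
#' @return Character vector of the five eukaryote species labels used
#'   for conservation scoring.
#' @export
conservationSpecies <- function() {
    c(
        "S.cerevisiae", "D.melanogaster", "C.elegans",
        "A.thaliana", "D.rerio"
    )
}

#' Evolutionary conservation scores from an ortholog table
#'
#' A gene earns 0.2 points for each panel species in which it has at
#' least one qualifying seed-ortholog pair — an ortholog record with
#' inparalog score exactly 1.0 and seed score >= 0.95 — for a maximum
#' of 1.0 over the five species. Genes without qualifying records
#' score 0.
#'
#' @param orthologs data.frame with columns \code{gene},
#'   \code{species}, \code{inparalog_score}, \code{seed_score}.
#' @param genes character vector of genes to score.
#' @param speciesPanel the species labels (default
#'   [conservationSpecies()]); any other label in the table is an
#'   error.
#' @return A data.frame with columns \code{gene},
#'   \code{n_species_conserved}, \code{conservation_score}; scores
#'   take values in \{0, 0.2, ..., 1.0\}.
#' @examples
#' orth <- data.frame(
#'     gene = "CDC6", species = conservationSpecies(),
#'     inparalog_score = 1, seed_score = 0.99
#' )
#' conservationScores(orth, "CDC6")
#' @export
conservationScores <- function(orthologs, genes,
                               speciesPanel = conservationSpecies()) {
    need <- c("gene", "species", "inparalog_score", "seed_score")
    miss <- setdiff(need, names(orthologs))
    if (length(miss)) {
        stop("ortholog table lacks column(s): ",
            paste(miss, collapse = ", "),
            call. = FALSE
        )
    }
    unknown <- setdiff(unique(orthologs$species), speciesPanel)
    if (length(unknown)) {
        stop("unknown species label(s): ", paste(unknown, collapse = ", "),
            call. = FALSE
        )
    }
    qual <- orthologs[
        orthologs$inparalog_score == 1 & orthologs$seed_score >= 0.95, ,
        drop = FALSE
    ]
    counts <- vapply(genes, function(g) {
        length(unique(qual$species[qual$gene == g]))
    }, integer(1))
    data.frame(
        gene = genes,
        n_species_conserved = unname(counts),
        conservation_score = unname(counts) * 0.2,
        stringsAsFactors = FALSE
    )
}

#' Compare a per-gene value between high- and low-rank biomarkers
#'
#' Splits the biomarkers at the median of their ranks under one
#' measure into a high-ranking and a low-ranking half of (near) equal
#' size (rank ties broken by gene id; with an odd count the high half
#' receives the extra gene), then compares \code{values} between
#' halves with a two-sided Wilcoxon rank-sum test (exact when the
#' combined count is at most 20 and the values carry no ties, normal
#' approximation with tie correction otherwise).
#'
#' @param values named numeric vector, gene -> value (e.g.
#'   conservation or node score).
#' @param ranking a \linkS4class{CentralityTable}.
#' @param biomarkers character vector of genes to split; every one
#'   must have both a value and a rank.
#' @return A list of class \code{"GroupComparison"}: \code{metric},
#'   \code{statistic} (Wilcoxon W), \code{p_value},
#'   \code{group_sizes}, \code{high}, \code{low}.
#' @export
highLowCompare <- function(values, ranking, biomarkers) {
    noVal <- setdiff(biomarkers, names(values))
    noRank <- setdiff(biomarkers, names(ranking@ranks))
    if (length(noVal) || length(noRank)) {
        stop("biomarker(s) lacking a value or rank: ",
            paste(sort(unique(c(noVal, noRank))), collapse = ", "),
            call. = FALSE
        )
    }
    ord <- order(ranking@ranks[biomarkers], biomarkers)
    genes <- biomarkers[ord]
    n <- length(genes)
    nHigh <- ceiling(n / 2)
    high <- genes[seq_len(nHigh)]
    low <- genes[-seq_len(nHigh)]
    if (length(high) < 2L || length(low) < 2L) {
        stop("need at least 2 biomarkers per group", call. = FALSE)
    }
    x <- unname(values[high])
    y <- unname(values[low])
    useExact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(
        x, y,
        alternative = "two.sided",
        exact = useExact, correct = FALSE
    ))
    structure(
        list(
            metric = ranking@metric,
            statistic = unname(wt$statistic),
            p_value = wt$p.value,
            group_sizes = c(high = length(x), low = length(y)),
            high = high, low = low
        ),
        class = "GroupComparison"
    )
}
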