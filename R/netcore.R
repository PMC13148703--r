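## File ingestion and network assembly.
##
## A scored gene table is a data.frame with columns `gene` and
## `disease_score`; an edge table has `gene_a`, `gene_b`, `confidence`.
## Biomarker reference sets are plain character vectors of gene ids.

detectDelimiter <- function(path) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) {
        stop("file '", path, "' is empty (no header line)", call. = FALSE)
    }
    if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

findColumn <- function(cols, candidates, what, path) {
    hit <- which(tolower(cols) %in% candidates)
    if (length(hit) == 0L) {
        stop(
            "file '", path, "': no ", what, " column (looked for ",
            paste(candidates, collapse = "/"), ")",
            call. = FALSE
        )
    }
    hit[1L]
}

#' Read a disease-scored gene table
#'
#' Reads a delimited text export of gene-to-disease association scores
#' (one row per gene, score on the 0-5 disease-score scale). The
#' delimiter (tab or comma) is detected from the header line. Row
#' order of the input is preserved; gene identifiers must be unique.
#'
#' @param path path to a delimited text file with a gene column
#'   (\code{gene}/\code{gene_id}) and a score column
#'   (\code{disease_score}/\code{score}).
#' @return A data.frame with columns \code{gene} (character) and
#'   \code{disease_score} (numeric in [0,5]), in input order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tdisease_score", "TP53\t4.9", "BRCA1\t4.5"), f)
#' readScoredGenes(f)
#' @export
readScoredGenes <- function(path) {
    sep <- detectDelimiter(path)
    df <- utils::read.table(path,
        header = TRUE, sep = sep, quote = "\"",
        colClasses = "character", check.names = FALSE,
        comment.char = "", stringsAsFactors = FALSE
    )
    gi <- findColumn(names(df), c("gene", "gene_id", "gene_name"), "gene", path)
    si <- findColumn(names(df), c("disease_score", "score"), "score", path)
    gene <- df[[gi]]
    score <- suppressWarnings(as.numeric(df[[si]]))
    bad <- which(is.na(score) & nzchar(df[[si]]))
    if (length(bad)) {
        stop(
            "non-numeric disease score on data line(s): ",
            paste(bad, collapse = ", "),
            call. = FALSE
        )
    }
    if (anyNA(score)) {
        stop("missing disease score on data line(s): ",
            paste(which(is.na(score)), collapse = ", "),
            call. = FALSE
        )
    }
    out <- which(score < 0 | score > 5)
    if (length(out)) {
        stop(
            "disease score outside [0, 5] on data line(s): ",
            paste(out, collapse = ", "),
            call. = FALSE
        )
    }
    if (anyDuplicated(gene)) {
        stop("duplicate gene identifiers in '", path, "'", call. = FALSE)
    }
    data.frame(gene = gene, disease_score = score, stringsAsFactors = FALSE)
}

#' Read a confidence-scored interaction edge table
#'
#' Reads a delimited export of undirected interactions with a combined
#' confidence score in [0,1] (a STRING-style edge list). Self-loops
#' are dropped and duplicate unordered pairs are collapsed to the
#' maximum confidence; both events are reported via \code{message()}.
#'
#' @param path path to a delimited text file with two gene columns
#'   (\code{gene_a}/\code{node1}, \code{gene_b}/\code{node2}) and a
#'   score column (\code{combined_score}/\code{confidence}/\code{score}).
#' @return A data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence}; one row per unordered pair with
#'   \code{gene_a < gene_b}.
#' @export
readEdgeTable <- function(path) {
    sep <- detectDelimiter(path)
    df <- utils::read.table(path,
        header = TRUE, sep = sep, quote = "\"",
        colClasses = "character", check.names = FALSE,
        comment.char = "", stringsAsFactors = FALSE
    )
    ai <- findColumn(names(df), c("gene_a", "node1", "protein1"), "gene_a", path)
    bi <- findColumn(names(df), c("gene_b", "node2", "protein2"), "gene_b", path)
    si <- findColumn(
        names(df), c("combined_score", "confidence", "score"),
        "confidence", path
    )
    conf <- suppressWarnings(as.numeric(df[[si]]))
    bad <- which(is.na(conf))
    if (length(bad)) {
        stop("non-numeric confidence on data line(s): ",
            paste(bad, collapse = ", "),
            call. = FALSE
        )
    }
    out <- which(conf < 0 | conf > 1)
    if (length(out)) {
        stop("confidence outside [0, 1] on data line(s): ",
            paste(out, collapse = ", "),
            call. = FALSE
        )
    }
    normalizeEdgeTable(data.frame(
        gene_a = df[[ai]], gene_b = df[[bi]], confidence = conf,
        stringsAsFactors = FALSE
    ))
}

## canonicalise an edge data.frame: drop self-loops, order endpoints
## lexicographically, collapse duplicate unordered pairs to max
## confidence
normalizeEdgeTable <- function(edges, quiet = FALSE) {
    loops <- edges$gene_a == edges$gene_b
    if (any(loops) && !quiet) {
        message("dropped ", sum(loops), " self-loop edge(s)")
    }
    edges <- edges[!loops, , drop = FALSE]
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
        if (!quiet) {
            message(
                "collapsed ", sum(duplicated(key)),
                " duplicate pair(s) to maximum confidence"
            )
        }
        conf <- tapply(edges$confidence, key, max)
        keep <- !duplicated(key)
        out <- data.frame(
            gene_a = a[keep], gene_b = b[keep],
            confidence = as.numeric(conf[key[keep]]),
            stringsAsFactors = FALSE
        )
    } else {
        out <- data.frame(
            gene_a = a, gene_b = b, confidence = edges$confidence,
            stringsAsFactors = FALSE
        )
    }
    rownames(out) <- NULL
    out
}

## top-n query genes by descending disease score, lexicographic gene id
## as the deterministic tie-break
topQueryGenes <- function(genes, topN) {
    ord <- order(-genes$disease_score, genes$gene)
    genes[ord[seq_len(topN)], , drop = FALSE]
}

#' Assemble a confidence-filtered disease network
#'
#' Takes the top \code{topN} query genes by descending disease score
#' (ties broken by lexicographic gene id), keeps those that appear in
#' the edge table's gene vocabulary, and connects them with every edge
#' whose confidence is at least \code{minConfidence}. Query genes that
#' map into the vocabulary but lose all edges at the cutoff are kept
#' as degree-0 nodes; they are excluded later from centrality ranking.
#'
#' @param genes data.frame from [readScoredGenes()].
#' @param topN number of top-scoring query genes to use.
#' @param edges data.frame from [readEdgeTable()].
#' @param minConfidence minimum combined confidence in [0,1] for an
#'   edge to be retained (0.4/0.7/0.9 are the conventional medium/
#'   high/highest-confidence cutoffs).
#' @return A \linkS4class{PPINetwork}.
#' @examples
#' genes <- data.frame(gene = c("A", "B", "C"), disease_score = c(4, 3, 2))
#' edges <- data.frame(gene_a = "A", gene_b = "B", confidence = 0.8)
#' net <- buildNetwork(genes, 3, edges, 0.7)
#' nodeCount(net)
#' @export
buildNetwork <- function(genes, topN, edges, minConfidence) {
    if (!is.numeric(topN) || length(topN) != 1L || topN <= 0) {
        stop("topN must be a positive integer", call. = FALSE)
    }
    topN <- as.integer(topN)
    if (topN > nrow(genes)) {
        stop("topN (", topN, ") exceeds the number of scored genes (",
            nrow(genes), ")",
            call. = FALSE
        )
    }
    if (minConfidence < 0 || minConfidence > 1) {
        stop("minConfidence must lie in [0, 1]", call. = FALSE)
    }
    edges <- normalizeEdgeTable(edges, quiet = TRUE)
    query <- topQueryGenes(genes, topN)
    vocab <- unique(c(edges$gene_a, edges$gene_b))
    mapped <- query[query$gene %in% vocab, , drop = FALSE]
    keep <- edges$confidence >= minConfidence &
        edges$gene_a %in% mapped$gene & edges$gene_b %in% mapped$gene
    kept <- edges[keep, , drop = FALSE]
    ends <- factor(c(kept$gene_a, kept$gene_b), levels = mapped$gene)
    adj <- lapply(
        split(c(kept$gene_b, kept$gene_a), ends),
        function(nb) sort(as.character(nb))
    )
    scores <- mapped$disease_score
    names(scores) <- mapped$gene
    rownames(kept) <- NULL
    new("PPINetwork",
        nodes = mapped$gene, adjacency = adj, edges = kept,
        diseaseScores = scores, minConfidence = as.numeric(minConfidence)
    )
}

#' @describeIn PPINetwork-class gene identifiers of the network nodes.
#' @export
setMethod("nodes", "PPINetwork", function(x) x@nodes)

#' @describeIn PPINetwork-class number of nodes, degree-0 included.
#' @export
setMethod("nodeCount", "PPINetwork", function(x) length(x@nodes))

#' @describeIn PPINetwork-class number of undirected edges.
#' @export
setMethod("edgeCount", "PPINetwork", function(x) nrow(x@edges))

#' @describeIn PPINetwork-class named integer vector of node degrees.
#' @export
setMethod("nodeDegree", "PPINetwork", function(x) {
    d <- lengths(x@adjacency)[x@nodes]
    vapply(d, as.integer, integer(1))
})

#' @describeIn PPINetwork-class neighbours of node \code{v}.
#' @param v a node identifier.
#' @export
setMethod("nodeNeighbors", "PPINetwork", function(x, v) {
    if (!v %in% x@nodes) stop("unknown node '", v, "'", call. = FALSE)
    x@adjacency[[v]]
})

#' @describeIn PPINetwork-class the retained edge table.
#' @export
setMethod("edgeTable", "PPINetwork", function(x) x@edges)

#' @describeIn PPINetwork-class named numeric vector of disease scores.
#' @export
setMethod("diseaseScores", "PPINetwork", function(x) x@diseaseScores)

#' @describeIn PPINetwork-class graph density 2m/(n(n-1)); errors on
#'   networks with fewer than two nodes, where density is undefined.
#' @export
setMethod("networkDensity", "PPINetwork", function(x) {
    n <- length(x@nodes)
    if (n < 2L) {
        stop("density is undefined for networks with fewer than 2 nodes",
            call. = FALSE
        )
    }
    2 * nrow(x@edges) / (n * (n - 1))
})

setMethod("show", "PPINetwork", function(object) {
    n <- length(object@nodes)
    m <- nrow(object@edges)
    iso <- sum(lengths(object@adjacency) == 0L)
    cat("PPINetwork with", n, "nodes and", m, "edges\n")
    cat("  confidence cutoff:", object@minConfidence, "\n")
    cat("  degree-0 nodes:", iso, "\n")
    if (n >= 2L) {
        cat("  density:", format(2 * m / (n * (n - 1)), digits = 4), "\n")
    }
    invisible(object)
})

#' Biomarkers connected in a network
#'
#' Returns the members of a biomarker reference set that are present
#' in the network with degree at least one. Reference genes absent
#' from the network, or present only as degree-0 nodes, are excluded
#' (degree-0 genes carry no topological signal and are dropped from
#' all centrality rankings).
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param biomarkers character vector of reference gene ids.
#' @return Character vector (sorted) of connected in-network biomarkers.
#' @export
connectedBiomarkers <- function(net, biomarkers) {
    present <- intersect(biomarkers, net@nodes)
    deg <- lengths(net@adjacency)[present]
    sort(present[deg >= 1L])
}

#' Summarise a network grid cell
#'
#' One-row summary of a built network in the layout of a network-
#' construction table: node counts with and without degree-0 genes,
#' edge count, density, and how many reference biomarkers mapped in.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param biomarkers optional character vector of reference gene ids.
#' @return A one-row data.frame with columns \code{n_nodes},
#'   \code{n_connected}, \code{m_edges}, \code{density},
#'   \code{min_confidence} and (when a reference set is supplied)
#'   \code{biomarkers_mapped}, \code{biomarkers_connected}.
#' @export
networkSummary <- function(net, biomarkers = NULL) {
    n <- length(net@nodes)
    out <- data.frame(
        n_nodes = n,
        n_connected = sum(lengths(net@adjacency) >= 1L),
        m_edges = nrow(net@edges),
        density = if (n >= 2L) networkDensity(net) else NA_real_,
        min_confidence = net@minConfidence
    )
    if (!is.null(biomarkers)) {
        out$biomarkers_mapped <- length(intersect(biomarkers, net@nodes))
        out$biomarkers_connected <- length(connectedBiomarkers(net, biomarkers))
    }
    out
}
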