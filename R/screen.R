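## Survival and differential-expression filters over the non-biomarker
## top-ranked genes, and biomarker-connectivity profiling of the
## survivors.

#' Median-split log-rank test
#'
#' Splits patients at the median expression of a gene (values exactly
#' at the median go to the low group), then tests the two survival
#' curves with a two-sided log-rank test (chi-squared, 1 df; tied
#' event times handled by the standard hypergeometric variance of
#' \code{survival::survdiff}).
#'
#' @param rec data.frame with columns \code{time} (> 0, months),
#'   \code{event} (0/1) and \code{expression}.
#' @return A list: \code{chisq}, \code{p_value}, \code{group_sizes}
#'   (high/low patient counts).
#' @examples
#' set.seed(1)
#' rec <- data.frame(
#'     time = rexp(40, 0.05), event = rbinom(40, 1, 0.7),
#'     expression = rnorm(40)
#' )
#' medianSplitLogrank(rec)$p_value
#' @export
medianSplitLogrank <- function(rec) {
    need <- c("time", "event", "expression")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
        stop("survival table lacks column(s): ", paste(miss, collapse = ", "),
            call. = FALSE
        )
    }
    if (any(rec$time <= 0) || !all(rec$event %in% c(0, 1))) {
        stop("time must be positive and event must be 0/1", call. = FALSE)
    }
    med <- stats::median(rec$expression)
    high <- rec$expression > med
    if (sum(high) < 2L || sum(!high) < 2L) {
        stop("degenerate median split: fewer than 2 patients in a group ",
            "(constant or near-constant expression)",
            call. = FALSE
        )
    }
    sd <- survival::survdiff(
        survival::Surv(rec$time, rec$event) ~ high,
        rho = 0
    )
    list(
        chisq = unname(sd$chisq),
        p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
        group_sizes = c(high = sum(high), low = sum(!high))
    )
}

#' Kruskal-Wallis with Dunn's post-hoc pairs
#'
#' Compares expression across the normal / tumor / metastatic groups
#' with a tie-corrected Kruskal-Wallis test, followed by Dunn's
#' z-tests on the joint ranks for the two contrasts the screen uses:
#' normal vs tumor and tumor vs metastatic. Dunn p-values are
#' two-sided and unadjusted by default (\code{adjust = "bonferroni"}
#' multiplies by the 3 pairwise comparisons).
#'
#' @param expr data.frame with columns \code{value} (numeric) and
#'   \code{group} (one of "normal", "tumor", "metastatic"); all three
#'   groups must be non-empty.
#' @param adjust "none" (default) or "bonferroni".
#' @return A list: \code{kw_statistic}, \code{kw_p},
#'   \code{dunn_p_normal_tumor}, \code{dunn_p_tumor_metastatic},
#'   \code{dunn_z} (named length-2 vector).
#' @export
kwDunn <- function(expr, adjust = c("none", "bonferroni")) {
    adjust <- match.arg(adjust)
    lv <- c("normal", "tumor", "metastatic")
    if (!all(c("value", "group") %in% names(expr))) {
        stop("expression table needs columns value, group", call. = FALSE)
    }
    if (!all(expr$group %in% lv)) {
        stop("group labels must be normal/tumor/metastatic", call. = FALSE)
    }
    g <- factor(expr$group, levels = lv)
    if (any(table(g) == 0L)) {
        stop("every group must be non-empty", call. = FALSE)
    }
    kw <- stats::kruskal.test(expr$value, g)
    ## Dunn z on joint ranks with tie correction
    r <- rank(expr$value)
    N <- length(r)
    ties <- table(expr$value)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- N * (N + 1) / 12 - tieTerm / (12 * (N - 1))
    meanRank <- tapply(r, g, mean)
    nPer <- tapply(r, g, length)
    zPair <- function(a, b) {
        (meanRank[[a]] - meanRank[[b]]) /
            sqrt(sigma2 * (1 / nPer[[a]] + 1 / nPer[[b]]))
    }
    z <- c(
        normal_tumor = zPair("normal", "tumor"),
        tumor_metastatic = zPair("tumor", "metastatic")
    )
    p <- 2 * stats::pnorm(-abs(z))
    if (adjust == "bonferroni") p[] <- pmin(1, p * 3)
    list(
        kw_statistic = unname(kw$statistic),
        kw_p = kw$p.value,
        dunn_p_normal_tumor = unname(p["normal_tumor"]),
        dunn_p_tumor_metastatic = unname(p["tumor_metastatic"]),
        dunn_z = z
    )
}

#' Assemble filter flags from per-gene tables
#'
#' Runs the median-split log-rank test on each gene's relapse-free
#' and overall-survival tables and the Kruskal-Wallis/Dunn contrasts
#' on its three-group expression table, producing the four p-values
#' the candidate screen thresholds. Precomputed flag tables (columns
#' \code{gene, rfs_p, os_p, nt_p, tm_p}) can be passed to
#' [screenCandidates()] directly instead.
#'
#' @param rfs,os named lists of per-gene survival data.frames
#'   ([medianSplitLogrank()] layout).
#' @param expression named list of per-gene expression data.frames
#'   ([kwDunn()] layout).
#' @param genes genes to flag (default: those present in all three
#'   lists).
#' @return A data.frame with columns \code{gene}, \code{rfs_p},
#'   \code{os_p}, \code{nt_p}, \code{tm_p}, \code{pass}.
#' @export
filterFlags <- function(rfs, os, expression,
                        genes = Reduce(intersect, list(
                            names(rfs), names(os), names(expression)
                        ))) {
    rows <- lapply(genes, function(g) {
        kd <- kwDunn(expression[[g]])
        data.frame(
            gene = g,
            rfs_p = medianSplitLogrank(rfs[[g]])$p_value,
            os_p = medianSplitLogrank(os[[g]])$p_value,
            nt_p = kd$dunn_p_normal_tumor,
            tm_p = kd$dunn_p_tumor_metastatic,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    out$pass <- out$rfs_p < 0.05 & out$os_p < 0.05 &
        out$nt_p < 0.05 & out$tm_p < 0.05
    out
}

#' Four-filter candidate screen
#'
#' From the non-biomarker members of a top-ranked set, keeps the genes
#' whose four p-values (RFS, OS, normal-vs-tumor, tumor-vs-
#' metastatic) are all below \code{alpha}, preserving the ranking
#' order of the top set.
#'
#' @param top a \code{TopSet} from [topFraction()].
#' @param biomarkers character vector of known reference genes
#'   (excluded from screening).
#' @param flags data.frame with columns \code{gene}, \code{rfs_p},
#'   \code{os_p}, \code{nt_p}, \code{tm_p} covering every screened
#'   gene.
#' @param alpha significance threshold (default 0.05).
#' @return Character vector of surviving candidate genes, in rank
#'   order.
#' @export
screenCandidates <- function(top, biomarkers, flags, alpha = 0.05) {
    candidates <- setdiff(top$members, biomarkers) # keeps rank order
    missing <- setdiff(candidates, flags$gene)
    if (length(missing)) {
        stop("no filter flags for screened gene(s): ",
            paste(missing, collapse = ", "),
            call. = FALSE
        )
    }
    f <- flags[match(candidates, flags$gene), , drop = FALSE]
    pass <- f$rfs_p < alpha & f$os_p < alpha &
        f$nt_p < alpha & f$tm_p < alpha
    candidates[pass]
}

#' Biomarker connectivity of candidate genes
#'
#' Counts, for each candidate, the reference biomarkers joined to it
#' by an edge of at least \code{minConfidence}, and expresses the
#' count as a percentage of the full reference panel. Candidates
#' absent from the edge vocabulary score 0 and are reported via
#' \code{message()}.
#'
#' @param candidates character vector of candidate genes.
#' @param reference character vector, the full biomarker reference
#'   panel.
#' @param edges edge data.frame ([readEdgeTable()] layout).
#' @param minConfidence confidence cutoff for counting an interaction.
#' @return A data.frame with columns \code{gene},
#'   \code{linked_biomarkers}, \code{percent_of_reference}.
#' @export
biomarkerConnectivity <- function(candidates, reference, edges,
                                  minConfidence = 0.4) {
    edges <- normalizeEdgeTable(edges, quiet = TRUE)
    edges <- edges[edges$confidence >= minConfidence, , drop = FALSE]
    vocab <- unique(c(edges$gene_a, edges$gene_b))
    absent <- setdiff(candidates, vocab)
    if (length(absent)) {
        message(
            "candidate(s) absent from the edge vocabulary (count 0): ",
            paste(sort(absent), collapse = ", ")
        )
    }
    counts <- vapply(candidates, function(g) {
        partners <- c(
            edges$gene_b[edges$gene_a == g],
            edges$gene_a[edges$gene_b == g]
        )
        length(intersect(partners, reference))
    }, integer(1))
    data.frame(
        gene = candidates,
        linked_biomarkers = unname(counts),
        percent_of_reference = unname(counts) / length(reference) * 100,
        stringsAsFactors = FALSE
    )
}
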