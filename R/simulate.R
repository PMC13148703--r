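## Seeded generators for every input class the pipeline consumes:
## planted-clique interaction networks with disease-scored genes and a
## biomarker reference set, ortholog tables with elevated conservation
## for clique members, and survival/expression tables with hazard and
## group-shift effects for designated true candidates. All output is
## fully determined by the seed (R's Mersenne-Twister stream,
## restored on exit so callers' RNG state is untouched).

#' SyntheticSpec: parameters of the synthetic study conditions
#'
#' Defaults describe a desk-scale emulation of a disease-gene
#' interactome: 300 genes, two disjoint planted 7-cliques over a
#' sparse background (so that a top-5% set can hold every clique
#' member), 16 reference biomarkers of which three quarters sit in
#' clique positions, clique edges drawn with high confidence
#' (so cliques persist, though thinned, at the 0.9 cutoff) and
#' background edges spanning the 0.4/0.7/0.9 cutoffs, a +0.4
#' ortholog-presence boost for clique members, hazard ratio 2.5 for
#' above-median expression of hazard-linked genes, and expression
#' group means 0 / 1.5 / 3 for true candidates.
#'
#' @slot nGenes,nBiomarkers,nCliques,cliqueSize integers.
#' @slot biomarkerCliqueFraction share of biomarkers planted into
#'   clique positions.
#' @slot backgroundEdgeProb Erdos-Renyi probability of a background
#'   edge.
#' @slot cliqueConfRange,backgroundConfRange uniform confidence ranges
#'   for clique and background edges.
#' @slot orthologBaseProb baseline per-species probability of a
#'   qualifying seed-ortholog pair.
#' @slot conservationBoost added probability for clique members.
#' @slot hazardRatio multiplicative hazard for above-median expression
#'   of hazard-linked genes.
#' @slot nPatients patients per survival table.
#' @slot baseHazard exponential event rate per month at baseline.
#' @slot censorMax upper bound (months) of the uniform censoring time.
#' @slot groupShifts numeric(3), normal/tumor/metastatic expression
#'   means for true candidates.
#' @slot nPerGroup samples per expression group.
#' @slot nTrueCandidates non-biomarker clique members given all four
#'   planted effects.
#' @slot rngSeed integer seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(
        nGenes = "integer", nBiomarkers = "integer", nCliques = "integer",
        cliqueSize = "integer", biomarkerCliqueFraction = "numeric",
        backgroundEdgeProb = "numeric", cliqueConfRange = "numeric",
        backgroundConfRange = "numeric", orthologBaseProb = "numeric",
        conservationBoost = "numeric", hazardRatio = "numeric",
        nPatients = "integer", baseHazard = "numeric", censorMax = "numeric",
        groupShifts = "numeric", nPerGroup = "integer",
        nTrueCandidates = "integer", rngSeed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@cliqueSize < 3L) msgs <- c(msgs, "cliqueSize must be >= 3")
    if (object@nCliques * object@cliqueSize > object@nGenes) {
        msgs <- c(msgs, "nCliques * cliqueSize exceeds nGenes")
    }
    if (object@nBiomarkers > object@nGenes) {
        msgs <- c(msgs, "nBiomarkers exceeds nGenes")
    }
    probs <- c(
        object@biomarkerCliqueFraction, object@backgroundEdgeProb,
        object@orthologBaseProb
    )
    if (any(probs < 0 | probs > 1)) {
        msgs <- c(msgs, "probabilities must lie in [0, 1]")
    }
    nCliqueSlots <- object@nCliques * object@cliqueSize
    if (round(object@biomarkerCliqueFraction * object@nBiomarkers) >
        nCliqueSlots) {
        msgs <- c(msgs, "more clique-bound biomarkers than clique slots")
    }
    if (length(object@groupShifts) != 3L) {
        msgs <- c(msgs, "groupShifts must have length 3")
    }
    if (object@hazardRatio <= 0 || object@baseHazard <= 0) {
        msgs <- c(msgs, "hazardRatio and baseHazard must be positive")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param nGenes,nBiomarkers,nCliques,cliqueSize,biomarkerCliqueFraction
#'   network composition; see \linkS4class{SyntheticSpec}.
#' @param backgroundEdgeProb,cliqueConfRange,backgroundConfRange edge
#'   generation parameters.
#' @param orthologBaseProb,conservationBoost ortholog generation.
#' @param hazardRatio,nPatients,baseHazard,censorMax survival
#'   generation.
#' @param groupShifts,nPerGroup expression-group generation.
#' @param nTrueCandidates planted full-effect candidates.
#' @param rngSeed integer seed; all generator output is a pure
#'   function of it.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' syntheticSpec(rngSeed = 7)
#' @export
syntheticSpec <- function(nGenes = 300L, nBiomarkers = 16L, nCliques = 2L,
                          cliqueSize = 7L, biomarkerCliqueFraction = 0.75,
                          backgroundEdgeProb = 0.03,
                          cliqueConfRange = c(0.75, 1),
                          backgroundConfRange = c(0.2, 0.9),
                          orthologBaseProb = 0.3, conservationBoost = 0.4,
                          hazardRatio = 2.5, nPatients = 200L,
                          baseHazard = 0.02, censorMax = 120,
                          groupShifts = c(0, 1.5, 3), nPerGroup = 50L,
                          nTrueCandidates = 2L, rngSeed = 1L) {
    new("SyntheticSpec",
        nGenes = as.integer(nGenes), nBiomarkers = as.integer(nBiomarkers),
        nCliques = as.integer(nCliques), cliqueSize = as.integer(cliqueSize),
        biomarkerCliqueFraction = biomarkerCliqueFraction,
        backgroundEdgeProb = backgroundEdgeProb,
        cliqueConfRange = cliqueConfRange,
        backgroundConfRange = backgroundConfRange,
        orthologBaseProb = orthologBaseProb,
        conservationBoost = conservationBoost,
        hazardRatio = hazardRatio, nPatients = as.integer(nPatients),
        baseHazard = baseHazard, censorMax = censorMax,
        groupShifts = as.numeric(groupShifts),
        nPerGroup = as.integer(nPerGroup),
        nTrueCandidates = as.integer(nTrueCandidates),
        rngSeed = as.integer(rngSeed)
    )
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(
        "SyntheticSpec:", object@nGenes, "genes,", object@nCliques,
        "planted", paste0("K", object@cliqueSize), "cliques,",
        object@nBiomarkers, "biomarkers",
        sprintf("(%.0f%% in cliques),", 100 * object@biomarkerCliqueFraction),
        "seed", object@rngSeed, "\n"
    )
    invisible(object)
})

#' Generate a planted-clique disease network
#'
#' Plants \code{nCliques} vertex-disjoint cliques of size
#' \code{cliqueSize} on randomly chosen genes over an Erdos-Renyi
#' background, assigns a \code{biomarkerCliqueFraction} share of the
#' biomarkers to clique positions (the rest to background genes),
#' draws disease scores so that biomarkers and clique members
#' concentrate in the top query ranks, and gives every edge a
#' confidence drawn from its stratum's range.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed overrides \code{spec@rngSeed} when given.
#' @return A list: \code{genes} (scored gene data.frame),
#'   \code{edges} (edge data.frame), \code{biomarkers} (character),
#'   \code{truth} (data.frame with \code{gene}, \code{is_biomarker},
#'   \code{clique_id}, \code{conservation_propensity},
#'   \code{hazard_linked}, \code{true_candidate}).
#' @examples
#' net <- generateNetwork(syntheticSpec(rngSeed = 7))
#' head(net$truth)
#' @export
generateNetwork <- function(spec, seed = spec@rngSeed) {
    validObject(spec)
    withLocalSeed(seed, {
        n <- spec@nGenes
        genes <- sprintf("G%04d", seq_len(n))
        ## plant disjoint cliques
        cliqueId <- rep(NA_integer_, n)
        slots <- sample.int(n, spec@nCliques * spec@cliqueSize)
        for (c in seq_len(spec@nCliques)) {
            take <- slots[seq_len(spec@cliqueSize) +
                (c - 1L) * spec@cliqueSize]
            cliqueId[take] <- c
        }
        ## biomarkers: a fixed share into clique positions
        nInClique <- round(spec@biomarkerCliqueFraction * spec@nBiomarkers)
        cliquePos <- which(!is.na(cliqueId))
        bgPos <- which(is.na(cliqueId))
        isBio <- logical(n)
        isBio[sample(cliquePos, nInClique)] <- TRUE
        isBio[sample(bgPos, spec@nBiomarkers - nInClique)] <- TRUE
        ## true candidates: non-biomarker clique members
        pool <- setdiff(cliquePos, which(isBio))
        trueCand <- logical(n)
        trueCand[sample(pool, min(spec@nTrueCandidates, length(pool)))] <- TRUE
        ## disease scores: biomarkers and clique members ride high
        score <- stats::runif(n, 0.5, 4.5)
        hot <- isBio | !is.na(cliqueId)
        score[hot] <- stats::runif(sum(hot), 2.5, 5)
        ## edges: all within-clique pairs, plus random background pairs
        pairs <- utils::combn(n, 2L)
        sameClique <- !is.na(cliqueId[pairs[1L, ]]) &
            !is.na(cliqueId[pairs[2L, ]]) &
            cliqueId[pairs[1L, ]] == cliqueId[pairs[2L, ]]
        bgKeep <- !sameClique &
            stats::runif(ncol(pairs)) < spec@backgroundEdgeProb
        keep <- sameClique | bgKeep
        conf <- numeric(sum(keep))
        strata <- sameClique[keep]
        conf[strata] <- stats::runif(
            sum(strata),
            spec@cliqueConfRange[1L], spec@cliqueConfRange[2L]
        )
        conf[!strata] <- stats::runif(
            sum(!strata),
            spec@backgroundConfRange[1L], spec@backgroundConfRange[2L]
        )
        edges <- data.frame(
            gene_a = genes[pairs[1L, keep]],
            gene_b = genes[pairs[2L, keep]],
            confidence = conf,
            stringsAsFactors = FALSE
        )
        truth <- data.frame(
            gene = genes,
            is_biomarker = isBio,
            clique_id = cliqueId,
            conservation_propensity = pmin(
                1, spec@orthologBaseProb +
                    spec@conservationBoost * !is.na(cliqueId)
            ),
            hazard_linked = trueCand,
            true_candidate = trueCand,
            stringsAsFactors = FALSE
        )
        list(
            genes = data.frame(
                gene = genes, disease_score = score,
                stringsAsFactors = FALSE
            ),
            edges = edges,
            biomarkers = genes[isBio],
            truth = truth
        )
    })
}

#' Generate an ortholog table
#'
#' For every gene and each of the five panel species, a qualifying
#' seed-ortholog record (inparalog score 1.0, seed score drawn in
#' [0.95, 1]) is emitted with the gene's conservation propensity;
#' otherwise, with probability 0.5, a decoy record that fails one of
#' the two gates (seed score below 0.95, or inparalog score below
#' 1.0) is emitted instead, so the qualifying rule is genuinely
#' exercised.
#'
#' @param truth ground-truth data.frame from [generateNetwork()].
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed overrides \code{spec@rngSeed + 1} when given.
#' @return Ortholog data.frame with columns \code{gene},
#'   \code{species}, \code{inparalog_score}, \code{seed_score}.
#' @export
generateOrthologs <- function(truth, spec, seed = spec@rngSeed + 1L) {
    withLocalSeed(seed, {
        rows <- list()
        for (i in seq_len(nrow(truth))) {
            p <- truth$conservation_propensity[i]
            for (sp in conservationSpecies()) {
                u <- stats::runif(1)
                if (u < p) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        gene = truth$gene[i], species = sp,
                        inparalog_score = 1,
                        seed_score = stats::runif(1, 0.95, 1),
                        stringsAsFactors = FALSE
                    )
                } else if (stats::runif(1) < 0.5) {
                    failSeed <- stats::runif(1) < 0.5
                    rows[[length(rows) + 1L]] <- data.frame(
                        gene = truth$gene[i], species = sp,
                        inparalog_score = if (failSeed) {
                            1
                        } else {
                            stats::runif(1, 0.3, 0.9)
                        },
                        seed_score = if (failSeed) {
                            stats::runif(1, 0.5, 0.949)
                        } else {
                            stats::runif(1, 0.95, 1)
                        },
                        stringsAsFactors = FALSE
                    )
                }
            }
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}

## one survival table: exponential event times, hazard multiplied for
## above-median expression when linked; uniform censoring
simulateSurvivalTable <- function(spec, linked) {
    n <- spec@nPatients
    expression <- stats::rnorm(n)
    hr <- if (linked) spec@hazardRatio else 1
    rate <- spec@baseHazard *
        ifelse(expression > stats::median(expression), hr, 1)
    eventTime <- stats::rexp(n, rate)
    censorTime <- stats::runif(n, 0, spec@censorMax)
    data.frame(
        time = pmin(eventTime, censorTime),
        event = as.integer(eventTime <= censorTime),
        expression = expression
    )
}

## one three-group expression table; shifts apply to true candidates
simulateExpressionTable <- function(spec, shifted) {
    shifts <- if (shifted) spec@groupShifts else c(0, 0, 0)
    groups <- c("normal", "tumor", "metastatic")
    data.frame(
        value = stats::rnorm(
            3L * spec@nPerGroup,
            mean = rep(shifts, each = spec@nPerGroup)
        ),
        group = rep(groups, each = spec@nPerGroup),
        stringsAsFactors = FALSE
    )
}

#' Generate survival and expression tables
#'
#' Per gene: one relapse-free-survival and one overall-survival table
#' (exponential event times with the spec's hazard ratio applied to
#' above-median expression of hazard-linked genes, uniform
#' censoring), and one three-group expression table (normal / tumor /
#' metastatic means follow \code{groupShifts} for true candidates,
#' all zero otherwise).
#'
#' @param truth ground-truth data.frame from [generateNetwork()].
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param genes genes to simulate (default: all in \code{truth}).
#' @param seed overrides \code{spec@rngSeed + 2} when given.
#' @return A list with named lists \code{rfs}, \code{os},
#'   \code{expression}, each keyed by gene.
#' @export
generateSurvivalExpression <- function(truth, spec, genes = truth$gene,
                                       seed = spec@rngSeed + 2L) {
    withLocalSeed(seed, {
        idx <- match(genes, truth$gene)
        if (anyNA(idx)) {
            stop("genes absent from the ground truth", call. = FALSE)
        }
        rfs <- list()
        os <- list()
        expression <- list()
        for (j in seq_along(genes)) {
            g <- genes[j]
            linked <- truth$hazard_linked[idx[j]]
            shifted <- truth$true_candidate[idx[j]]
            rfs[[g]] <- simulateSurvivalTable(spec, linked)
            os[[g]] <- simulateSurvivalTable(spec, linked)
            expression[[g]] <- simulateExpressionTable(spec, shifted)
        }
        list(rfs = rfs, os = os, expression = expression)
    })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every file the ingestion layer reads — scored genes, edge
#' table, biomarker list, ortholog table, long-format survival tables
#' for both endpoints and the three-group expression table — plus the
#' ground-truth manifest of planted structure, all as tab-separated
#' text.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created if needed).
#' @param seed overrides \code{spec@rngSeed} when given.
#' @return Invisibly, a named list of the written file paths.
#' @export
endToEndFixture <- function(spec, dir, seed = spec@rngSeed) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    net <- generateNetwork(spec, seed)
    orth <- generateOrthologs(net$truth, spec, seed + 1L)
    surv <- generateSurvivalExpression(net$truth, spec, seed = seed + 2L)
    long <- function(lst) {
        do.call(rbind, lapply(names(lst), function(g) {
            cbind(data.frame(gene = g, stringsAsFactors = FALSE), lst[[g]])
        }))
    }
    paths <- list(
        genes = file.path(dir, "genes.tsv"),
        edges = file.path(dir, "edges.tsv"),
        biomarkers = file.path(dir, "biomarkers.txt"),
        orthologs = file.path(dir, "orthologs.tsv"),
        rfs = file.path(dir, "survival_rfs.tsv"),
        os = file.path(dir, "survival_os.tsv"),
        expression = file.path(dir, "expression.tsv"),
        truth = file.path(dir, "truth.tsv")
    )
    writeTsv(net$genes, paths$genes)
    writeTsv(net$edges, paths$edges)
    writeLines(net$biomarkers, paths$biomarkers)
    writeTsv(orth, paths$orthologs)
    writeTsv(long(surv$rfs), paths$rfs)
    writeTsv(long(surv$os), paths$os)
    writeTsv(long(surv$expression), paths$expression)
    writeTsv(net$truth, paths$truth)
    invisible(paths)
}

#' Run the full screen on a synthetic bundle
#'
#' Convenience pipeline from an in-memory synthetic bundle to the
#' candidate report: build the network, rank genes by maximal clique
#' centrality, take the tie-aware top fraction, compute the four
#' filter p-values for the non-biomarker members, screen them, and
#' profile the survivors' biomarker connectivity.
#'
#' @param bundle list from [generateNetwork()].
#' @param spec the \linkS4class{SyntheticSpec} used to generate it.
#' @param topN query size (default: all genes).
#' @param minConfidence edge confidence cutoff (default 0.4).
#' @param q top fraction (default 0.05).
#' @param seed seed for the survival/expression draws (default
#'   \code{spec@rngSeed + 2}).
#' @return A list: \code{network}, \code{mcc}
#'   (\linkS4class{CentralityTable}), \code{top} (TopSet),
#'   \code{flags}, \code{candidates} (character),
#'   \code{report} (data.frame: gene, mcc_rank, the four p-values,
#'   pass, linked_biomarkers, percent_of_reference).
#' @export
screenPipeline <- function(bundle, spec, topN = nrow(bundle$genes),
                           minConfidence = 0.4, q = 0.05,
                           seed = spec@rngSeed + 2L) {
    net <- buildNetwork(bundle$genes, topN, bundle$edges, minConfidence)
    mcc <- mccCentrality(net)
    top <- topFraction(mcc, q)
    screened <- setdiff(top$members, bundle$biomarkers)
    surv <- generateSurvivalExpression(
        bundle$truth, spec,
        genes = screened, seed = seed
    )
    flags <- filterFlags(surv$rfs, surv$os, surv$expression, genes = screened)
    candidates <- screenCandidates(top, bundle$biomarkers, flags)
    conn <- biomarkerConnectivity(
        candidates, bundle$biomarkers, bundle$edges, minConfidence
    )
    report <- flags
    report$mcc_rank <- as.integer(metricRanks(mcc)[report$gene])
    report <- merge(report, conn, by = "gene", all.x = TRUE)
    report$linked_biomarkers[is.na(report$linked_biomarkers)] <- 0L
    report$percent_of_reference[is.na(report$percent_of_reference)] <- 0
    report <- report[order(report$mcc_rank, report$gene), c(
        "gene", "mcc_rank", "rfs_p", "os_p", "nt_p", "tm_p", "pass",
        "linked_biomarkers", "percent_of_reference"
    )]
    rownames(report) <- NULL
    list(
        network = net, mcc = mcc, top = top, flags = flags,
        candidates = candidates, report = report
    )
}
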