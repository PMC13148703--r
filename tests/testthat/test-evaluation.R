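test_that("top-fraction selection sizes the set and extends over ties", {
  # 1362 distinct scores: floor(0.05 * 1362) = 68, no extension
  set.seed(21)
  s <- setNames(sample(10000, 1362), sprintf("g%04d", 1:1362))
  top <- topFraction(rankTable(s), 0.05)
  expect_identical(top$nominal_k, 68L)
  expect_identical(top$extended_size, 68L)
  expect_false(top$tie_extended)
  expect_setequal(top$members, names(sort(-s))[1:68])

  s2 <- setNames(sample(1000, 100), paste0("h", 1:100))
  expect_identical(topFraction(rankTable(s2), 0.05)$nominal_k, 5L)

  # 5 genes at score 2, 5 at score 1, q = 0.3: nominal 3 extends to 5
  s3 <- setNames(rep(c(2, 1), each = 5), paste0("t", 1:10))
  top3 <- topFraction(rankTable(s3), 0.3)
  expect_identical(top3$nominal_k, 3L)
  expect_identical(top3$extended_size, 5L)
  expect_true(top3$tie_extended)
  expect_setequal(top3$members, paste0("t", 1:5))

  expect_error(topFraction(rankTable(s3), 0), "strictly between")
  expect_error(topFraction(rankTable(s3), 1), "strictly between")
})

test_that("inclusion rates reproduce the worked percentages", {
  # a network holding 46 biomarkers, 4 of them in the top set
  bio <- sprintf("B%02d", 1:46)
  others <- sprintf("N%02d", 1:20)
  ids <- c(bio, others)
  ring <- data.frame(
    gene_a = ids, gene_b = c(ids[-1], ids[1]),
    confidence = 1
  )
  net <- mkNet(ring)
  top <- structure(
    list(
      metric = "Betweenness", nominal_k = 10L,
      members = c(bio[1:4], others[1:6]),
      tie_extended = FALSE, extended_size = 10L
    ),
    class = "TopSet"
  )
  r <- inclusionRate(top, bio, net)
  expect_identical(r$biomarkers_in_top, 4L)
  expect_identical(r$biomarkers_in_network, 46L)
  expect_equal(r$rate_percent, 8.7) # 4/46 x 100

  top0 <- top
  top0$members <- others[1:10]
  expect_equal(inclusionRate(top0, bio, net)$rate_percent, 0)

  # tie-extended sets are rescaled by nominal/extended
  topx <- top
  topx$tie_extended <- TRUE
  topx$extended_size <- 20L
  rx <- inclusionRate(topx, bio, net)
  expect_equal(rx$rate_percent_raw, 4 / 46 * 100)
  expect_equal(rx$rate_percent, round(4 / 46 * 100 * 10 / 20, 1))

  expect_error(inclusionRate(top, c("Q1", "Q2"), net), "no reference")
})

test_that("full inclusion gives 100 percent exactly when untied", {
  bio <- c("a", "b")
  net <- mkNet(completeEdges(c("a", "b", "c", "d")))
  top <- structure(
    list(
      metric = "Degree", nominal_k = 2L, members = c("a", "b"),
      tie_extended = FALSE, extended_size = 2L
    ),
    class = "TopSet"
  )
  expect_equal(inclusionRate(top, bio, net)$rate_percent, 100)
})

test_that("grid evaluation matches its single-cell constituent", {
  spec <- syntheticSpec(
    nGenes = 60L, nBiomarkers = 8L, nCliques = 2L, cliqueSize = 5L,
    nTrueCandidates = 1L, rngSeed = 3L
  )
  b <- generateNetwork(spec)
  g <- gridEvaluate(
    b$genes, b$edges, b$biomarkers,
    topNs = 60, confidences = 0.4, metrics = "MCC"
  )
  expect_identical(nrow(g$results), 1L)
  net <- buildNetwork(b$genes, 60, b$edges, 0.4)
  direct <- inclusionRate(
    topFraction(mccCentrality(net), 0.05), b$biomarkers, net
  )
  expect_equal(g$results$rate_percent, direct$rate_percent)
  # single-cell marginals collapse to the cell itself
  expect_equal(g$by_confidence$mean_rate_percent, direct$rate_percent)
  expect_equal(g$by_top_n$mean_rate_percent, direct$rate_percent)
})

test_that("clique-planted biomarkers give MCC the best average rate", {
  spec <- syntheticSpec(
    nGenes = 120L, nBiomarkers = 12L, nCliques = 2L, cliqueSize = 6L,
    biomarkerCliqueFraction = 1, nTrueCandidates = 1L, rngSeed = 17L
  )
  b <- generateNetwork(spec)
  g <- gridEvaluate(
    b$genes, b$edges, b$biomarkers,
    topNs = c(80, 120), confidences = c(0.4, 0.7),
    params = metricParams(epcIterations = 100, rngSeed = 1)
  )
  avg <- tapply(g$results$rate_percent, g$results$metric, mean)
  expect_true(avg[["MCC"]] >= max(avg))
  expect_gt(avg[["MCC"]], avg[["Betweenness"]])
})

test_that("biomarker rank matrices carry full-network competition ranks", {
  net <- mkNet(rbind(
    completeEdges(c("a", "b", "c", "d")),
    data.frame(gene_a = "d", gene_b = "e", confidence = 1),
    data.frame(gene_a = "e", gene_b = "f", confidence = 1)
  ), extra = "z")
  tables <- allCentralities(net, c("Degree", "MCC", "Closeness"))
  bio <- c("a", "d", "f", "z", "missing")
  expect_message(M <- biomarkerRankMatrix(tables, bio), "not ranked")
  expect_identical(rownames(M), c("a", "d", "f"))
  expect_identical(colnames(M), c("Degree", "MCC", "Closeness"))
  expect_identical(M[, "Degree"], metricRanks(tables$Degree)[c("a", "d", "f")])

  # identical scores give identical columns
  t2 <- list(x = rankTable(c(a = 1, d = 2, f = 3), "m1"),
             y = rankTable(c(a = 10, d = 20, f = 30), "m2"))
  M2 <- biomarkerRankMatrix(t2, c("a", "d", "f"))
  expect_identical(M2[, 1], M2[, 2])
})

test_that("rank correlation handles ties like the closed-form oracle", {
  M <- cbind(
    m1 = c(1, 2, 2, 4, 5),
    m2 = c(2, 1, 4, 4, 3)
  )
  rownames(M) <- paste0("g", 1:5)
  rho <- spearmanMatrix(M)
  expect_equal(diag(rho), c(m1 = 1, m2 = 1))
  expect_equal(rho[1, 2], rho[2, 1])
  # oracle: Pearson product-moment on midranks, from raw sums
  midrank <- function(x) {
    vapply(x, function(v) mean(which(sort(x) == v)), numeric(1))
  }
  pearson <- function(a, b) {
    n <- length(a)
    (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  }
  expect_equal(rho[1, 2], pearson(midrank(M[, 1]), midrank(M[, 2])))

  # perfect agreement and perfect reversal
  R <- cbind(a = 1:5, b = 1:5, c = 5:1)
  rho2 <- spearmanMatrix(R)
  expect_equal(rho2["a", "b"], 1)
  expect_equal(rho2["a", "c"], -1)
  expect_error(spearmanMatrix(M[1:2, ]), "at least 3")

  # invariance under common monotone transform of the underlying scores
  set.seed(5)
  s <- matrix(runif(40), 10, 4, dimnames = list(paste0("g", 1:10), paste0("m", 1:4)))
  r1 <- spearmanMatrix(apply(s, 2, rank))
  r2 <- spearmanMatrix(apply(exp(3 * s), 2, rank))
  expect_equal(r1, r2)
})

test_that("measure clustering cuts the Ward dendrogram at 1 - rho", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.95
  rho[1, 3] <- rho[3, 1] <- -0.8
  rho[2, 3] <- rho[3, 2] <- -0.8
  dimnames(rho) <- list(c("m1", "m2", "m3"), c("m1", "m2", "m3"))
  cl <- wardClusters(rho, 0.8)
  expect_identical(cl[["m1"]], cl[["m2"]])
  expect_false(cl[["m1"]] == cl[["m3"]])

  # all correlations below the threshold: all singletons
  lo <- diag(3)
  lo[lower.tri(lo)] <- lo[upper.tri(lo)] <- 0.1
  dimnames(lo) <- dimnames(rho)
  expect_identical(length(unique(wardClusters(lo, 0.8))), 3L)

  expect_identical(wardClusters(rho, 0.8), wardClusters(rho, 0.8))
  bad <- rho
  bad[1, 2] <- 0.2 # asymmetric
  expect_error(wardClusters(bad, 0.8), "symmetric")
  psd <- matrix(c(1, 1, -1, 1, 1, 1, -1, 1, 1), 3, 3)
  expect_error(wardClusters(psd, 0.8), "positive semi-definite")
})

test_that("conservation scores award 0.2 per qualifying species", {
  sp <- conservationSpecies()
  orth <- rbind(
    data.frame(gene = "CDC6", species = sp, inparalog_score = 1,
               seed_score = c(0.99, 0.95, 1, 0.97, 0.96)),
    data.frame(gene = "G3", species = sp[1:3], inparalog_score = 1,
               seed_score = 0.98),
    data.frame(gene = "G3", species = sp[4], inparalog_score = 1,
               seed_score = 0.90), # fails the seed gate
    data.frame(gene = "G4", species = sp[1], inparalog_score = 0.8,
               seed_score = 0.99) # fails the inparalog gate
  )
  tab <- conservationScores(orth, c("CDC6", "G3", "G4", "G5"))
  expect_equal(tab$conservation_score, c(1.0, 0.6, 0, 0))
  expect_true(all(tab$conservation_score %in% seq(0, 1, 0.2)))

  bad <- data.frame(gene = "X", species = "H.sapiens",
                    inparalog_score = 1, seed_score = 1)
  expect_error(conservationScores(bad, "X"), "unknown species")
})

test_that("high/low-rank splits are balanced and Wilcoxon-tested", {
  mk <- function(n) {
    set.seed(n)
    genes <- sprintf("b%02d", 1:n)
    rankTable(setNames(sample(1000, n), genes))
  }
  tb64 <- mk(64)
  vals <- setNames(runif(64), names(metricScores(tb64)))
  cmp <- highLowCompare(vals, tb64, names(vals))
  expect_identical(unname(cmp$group_sizes), c(32L, 32L))
  tb62 <- mk(62)
  v62 <- setNames(runif(62), names(metricScores(tb62)))
  expect_identical(
    unname(highLowCompare(v62, tb62, names(v62))$group_sizes),
    c(31L, 31L)
  )

  # mirror-symmetric toy: both halves share {1, 2}, p = 1
  tb4 <- rankTable(c(w = 4, x = 3, y = 2, z = 1))
  p1 <- highLowCompare(c(w = 1, x = 2, y = 1, z = 2), tb4, c("w", "x", "y", "z"))
  expect_equal(p1$p_value, 1)

  # high = {1,2}, low = {3,4}: exact two-sided p = 2/6
  p2 <- highLowCompare(c(w = 1, x = 2, y = 3, z = 4), tb4, c("w", "x", "y", "z"))
  expect_equal(p2$p_value, 1 / 3, tolerance = 1e-12)

  expect_error(
    highLowCompare(c(w = 1), tb4, c("w", "q")),
    "lacking a value or rank"
  )
})

test_that("the Wilcoxon route matches exact enumeration on small fixtures", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    vals <- sample(100, n) # distinct, so the exact path is taken
    genes <- paste0("g", seq_len(n))
    tb <- rankTable(setNames(sample(1000, n), genes))
    cmp <- highLowCompare(setNames(vals, genes), tb, genes)
    ordByRank <- genes[order(metricRanks(tb)[genes], genes)]
    nh <- ceiling(n / 2)
    x <- vals[match(ordByRank[1:nh], genes)]
    y <- vals[match(ordByRank[(nh + 1):n], genes)]
    expect_equal(cmp$p_value, oWilcoxExact(x, y), tolerance = 1e-12)
  }
})
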