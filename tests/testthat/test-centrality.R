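test_that("toy graphs reproduce the hand-computed centrality values", {
  k3 <- k3Net()
  k4 <- k4Net()
  p3 <- p3Net()
  st <- starNet() # a is the hub

  sc <- function(tb) metricScores(tb)

  expect_equal(unname(sc(degreeCentrality(k4))), rep(3, 4))
  expect_equal(sc(degreeCentrality(p3))[["b"]], 2)
  expect_equal(sc(degreeCentrality(p3))[["a"]], 1)

  expect_equal(sc(betweennessCentrality(p3))[["b"]], 1)
  expect_equal(unname(sc(betweennessCentrality(k3))), rep(0, 3))
  expect_equal(sc(betweennessCentrality(st))[["a"]], 3)

  expect_equal(sc(stressCentrality(p3))[["b"]], 1)
  expect_equal(sc(stressCentrality(st))[["a"]], 3)
  expect_equal(unname(sc(stressCentrality(k4))), rep(0, 4))

  expect_equal(sc(closenessCentrality(p3))[["b"]], 2)
  expect_equal(sc(closenessCentrality(p3))[["a"]], 1.5)
  expect_equal(unname(sc(closenessCentrality(k4))), rep(3, 4))

  expect_equal(unname(sc(radialityCentrality(k3))), rep(1, 3))
  expect_equal(sc(radialityCentrality(p3))[["b"]], 2)
  expect_equal(sc(radialityCentrality(p3))[["a"]], 1.5)
  expect_equal(sc(radialityCentrality(st))[["a"]], 2)

  expect_equal(unname(sc(eccentricityCentrality(k3))), rep(1, 3))
  expect_equal(sc(eccentricityCentrality(p3))[["a"]], 0.5)
  expect_equal(sc(eccentricityCentrality(p3))[["b"]], 1)

  expect_equal(unname(sc(clusteringCoefficient(k4))), rep(1, 4))
  expect_equal(sc(clusteringCoefficient(st))[["a"]], 0)
  # K4 minus one edge: the two degree-3 nodes see 2 of 3 neighbour pairs
  k4m <- mkNet(completeEdges(c("a", "b", "c", "d"))[-1, ]) # drop a-b
  expect_equal(sc(clusteringCoefficient(k4m))[["c"]], 2 * 2 / (3 * 2))

  expect_equal(unname(sc(mncCentrality(k4))), rep(3, 4))
  expect_equal(sc(mncCentrality(p3))[["b"]], 1)
  expect_equal(sc(mncCentrality(st))[["a"]], 1)

  expect_equal(sc(dmncCentrality(k4))[["a"]], 3 / 3^1.7)
  expect_equal(sc(dmncCentrality(k3))[["a"]], 1 / 2^1.7)
  expect_equal(sc(dmncCentrality(p3))[["b"]], 0)

  expect_equal(unname(sc(mccCentrality(k4))), rep(6, 4)) # 3!
  expect_equal(sc(mccCentrality(p3))[["b"]], 2) # 1! + 1!
  expect_equal(sc(mccCentrality(st))[["a"]], 3) # edgeless neighbourhood

  expect_equal(sc(bottleneckCentrality(st))[["a"]], 3)
  expect_equal(unname(sc(bottleneckCentrality(st))[c("b", "c", "d")]), rep(0, 3))
  k2 <- mkNet(cbind("a", "b"))
  expect_equal(unname(sc(bottleneckCentrality(k2))), c(1, 1))
})

test_that("deterministic metrics match exhaustive oracles on random graphs", {
  fam <- randomConnectedAdj(30, seed = 101)
  for (A in fam) {
    net <- netFromAdjMatrix(A)
    ids <- rownames(A)
    o <- function(x) setNames(x, ids)[names(metricScores(degreeCentrality(net)))]

    pl <- oPathLoad(A)
    expect_equal(metricScores(betweennessCentrality(net)), o(pl$betweenness))
    expect_equal(metricScores(stressCentrality(net)), o(pl$stress))
    expect_equal(metricScores(closenessCentrality(net)), o(oCloseness(A)))
    expect_equal(metricScores(radialityCentrality(net)), o(oRadiality(A)))
    expect_equal(metricScores(eccentricityCentrality(net)), o(oEccentricity(A)))
    expect_equal(metricScores(clusteringCoefficient(net)), o(oClustering(A)))
    expect_equal(metricScores(mncCentrality(net)), o(oMNC(A)))
    expect_equal(metricScores(dmncCentrality(net)), o(oDMNC(A)))
    expect_equal(metricScores(mccCentrality(net)), o(oMCC(A)))
    expect_equal(metricScores(bottleneckCentrality(net)), o(oBottleneck(A)))
    expect_equal(
      metricScores(degreeCentrality(net)),
      o(rowSums(A))
    )
  }
})

test_that("results agree with igraph on library-covered measures", {
  skip_if_not_installed("igraph")
  fam <- randomConnectedAdj(10, seed = 55)
  for (A in fam) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    net <- netFromAdjMatrix(A)
    ids <- names(metricScores(degreeCentrality(net)))
    bw <- igraph::betweenness(g)
    expect_equal(metricScores(betweennessCentrality(net)), bw[ids])
    hc <- igraph::harmonic_centrality(g, normalized = FALSE)
    expect_equal(metricScores(closenessCentrality(net)), hc[ids])
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    names(cc) <- rownames(A)
    expect_equal(metricScores(clusteringCoefficient(net)), cc[ids])
  }
})

test_that("percolation centrality honours its boundary thresholds and seed", {
  p3 <- p3Net()
  t0 <- epcCentrality(p3, metricParams(epcIterations = 50, epcThreshold = 0))
  expect_equal(unname(metricScores(t0)), rep(50, 3)) # nothing removed
  t1 <- epcCentrality(p3, metricParams(epcIterations = 50, epcThreshold = 1))
  expect_equal(unname(metricScores(t1)), rep(50 / 3, 3)) # everything removed

  a <- epcCentrality(p3, metricParams(epcIterations = 200, rngSeed = 9))
  b <- epcCentrality(p3, metricParams(epcIterations = 200, rngSeed = 9))
  expect_identical(metricScores(a), metricScores(b)) # bit-reproducible
  c2 <- epcCentrality(p3, metricParams(epcIterations = 200, rngSeed = 10))
  expect_false(identical(metricScores(a), metricScores(c2)))

  # K3 at threshold 0.5: compare to exact enumeration of the 8 edge
  # subsets, within 3 Monte-Carlo standard errors
  k3 <- k3Net()
  T <- 10000
  est <- metricScores(epcCentrality(
    k3, metricParams(epcIterations = T, epcThreshold = 0.5, rngSeed = 4)
  ))
  A <- matrix(1, 3, 3) - diag(3)
  dimnames(A) <- list(c("a", "b", "c"), c("a", "b", "c"))
  exact <- oEPCExact(A, 0.5)
  for (i in 1:3) {
    se <- sqrt(T * exact$var[i]) / 3 # score = T * meanSize / n
    expect_lt(abs(est[i] - T * exact$mean[i] / 3), 3 * se)
  }
})

test_that("competition ranking follows the 1224 rule", {
  tb <- rankTable(c(a = 3, b = 3, c = 1))
  expect_identical(unname(metricRanks(tb)[c("a", "b", "c")]), c(1L, 1L, 3L))

  # four tied leaders, then the next distinct score ranks fifth
  tb2 <- rankTable(c(g1 = 9, g2 = 9, g3 = 9, g4 = 9, g5 = 7, g6 = 5))
  expect_identical(
    unname(metricRanks(tb2)[paste0("g", 1:6)]),
    c(1L, 1L, 1L, 1L, 5L, 6L)
  )

  set.seed(8)
  s <- setNames(sample(100, 20), paste0("x", 1:20))
  expect_identical(sort(unname(metricRanks(rankTable(s)))), 1:20)

  # invariance under order-preserving transforms
  expect_identical(
    metricRanks(rankTable(s)),
    metricRanks(rankTable(log(s + 1)))
  )
  expect_error(rankTable(c(1, 2)), "names")
})

test_that("vertex-transitive graphs score identically at every node", {
  k5 <- mkNet(completeEdges(letters[1:5]))
  c6 <- mkNet(cbind(letters[1:6], letters[c(2:6, 1)]))
  for (net in list(k5, c6)) {
    for (m in centralityMetrics()) {
      # EPC is Monte-Carlo: node symmetry holds only in expectation
      if (m == "EPC") next
      # BottleNeck's deterministic lexicographic tie-break picks one
      # shortest-path tree per root, which is not label-symmetric on
      # cycles; only tie-free transitive graphs (complete) stay exact
      if (m == "BottleNeck" && nodeCount(net) == 6L) next
      tb <- centralityTable(net, m)
      expect_equal(
        max(metricScores(tb)) - min(metricScores(tb)), 0,
        info = paste(m)
      )
    }
    # EPC: per-node spread stays within Monte-Carlo noise of the
    # common expectation (comp sizes <= n, so score SE <= sqrt(T)*n/n)
    T <- 400
    epc <- metricScores(epcCentrality(net, metricParams(epcIterations = T)))
    se <- sqrt(T * nodeCount(net)^2 / 4) / nodeCount(net)
    expect_lt(max(epc) - min(epc), 6 * se)
  }
})

test_that("structural score bounds hold on random graphs", {
  fam <- randomConnectedAdj(15, seed = 77)
  for (A in fam) {
    net <- netFromAdjMatrix(A)
    deg <- metricScores(degreeCentrality(net))
    mcc <- metricScores(mccCentrality(net))
    expect_true(all(mcc >= deg - 1e-9)) # each edge sits in >= 1 maximal clique
    clo <- metricScores(closenessCentrality(net))
    n <- nodeCount(net)
    expect_true(all(clo <= n - 1 + 1e-9))
    full <- names(deg)[deg == n - 1]
    expect_equal(names(clo)[abs(clo - (n - 1)) < 1e-9], full)
  }
})

test_that("degree-0 genes never enter a centrality table", {
  net <- mkNet(completeEdges(c("a", "b", "c")), extra = c("x", "z"))
  for (m in centralityMetrics()) {
    tb <- centralityTable(net, m, metricParams(epcIterations = 50))
    expect_setequal(names(metricScores(tb)), c("a", "b", "c"))
  }
  # two disconnected dumbbells: harmonic closeness scores both halves
  two <- mkNet(rbind(cbind("a", "b"), cbind("c", "d")))
  expect_equal(unname(metricScores(closenessCentrality(two))), rep(1, 4))
})

test_that("classic closeness is available behind the form flag", {
  p3 <- p3Net()
  tb <- closenessCentrality(p3, metricParams(closenessForm = "classic"))
  expect_equal(metricScores(tb)[["b"]], 1 / 2) # distances 1 + 1
  expect_equal(metricScores(tb)[["a"]], 1 / 3) # distances 1 + 2
  expect_identical(tb@params$form, "classic")
})
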