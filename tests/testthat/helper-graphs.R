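# graph fixtures built in code

# network from an edge data.frame (or 2-column matrix of endpoints),
# all nodes score 3, optional isolated nodes added via `extra`
mkNet <- function(edges, confidence = 1, extra = character(0),
                  minConfidence = 0) {
  if (is.matrix(edges)) {
    edges <- data.frame(
      gene_a = edges[, 1], gene_b = edges[, 2],
      confidence = confidence, stringsAsFactors = FALSE
    )
  }
  if (is.null(edges$confidence)) edges$confidence <- confidence
  vocab <- unique(c(edges$gene_a, edges$gene_b, extra))
  # isolated nodes enter the vocabulary through a below-cutoff self-pair
  # partner trick: pair them with themselves is disallowed, so pair with
  # an existing node at confidence below the cutoff
  if (length(extra)) {
    anchor <- edges$gene_a[1]
    edges <- rbind(edges, data.frame(
      gene_a = extra, gene_b = anchor, confidence = -1 # never kept
    ))
    edges$confidence[edges$confidence < 0] <- 0
    minConfidence <- max(minConfidence, 1e-9)
  }
  genes <- data.frame(
    gene = sort(vocab), disease_score = 3,
    stringsAsFactors = FALSE
  )
  buildNetwork(genes, nrow(genes), edges, minConfidence)
}

completeEdges <- function(ids) {
  p <- t(utils::combn(ids, 2))
  data.frame(gene_a = p[, 1], gene_b = p[, 2], confidence = 1)
}

k3Net <- function() mkNet(completeEdges(c("a", "b", "c")))
k4Net <- function() mkNet(completeEdges(c("a", "b", "c", "d")))
p3Net <- function() mkNet(cbind(c("a", "b"), c("b", "c")))
starNet <- function() mkNet(cbind(c("a", "a", "a"), c("b", "c", "d")))

# seeded family of random connected graphs with <= maxN nodes;
# returns a list of adjacency matrices (dimnames = letters)
randomConnectedAdj <- function(count, maxN = 8L, seed = 20260923) {
  out <- vector("list", count)
  set.seed(seed)
  i <- 0L
  while (i < count) {
    n <- sample(3:maxN, 1L)
    p <- runif(1, 0.25, 0.8)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    # connectivity via reachability of node 1
    reach <- (diag(n) + A)
    for (s in seq_len(n)) reach <- reach %*% (diag(n) + A)
    if (any(reach[1, ] == 0)) next
    i <- i + 1L
    dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
    out[[i]] <- A
  }
  out
}

netFromAdjMatrix <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  mkNet(cbind(rownames(A)[idx[, 1]], rownames(A)[idx[, 2]]))
}
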