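# Exhaustive brute-force oracles, independent of the package internals.
# All oracles work on a symmetric 0/1 adjacency matrix A with dimnames.

oDist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# all shortest s-t paths as a list of index vectors (DFS guided by the
# distance matrix: only steps that decrease the distance to t survive)
oShortestPaths <- function(A, D, s, t) {
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (w in which(A[v, ] > 0)) {
      if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) {
        walk(w, c(acc, w))
      }
    }
  }
  if (is.finite(D[s, t])) walk(s, s)
  paths
}

# betweenness (raw, unordered pairs) and stress by full path enumeration
oPathLoad <- function(A) {
  n <- nrow(A)
  D <- oDist(A)
  bet <- numeric(n)
  str <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(D[s, t])) next
      paths <- oShortestPaths(A, D, s, t)
      sigma <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        str[interior] <- str[interior] + 1
        bet[interior] <- bet[interior] + 1 / sigma
      }
    }
  }
  list(betweenness = bet, stress = str)
}

oCloseness <- function(A) {
  D <- oDist(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  }, numeric(1))
}

oEccentricity <- function(A) {
  D <- oDist(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, ]
    1 / max(d[is.finite(d)])
  }, numeric(1))
}

oRadiality <- function(A) {
  D <- oDist(A)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    comp <- which(is.finite(D[v, ]))
    delta <- max(D[comp, comp][is.finite(D[comp, comp])])
    others <- setdiff(comp, v)
    sum(delta + 1 - D[v, others]) / (length(comp) - 1)
  }, numeric(1))
}

oClustering <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) {
      return(0)
    }
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# connected components of an induced vertex subset, via matrix-power
# reachability (independent of any BFS code)
oComponentsOf <- function(A, vs) {
  if (!length(vs)) {
    return(list())
  }
  S <- A[vs, vs, drop = FALSE]
  n <- length(vs)
  R <- diag(n) + S
  for (i in seq_len(n)) R <- R %*% (diag(n) + S)
  groups <- unique(apply(R > 0, 1, paste, collapse = ""))
  lapply(groups, function(g) vs[apply(R > 0, 1, paste, collapse = "") == g])
}

oMNC <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    comps <- oComponentsOf(A, which(A[v, ] > 0))
    max(lengths(comps))
  }, numeric(1))
}

oDMNC <- function(A, eps = 1.7) {
  vapply(seq_len(nrow(A)), function(v) {
    comps <- oComponentsOf(A, which(A[v, ] > 0))
    H <- comps[[which.max(lengths(comps))]]
    eH <- sum(A[H, H]) / 2
    if (eH == 0) 0 else eH / length(H)^eps
  }, numeric(1))
}

# maximal cliques by testing every vertex subset (n <= ~12)
oMaximalCliques <- function(A) {
  n <- nrow(A)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  isClique <- vapply(subsets, function(s) {
    length(s) == 1 || all(A[s, s][upper.tri(A[s, s])] == 1)
  }, logical(1))
  cliques <- subsets[isClique]
  keys <- vapply(cliques, paste, character(1), collapse = ",")
  maximal <- vapply(cliques, function(s) {
    !any(vapply(seq_len(n), function(v) {
      !(v %in% s) && all(A[v, s] == 1)
    }, logical(1)))
  }, logical(1))
  cliques[maximal & lengths(cliques) >= 2]
}

oMCC <- function(A) {
  scores <- numeric(nrow(A))
  for (cl in oMaximalCliques(A)) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

# BottleNeck: independent layered BFS tree (lexicographic scan, first
# discovery fixes the parent), bottleneck decided by walking every
# node's parent chain
oBottleneck <- function(A) {
  n <- nrow(A)
  scores <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    frontier <- s
    treeNodes <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) { # frontier kept in discovery order
        for (w in which(A[v, ] > 0)) { # lexicographic scan
          if (!seen[w]) {
            seen[w] <- TRUE
            parent[w] <- v
            nxt <- c(nxt, w)
          }
        }
      }
      treeNodes <- c(treeNodes, nxt)
      frontier <- nxt
    }
    treeSize <- length(treeNodes)
    meet <- numeric(n)
    for (w in setdiff(treeNodes, s)) {
      v <- w
      while (!is.na(v)) { # w's path to the root passes v (w included)
        meet[v] <- meet[v] + 1
        v <- parent[v]
      }
    }
    hits <- setdiff(treeNodes, s)[meet[setdiff(treeNodes, s)] > treeSize / 4]
    scores[hits] <- scores[hits] + 1
  }
  scores
}

# highest k-core of a vertex subset by union of all qualifying subsets
oHighestKCore <- function(A, vs) {
  best <- list(k = 0L, members = vs)
  n <- length(vs)
  for (k in seq_len(n - 1)) {
    members <- integer(0)
    for (mask in seq_len(2^n - 1)) {
      s <- vs[which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)]
      if (length(s) < k + 1) next
      degs <- rowSums(A[s, s, drop = FALSE])
      if (all(degs >= k)) members <- union(members, s)
    }
    if (length(members)) best <- list(k = k, members = sort(members)) else break
  }
  best
}

oNodeScore <- function(A, v) {
  closed <- sort(c(v, which(A[v, ] > 0)))
  core <- oHighestKCore(A, closed)
  H <- core$members
  if (length(H) < 2) {
    return(0)
  }
  eH <- sum(A[H, H]) / 2
  core$k * eH / (length(H) * (length(H) - 1) / 2)
}

# exact EPC expectation and variance of per-node component size under
# independent edge retention with probability 1 - threshold
oEPCExact <- function(A, threshold) {
  n <- nrow(A)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(idx)
  pKeep <- 1 - threshold
  e1 <- numeric(n)
  e2 <- numeric(n)
  for (mask in 0:(2^m - 1)) {
    kept <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    B <- matrix(0, n, n)
    if (length(kept)) {
      B[idx[kept, , drop = FALSE]] <- 1
      B <- B + t(B)
    }
    pr <- pKeep^length(kept) * (1 - pKeep)^(m - length(kept))
    comps <- oComponentsOf(B, seq_len(n))
    for (comp in comps) {
      sz <- length(comp)
      e1[comp] <- e1[comp] + pr * sz
      e2[comp] <- e2[comp] + pr * sz^2
    }
  }
  list(mean = e1, var = e2 - e1^2)
}

# log-rank chi-square by the standard O-E / hypergeometric-variance
# formula, written independently of survival::survdiff
oLogrankChisq <- function(time, event, group1) {
  O <- 0
  E <- 0
  V <- 0
  for (tj in sort(unique(time[event == 1]))) {
    atRisk <- time >= tj
    nj <- sum(atRisk)
    n1j <- sum(atRisk & group1)
    dj <- sum(time == tj & event == 1)
    d1j <- sum(time == tj & event == 1 & group1)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  (O - E)^2 / V
}

# two-sided exact Wilcoxon rank-sum p by enumerating all group splits
oWilcoxExact <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  k <- length(x)
  W <- function(ix) {
    r <- rank(vals)
    sum(r[ix]) - k * (k + 1) / 2
  }
  obs <- W(seq_len(k))
  all <- utils::combn(n, k)
  Ws <- apply(all, 2, W)
  pLe <- mean(Ws <= obs)
  pGe <- mean(Ws >= obs)
  min(1, 2 * min(pLe, pGe))
}
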