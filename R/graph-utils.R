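## Internal graph primitives shared by the centrality and MCODE code.
## Graphs are adjacency lists of integer indices (1..n) for speed; the
## named-character adjacency of a PPINetwork is converted once per call.

## integer adjacency from a PPINetwork, nodes in a fixed order
intAdjacency <- function(net, nodeOrder = sort(net@nodes)) {
    idx <- seq_along(nodeOrder)
    names(idx) <- nodeOrder
    lapply(nodeOrder, function(v) unname(idx[net@adjacency[[v]]]))
}

## BFS hop distances from one source; NA_integer_ where unreachable.
## Also returns the number of distinct shortest paths (sigma) and, when
## parents = TRUE, the BFS tree parent under first-discovery with
## neighbours scanned in the order they appear in adj (callers wanting
## the lexicographic rule must order adj lists accordingly).
bfsFrom <- function(adj, s, parents = FALSE) {
    n <- length(adj)
    dist <- rep(NA_integer_, n)
    sigma <- numeric(n)
    parent <- rep(NA_integer_, n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
        v <- queue[head]
        head <- head + 1L
        dv <- dist[v]
        for (w in adj[[v]]) {
            if (is.na(dist[w])) {
                dist[w] <- dv + 1L
                sigma[w] <- sigma[v]
                parent[w] <- v
                tail <- tail + 1L
                queue[tail] <- w
            } else if (dist[w] == dv + 1L) {
                sigma[w] <- sigma[w] + sigma[v]
            }
        }
    }
    out <- list(dist = dist, sigma = sigma, order = queue[seq_len(tail)])
    if (parents) out$parent <- parent
    out
}

## all-pairs hop distances D and shortest-path counts S (n x n); D is
## NA where unreachable, S is 0 there
spMatrices <- function(adj) {
    n <- length(adj)
    D <- matrix(NA_integer_, n, n)
    S <- matrix(0, n, n)
    for (s in seq_len(n)) {
        b <- bfsFrom(adj, s)
        D[s, ] <- b$dist
        S[s, ] <- b$sigma
    }
    list(D = D, S = S)
}

## connected-component membership (integer labels 1..k)
componentMembership <- function(adj) {
    n <- length(adj)
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (s in seq_len(n)) {
        if (!is.na(comp[s])) next
        k <- k + 1L
        stack <- s
        comp[s] <- k
        while (length(stack)) {
            v <- stack[[length(stack)]]
            stack <- stack[-length(stack)]
            for (w in adj[[v]]) {
                if (is.na(comp[w])) {
                    comp[w] <- k
                    stack <- c(stack, w)
                }
            }
        }
    }
    comp
}

## component sizes per node given an edge list (two integer vectors)
## over n nodes; union-find with path halving. Used by EPC where the
## edge set changes every replicate.
componentSizesFromEdges <- function(n, from, to) {
    parent <- seq_len(n)
    findRoot <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    for (i in seq_along(from)) {
        ra <- findRoot(from[i])
        rb <- findRoot(to[i])
        if (ra != rb) parent[rb] <- ra
    }
    root <- vapply(seq_len(n), findRoot, integer(1))
    sz <- tabulate(match(root, unique(root)))
    sz[match(root, unique(root))]
}

## induced subgraph: keep vertices in `keep` (integer vector), return
## adjacency re-indexed to 1..length(keep)
inducedAdjacency <- function(adj, keep) {
    map <- integer(length(adj))
    map[keep] <- seq_along(keep)
    lapply(keep, function(v) {
        nb <- adj[[v]]
        nb <- nb[nb %in% keep]
        map[nb]
    })
}

## Bron-Kerbosch maximal clique enumeration with pivoting.
## adj: integer adjacency list; returns list of integer vectors.
maximalCliques <- function(adj) {
    n <- length(adj)
    nbr <- lapply(adj, function(x) {
        v <- logical(n)
        v[x] <- TRUE
        v
    })
    out <- vector("list", 0L)
    recurse <- function(R, P, X) {
        if (!length(P) && !length(X)) {
            out[[length(out) + 1L]] <<- R
            return(invisible(NULL))
        }
        ## pivot: vertex of P union X maximising |P intersect N(u)|
        PX <- c(P, X)
        best <- -1L
        pivot <- PX[1L]
        for (u in PX) {
            cnt <- sum(nbr[[u]][P])
            if (cnt > best) {
                best <- cnt
                pivot <- u
            }
        }
        for (v in P[!nbr[[pivot]][P]]) {
            nv <- nbr[[v]]
            recurse(c(R, v), P[nv[P]], X[nv[X]])
            P <- P[P != v]
            X <- c(X, v)
        }
        invisible(NULL)
    }
    if (n > 0L) recurse(integer(0), seq_len(n), integer(0))
    out
}

## k-core of an integer-adjacency graph: delete vertices of degree < k
## until none remain; returns the surviving integer vertex set
kCoreMembers <- function(adj, k) {
    members <- seq_along(adj)
    repeat {
        sub <- inducedAdjacency(adj, members)
        bad <- lengths(sub) < k
        if (!any(bad) || !length(members)) break
        members <- members[!bad]
    }
    members
}

## highest-k core: largest k with a non-empty k-core; returns
## list(k, members); the empty graph gives (0, integer(0))
highestKCore <- function(adj) {
    n <- length(adj)
    if (n == 0L) {
        return(list(k = 0L, members = integer(0)))
    }
    best <- list(k = 0L, members = seq_len(n))
    k <- 1L
    repeat {
        members <- kCoreMembers(adj, k)
        if (!length(members)) break
        best <- list(k = k, members = members)
        k <- k + 1L
    }
    best
}

## competition ("1224") ranking: rank(v) = 1 + #{u : score(u) > score(v)}
competitionRank <- function(scores) {
    r <- vapply(scores, function(s) 1L + sum(scores > s), integer(1))
    names(r) <- names(scores)
    r
}
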