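# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: the Delaunay oracle tests circumcircles
# directly instead of calling deldir; the permutation oracle enumerates all
# label arrangements in plain R instead of the compiled kernel; the
# centrality oracle runs Floyd-Warshall instead of igraph.

# ---- Delaunay oracle ------------------------------------------------------
# Edge (i, j) belongs to the Delaunay triangulation (points in general
# position) iff some circumcircle through i, j and a third point k contains
# no other point.
oracleDelaunayEdges <- function(coords) {
    n <- nrow(coords)
    edges <- matrix(integer(), ncol = 2)
    if (n < 2) return(edges)
    inCircumcircle <- function(a, b, c, p) {
        # positive determinant <=> p strictly inside circle through a, b, c
        # (a, b, c counter-clockwise)
        m <- rbind(c(a - p, sum(a^2) - sum(p^2)),
                   c(b - p, sum(b^2) - sum(p^2)),
                   c(c - p, sum(c^2) - sum(p^2)))
        orient <- (b[1] - a[1]) * (c[2] - a[2]) -
                  (b[2] - a[2]) * (c[1] - a[1])
        det(m) * sign(orient) > 0
    }
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            found <- FALSE
            for (k in seq_len(n)) {
                if (k == i || k == j) next
                empty <- TRUE
                for (p in seq_len(n)) {
                    if (p %in% c(i, j, k)) next
                    if (inCircumcircle(coords[i, ], coords[j, ],
                                       coords[k, ], coords[p, ])) {
                        empty <- FALSE
                        break
                    }
                }
                if (empty) { found <- TRUE; break }
            }
            if (n == 2) found <- TRUE
            if (found) edges <- rbind(edges, c(i, j))
        }
    }
    edges
}

edgeKey <- function(e) {
    if (!nrow(e)) return(character())
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
}

# ---- exhaustive permutation oracle ---------------------------------------
# Directed pair statistic computed by plain loops for one labeling.
oraclePairStats <- function(edges, labels, types, variant) {
    K <- length(types)
    stats <- matrix(NA_real_, K, K, dimnames = list(types, types))
    for (a in types) {
        for (b in types) {
            links <- 0L
            hasB <- rep(FALSE, length(labels))
            if (nrow(edges)) for (r in seq_len(nrow(edges))) {
                i <- edges[r, 1]; j <- edges[r, 2]
                if (labels[i] == a && labels[j] == b) links <- links + 1L
                if (labels[j] == a && labels[i] == b) links <- links + 1L
                if (labels[j] == b) hasB[i] <- TRUE
                if (labels[i] == b) hasB[j] <- TRUE
            }
            den <- if (variant == "classic") sum(labels == a)
                   else sum(labels == a & hasB)
            stats[a, b] <- if (den > 0) links / den else NA_real_
        }
    }
    stats
}

# All permutations of 1..n (Heap's algorithm); n <= 7 in the tests.
allPermutations <- function(n) {
    out <- vector("list", factorial(n))
    cnt <- 0L
    a <- seq_len(n)
    rec <- function(k) {
        if (k == 1L) {
            cnt <<- cnt + 1L
            out[[cnt]] <<- a
            return()
        }
        for (i in seq_len(k)) {
            rec(k - 1L)
            if (k %% 2L == 0L) {
                tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
            } else {
                tmp <- a[1L]; a[1L] <<- a[k]; a[k] <<- tmp
            }
        }
    }
    rec(n)
    out
}

# Exact one-sided p-values over the full permutation distribution.
oracleExactP <- function(edges, labels, types, variant) {
    obs <- oraclePairStats(edges, labels, types, variant)
    perms <- allPermutations(length(labels))
    nulls <- lapply(perms, function(p)
        oraclePairStats(edges, labels[p], types, variant))
    K <- length(types)
    p_int <- p_avd <- matrix(NA_real_, K, K, dimnames = list(types, types))
    for (a in types) for (b in types) {
        o <- obs[a, b]
        if (is.na(o)) next
        null_ab <- vapply(nulls, function(m) {
            v <- m[a, b]
            if (is.na(v)) 0 else v  # undefined permutations count as zero
        }, 0)
        p_int[a, b] <- mean(null_ab >= o)
        p_avd[a, b] <- mean(null_ab <= o)
    }
    list(p_interact = p_int, p_avoid = p_avd, observed = obs)
}

# ---- centrality oracle ----------------------------------------------------
# Degree, Wasserman-Faust closeness and normalized betweenness from a dense
# adjacency matrix. Unweighted graphs: distances and shortest-path counts
# come from one breadth-first search per source.
oracleCentralities <- function(adj) {
    n <- nrow(adj)
    deg <- rowSums(adj)
    d <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)  # number of shortest paths
    for (s in seq_len(n)) {
        d[s, s] <- 0
        sigma[s, s] <- 1
        frontier <- s
        lev <- 0
        while (length(frontier)) {
            lev <- lev + 1
            nxt <- integer()
            for (v in frontier) {
                for (w in which(adj[v, ] == 1)) {
                    if (!is.finite(d[s, w])) {
                        d[s, w] <- lev
                        nxt <- c(nxt, w)
                    }
                    if (d[s, w] == lev)
                        sigma[s, w] <- sigma[s, w] + sigma[s, v]
                }
            }
            frontier <- unique(nxt)
        }
    }
    clo <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        r <- length(reach)
        if (r == 0 || n == 1) return(0)
        (r / (n - 1)) * (r / sum(reach))
    }, 0)
    btw <- rep(0, n)
    for (v in seq_len(n)) {
        tot <- 0
        for (s in seq_len(n)) {
            for (t in seq_len(n)) {
                if (s >= t || s == v || t == v) next
                if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
                if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
                    d[s, v] + d[v, t] == d[s, t])
                    tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
            }
        }
        btw[v] <- if (n > 2) tot / ((n - 1) * (n - 2) / 2) else 0
    }
    list(degree = deg, closeness = clo, betweenness = btw)
}

# ---- small fixture builders ----------------------------------------------
# A graph with explicit edges (bypassing triangulation) for unit fixtures.
makeGraph <- function(coords, edges, ids = NULL, max_dist = 50) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
    edges <- matrix(as.integer(edges), ncol = 2)
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                         coords[edges[, 2], , drop = FALSE])^2))
    new("SpatialGraph", roi = "fixture", cellIds = ids, coords = coords,
        edges = edges, lengths = len, maxDist = max_dist)
}

# A zig-zag two-type path: consecutive cells 30.6 um apart (kept), skip
# neighbors ~60 um (pruned), so the pruned Delaunay graph is the pure path
# and type labels strictly alternate along it.
alternatingPathTable <- function(n = 40) {
    x <- (seq_len(n) - 1) * 30
    y <- rep(c(0, 6), length.out = n)
    coords <- cbind(x, y)
    labels <- rep(c("A", "B"), length.out = n)
    list(coords = coords, labels = setNames(labels, as.character(seq_len(n))))
}

# Minimal two-surgery cell table without markers, built directly.
tinyCellTable <- function(cd) {
    m <- matrix(0, nrow = 1, ncol = nrow(cd), dimnames = list("none", NULL))
    CellTable(m, cd)
}
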