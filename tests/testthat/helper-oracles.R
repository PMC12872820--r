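# Independent brute-force oracles. These deliberately share no code with the
# package internals: distances by explicit loops, shortest paths by per-source
# BFS, clusters by union-find, cycles by DFS enumeration, test statistics by
# full enumeration.

random_session <- function(T_points, D = 2, id = "rnd", dt = 0.5,
                           scale = 100) {
  vals <- matrix(stats::rnorm(T_points * D, 0, scale), ncol = D)
  time_series_session(vals, dt = dt, session_id = id)
}

# Full pairwise distance matrix by explicit loops (independent arithmetic
# path from stats::dist, same summation order over dimensions).
oracle_dist <- function(values) {
  n <- nrow(values)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- sqrt(sum((values[i, ] - values[j, ])^2))
    }
  }
  m
}

# STKNN construction from sorted full distance matrices.
oracle_stknn_edges <- function(values, k, rule = "mutual") {
  n <- nrow(values)
  dm <- oracle_dist(values)
  claims <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- dm[i, ]
    d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(k)]
    claims[i, nn] <- TRUE
  }
  linked <- if (rule == "union") claims | t(claims) else claims & t(claims)
  spat <- which(linked, arr.ind = TRUE)
  spat <- spat[order(spat[, 1L], spat[, 2L]), , drop = FALSE]
  temp <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  list(temporal = temp, spatial = unname(spat))
}

# Unit-weight directed shortest paths by per-source breadth-first search.
oracle_bfs_distances <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
  }
  out <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    frontier <- src
    level <- 0
    while (length(frontier)) {
      level <- level + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(dist[nxt])]
      dist[nxt] <- level
      frontier <- nxt
    }
    out[src, ] <- dist
  }
  out
}

# Contraction oracle: BFS distance matrix + union-find over the mutual
# within-d relation + edge projection.
oracle_contract <- function(g, d) {
  n <- g$n_points
  edges <- unique(rbind(g$temporal_edges, g$spatial_edges))
  dm <- oracle_bfs_distances(edges, n)
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    root
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (dm[i, j] <= d && dm[j, i] <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_ids <- sort(unique(roots))
  memb <- match(roots, comp_ids)           # already ordered by min member
  nodes <- unname(split(seq_len(n), memb))
  ecount <- list()
  for (r in seq_len(nrow(edges))) {
    a <- memb[edges[r, 1L]]; b <- memb[edges[r, 2L]]
    if (a != b) {
      key <- paste(a, b)
      ecount[[key]] <- (ecount[[key]] %||% 0L) + 1L
    }
  }
  if (length(ecount)) {
    parts <- do.call(rbind, strsplit(names(ecount), " "))
    edf <- data.frame(from = as.integer(parts[, 1L]),
                      to = as.integer(parts[, 2L]),
                      count = as.integer(unlist(ecount)))
    edf <- edf[order(edf$from, edf$to), , drop = FALSE]
    rownames(edf) <- NULL
  } else {
    edf <- data.frame(from = integer(), to = integer(), count = integer())
  }
  list(nodes = lapply(nodes, as.integer), edges = edf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All simple directed cycles by DFS (feasible for <= 12 nodes); returns the
# shortest cycle length through each node, NA when none.
oracle_loop_lengths <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
  }
  best <- rep(NA_real_, n)
  dfs <- function(start, v, path) {
    for (w in adj[[v]]) {
      if (w == start) {
        len <- length(path)
        if (len >= 2) {
          for (u in path) {
            if (is.na(best[u]) || len < best[u]) best[u] <<- len
          }
        }
      } else if (!(w %in% path) && w > start) {
        # enumerate each cycle once from its smallest node
        dfs(start, w, c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s, s)
  best
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(x) {
  d <- x[x != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# Build a transition_network by hand from an explicit topology, for testing
# metric operations in isolation.
manual_network <- function(nodes, edges, dt = 0.5, id = "manual") {
  Tn <- length(unlist(nodes))
  structure(
    list(nodes = lapply(nodes, as.integer),
         edges = data.frame(from = as.integer(edges$from),
                            to = as.integer(edges$to),
                            count = as.integer(edges$count %||% rep(1L, length(edges$from)))),
         d = 3L,
         provenance = list(k = 7L, metric = "euclidean", knn_rule = "mutual",
                           T = Tn, dt = dt, session_id = id)),
    class = "transition_network"
  )
}

expect_same_network <- function(a, b) {
  expect_equal(lapply(a$nodes, as.integer), lapply(b$nodes, as.integer))
  expect_equal(a$edges, b$edges)
}
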