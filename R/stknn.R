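# Spatiotemporal k-nearest-neighbor (STKNN) graph over the time points of a
# session: a directed temporal chain t -> t+1 (the arrow of time) plus
# bidirectional spatial edges between state-space neighbors. The mutual rule
# (default) links a pair only when each point is among the other's k nearest
# neighbors; the union rule links on either claim. Mutual linking keeps fast
# escape corridors from spatially bridging attractor clouds, which is what
# lets contraction separate dwell states from transition paths.

# Pairwise Euclidean distances with the self-distance masked out.
pairwise_distances <- function(values) {
  dmat <- as.matrix(stats::dist(values, method = "euclidean"))
  dimnames(dmat) <- NULL
  dmat
}

#' Spatial k nearest neighbors of one time point
#'
#' Exact nearest-neighbor query used by [build_stknn()] and exposed for
#' verification. Neighbors are ordered by (distance, time index): ties at
#' equal distance resolve to the smaller time index, so results are fully
#' deterministic.
#'
#' @param session a `ts_session`.
#' @param i time index (1-based), `1 <= i <= T`.
#' @param k neighborhood size, `k < T`.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @return integer vector of the k nearest other time indices.
#' @export
knn_of <- function(session, i, k, metric = "euclidean") {
  match.arg(metric, "euclidean")
  n <- n_points(session)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > n) stop_config("index i out of range 1..", n)
  if (k >= n) stop_config("k (", k, ") must be smaller than T (", n, ")")
  di <- sqrt(colSums((t(session$values) - session$values[i, ])^2))
  di[i] <- Inf
  order(di, seq_len(n))[seq_len(k)]
}

#' Build the spatiotemporal k-nearest-neighbor graph
#'
#' Constructs the directed graph over time points that underlies transition
#' network construction: temporal edges `(t, t+1)` for every consecutive pair
#' (directed forward in time) and spatial edges linking state-space neighbors
#' bidirectionally. Under the default mutual rule a pair `{i, j}` is linked
#' when j is among the k nearest neighbors of i *and* i is among the k
#' nearest of j; under the union rule either claim suffices (more
#' connective; provided for sensitivity analysis). Distance ties are broken
#' by smaller time index, so construction is deterministic.
#'
#' @param session a `ts_session` with `T >= 2`.
#' @param k neighborhood size (default 7), must satisfy `k < T`.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param knn_rule `"mutual"` (default) or `"union"`.
#' @return an object of class `stknn_graph` with fields `n_points`,
#'   `temporal_edges` and `spatial_edges` (2-column integer matrices of
#'   1-based time indices; spatial edges contain both directions of every
#'   linked pair), `k`, `metric`, `knn_rule`, and session provenance
#'   (`dt`, `session_id`).
#' @export
build_stknn <- function(session, k = 7, metric = "euclidean",
                        knn_rule = c("mutual", "union")) {
  knn_rule <- match.arg(knn_rule)
  match.arg(metric, "euclidean")
  n <- n_points(session)
  if (n < 2L) stop_data("need at least 2 time points")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_config("'k' must be a positive integer")
  if (k >= n) stop_config("k (", k, ") must be smaller than T (", n, ")")

  dmat <- pairwise_distances(session$values)
  diag(dmat) <- Inf
  idx <- seq_len(n)
  nn <- matrix(0L, nrow = n, ncol = k)
  for (i in idx) {
    nn[i, ] <- order(dmat[i, ], idx)[seq_len(k)]
  }

  # Directed "claims" i -> j (j in i's top-k), encoded as scalar keys.
  claim_from <- rep(idx, each = k)
  claim_to <- as.integer(t(nn))
  keys <- (claim_from - 1) * n + claim_to
  swapped <- (claim_to - 1) * n + claim_from
  if (knn_rule == "union") {
    lo <- pmin(claim_from, claim_to)
    hi <- pmax(claim_from, claim_to)
    pair_keys <- unique((lo - 1) * n + hi)
  } else {
    both <- keys[keys %in% swapped]
    a <- ((both - 1) %/% n) + 1
    b <- ((both - 1) %% n) + 1
    pair_keys <- unique((pmin(a, b) - 1) * n + pmax(a, b))
  }
  lo <- as.integer(((pair_keys - 1) %/% n) + 1)
  hi <- as.integer(((pair_keys - 1) %% n) + 1)
  spatial <- rbind(cbind(lo, hi), cbind(hi, lo))
  spatial <- spatial[order(spatial[, 1L], spatial[, 2L]), , drop = FALSE]
  dimnames(spatial) <- NULL

  structure(
    list(n_points = n,
         temporal_edges = cbind(idx[-n], idx[-1L]),
         spatial_edges = spatial,
         k = k, metric = metric, knn_rule = knn_rule,
         dt = session$dt, session_id = session$session_id),
    class = "stknn_graph"
  )
}

#' @export
print.stknn_graph <- function(x, ...) {
  cat(sprintf("<stknn_graph '%s': T=%d, k=%d (%s), %d temporal + %d spatial directed edges>\n",
              x$session_id, x$n_points, x$k, x$knn_rule,
              nrow(x$temporal_edges), nrow(x$spatial_edges)))
  invisible(x)
}

# Directed edge set of the graph (temporal union spatial, deduplicated).
stknn_edges <- function(g) {
  e <- rbind(g$temporal_edges, g$spatial_edges)
  unique(e)
}

# igraph view of the STKNN graph (unit edge weights, directed).
stknn_igraph <- function(g) {
  e <- stknn_edges(g)
  ig <- igraph::make_empty_graph(n = g$n_points, directed = TRUE)
  igraph::add_edges(ig, as.vector(t(e)))
}
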