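# Contraction of the STKNN graph at shortest-path distance d into the
# attractor transition network. Two time points merge when each can reach the
# other within d steps of the directed STKNN graph (mutual reachability);
# clusters are the connected components of that symmetric relation. Mutual
# reachability is what preserves the dwell/escape distinction: points along a
# fast one-way escape path cannot merge into the attractor they leave.

#' All-pairs shortest-path distances on an STKNN graph
#'
#' Unit-weight directed shortest paths; `Inf` marks unreachable pairs. The
#' temporal chain guarantees `dist(t, u) <= u - t` for `t < u`.
#'
#' @param g an `stknn_graph`.
#' @return a T x T numeric matrix with zero diagonal.
#' @export
all_pairs_distance <- function(g) {
  ig <- stknn_igraph(g)
  m <- igraph::distances(ig, mode = "out", algorithm = "unweighted")
  dimnames(m) <- NULL
  m
}

# Ordered pairs (i, j) with dist(i -> j) <= d, as scalar keys (i-1)*T + j,
# self pairs excluded. Uses bounded neighborhood search rather than the full
# distance matrix so study-scale sessions stay cheap.
reachable_keys <- function(g, d) {
  ig <- stknn_igraph(g)
  n <- g$n_points
  balls <- igraph::ego(ig, order = d, nodes = seq_len(n), mode = "out")
  sizes <- lengths(balls)
  from <- rep.int(seq_len(n), sizes)
  to <- as.integer(unlist(balls, use.names = FALSE))
  keep <- from != to
  (from[keep] - 1) * n + to[keep]
}

#' Contract an STKNN graph into an attractor transition network
#'
#' Merges time points i and j when `dist(i -> j) <= d` and `dist(j -> i) <= d`
#' in the STKNN graph (shortest-path length; the minimal number of time steps
#' to transition between the two states). Clusters are the connected
#' components of this mutual-proximity relation; every STKNN edge crossing
#' between two clusters is projected to a directed network edge whose
#' `count` accumulates the crossings. Node ids are assigned in order of each
#' cluster's smallest member time index, so output is deterministic.
#'
#' @param g an `stknn_graph`.
#' @param d contraction distance, a positive integer (default 3).
#' @return an object of class `transition_network` with fields:
#'   `nodes` (list of sorted 1-based member time-index vectors, partitioning
#'   `1..T`), `edges` (data.frame `from`, `to`, `count`), `d`, and
#'   `provenance` (k, metric, knn_rule, T, dt, session_id).
#' @export
contract <- function(g, d = 3) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop_config("'d' must be a positive integer >= 1")
  n <- g$n_points

  keys <- reachable_keys(g, d)
  from <- as.integer((keys - 1) %/% n) + 1L
  to <- as.integer((keys - 1) %% n) + 1L
  fwd <- from < to
  mutual <- keys[fwd][((to[fwd] - 1) * n + from[fwd]) %in% keys]
  mi <- as.integer((mutual - 1) %/% n) + 1L
  mj <- as.integer((mutual - 1) %% n) + 1L

  und <- igraph::make_empty_graph(n = n, directed = FALSE)
  und <- igraph::add_edges(und, as.vector(rbind(mi, mj)))
  memb <- igraph::components(und)$membership

  # Relabel clusters by smallest member time index.
  ord <- order(tapply(seq_len(n), memb, min))
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  memb <- relabel[memb]
  nodes <- split(seq_len(n), memb)
  nodes <- lapply(nodes, function(v) as.integer(sort(v)))
  names(nodes) <- NULL

  e <- stknn_edges(g)
  ca <- memb[e[, 1L]]
  cb <- memb[e[, 2L]]
  cross <- ca != cb
  if (any(cross)) {
    key <- (ca[cross] - 1) * length(nodes) + cb[cross]
    tab <- table(key)
    kk <- as.numeric(names(tab))
    edges <- data.frame(
      from = as.integer((kk - 1) %/% length(nodes)) + 1L,
      to = as.integer((kk - 1) %% length(nodes)) + 1L,
      count = as.integer(tab)
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(), count = integer())
  }

  structure(
    list(nodes = nodes, edges = edges, d = d,
         provenance = list(k = g$k, metric = g$metric, knn_rule = g$knn_rule,
                           T = n, dt = g$dt, session_id = g$session_id)),
    class = "transition_network"
  )
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("<transition_network '%s': %d nodes, %d edges (T=%d, k=%d, d=%d)>\n",
              x$provenance$session_id, length(x$nodes), nrow(x$edges),
              x$provenance$T, x$provenance$k, x$d))
  invisible(x)
}

#' Number of nodes of a transition network
#' @param net a `transition_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Node membership of every time point
#' @param net a `transition_network`.
#' @return integer vector of length T mapping each time point to its node id.
#' @export
node_membership <- function(net) {
  memb <- integer(net$provenance$T)
  for (i in seq_along(net$nodes)) memb[net$nodes[[i]]] <- i
  memb
}

#' Node count as a function of the contraction distance
#'
#' Diagnostic for parameter stability: a larger d merges more time points, so
#' the node count is non-increasing in d. Transition networks are typically
#' chosen on a plateau of this curve, where construction is stable under
#' small parameter changes.
#'
#' @param g an `stknn_graph`.
#' @param d_values positive integers to sweep (default `1:8`).
#' @return data.frame with columns `d` and `n_nodes`.
#' @export
coarse_grain_curve <- function(g, d_values = 1:8) {
  d_values <- as.integer(d_values)
  if (!length(d_values)) stop_config("'d_values' must be nonempty")
  data.frame(
    d = d_values,
    n_nodes = vapply(d_values, function(d) n_nodes(contract(g, d)), integer(1))
  )
}

# igraph view of the contracted network (directed, no self-loops).
network_igraph <- function(net) {
  ig <- igraph::make_empty_graph(n = n_nodes(net), directed = TRUE)
  if (nrow(net$edges)) {
    ig <- igraph::add_edges(ig, as.vector(rbind(net$edges$from, net$edges$to)))
  }
  ig
}
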