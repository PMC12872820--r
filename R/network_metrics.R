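# Dynamical-stability summaries of a transition network. Node size (member
# count = total dwell time) measures how strongly a state attracts nearby
# states -- local stability. The shortest directed loop through a node
# measures how many transitions it takes to leave the state and return --
# global stability (longer loops = harder recurrence, more diverse states).

#' Node sizes (total dwell time per attractor state)
#'
#' @param net a `transition_network`.
#' @return integer vector of member counts, one per node; sums to T.
#' @export
node_sizes <- function(net) {
  vapply(net$nodes, length, integer(1))
}

#' Shortest directed loop length through each node
#'
#' The loop length of node v is the number of edges of the shortest directed
#' cycle through v visiting at least two distinct nodes:
#' `1 + min over out-neighbors w != v of dist(w -> v)` with unit edge weights.
#' Nodes from which no return path exists (isolated nodes, pure sinks) get
#' `NA`. With `definition = "cycle_basis"` the value is instead the mean
#' length of the fundamental cycles (from a spanning forest of the
#' underlying undirected graph) that pass through v, provided for
#' sensitivity analysis.
#'
#' @param net a `transition_network`.
#' @param definition `"shortest_cycle"` (default) or `"cycle_basis"`.
#' @return numeric vector, one value (>= 2) or `NA` per node.
#' @export
loop_lengths <- function(net, definition = c("shortest_cycle", "cycle_basis")) {
  definition <- match.arg(definition)
  nn <- n_nodes(net)
  out <- rep(NA_real_, nn)
  if (!nrow(net$edges)) return(out)
  if (definition == "shortest_cycle") {
    ig <- network_igraph(net)
    dm <- igraph::distances(ig, mode = "out", algorithm = "unweighted")
    for (v in seq_len(nn)) {
      ws <- net$edges$to[net$edges$from == v]
      ws <- ws[ws != v]
      if (!length(ws)) next
      back <- dm[ws, v]
      if (any(is.finite(back))) out[v] <- 1 + min(back)
    }
  } else {
    cyc <- fundamental_cycles(net)
    if (length(cyc)) {
      for (v in seq_len(nn)) {
        lens <- vapply(cyc, function(cc) if (v %in% cc) length(cc) else NA_real_,
                       numeric(1))
        lens <- lens[!is.na(lens)]
        if (length(lens)) out[v] <- mean(lens)
      }
    }
  }
  out
}

#' Loop length of a single node
#' @param net a `transition_network`.
#' @param node_id node id (1-based).
#' @param definition see [loop_lengths()].
#' @return loop length or `NA` when no directed cycle returns to the node.
#' @export
loop_length <- function(net, node_id,
                        definition = c("shortest_cycle", "cycle_basis")) {
  node_id <- as.integer(node_id)
  if (is.na(node_id) || node_id < 1L || node_id > n_nodes(net)) {
    stop_config("node_id out of range 1..", n_nodes(net))
  }
  loop_lengths(net, definition)[node_id]
}

# Fundamental cycles of the underlying undirected simple graph, as vertex
# sets, one per non-tree edge of a spanning forest.
fundamental_cycles <- function(net) {
  e <- unique(cbind(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to)))
  ug <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  ug <- igraph::add_edges(ug, as.vector(t(e)))
  mst <- igraph::mst(ug)
  tree_el <- igraph::as_edgelist(mst)
  tree_keys <- if (nrow(tree_el)) {
    paste(pmin(tree_el[, 1L], tree_el[, 2L]),
          pmax(tree_el[, 1L], tree_el[, 2L]), sep = "-")
  } else character(0)
  cycles <- list()
  for (i in seq_len(nrow(e))) {
    key <- paste(e[i, ], collapse = "-")
    if (key %in% tree_keys) next
    path <- igraph::shortest_paths(mst, from = e[i, 1L], to = e[i, 2L])$vpath[[1L]]
    if (length(path)) cycles[[length(cycles) + 1L]] <- as.integer(path)
  }
  cycles
}

#' Per-node means of a time-point variable
#'
#' Averages a length-T variable (a session channel or an expanded annotation)
#' over each node's member time points -- the quantity used to color network
#' nodes by, e.g., average warmth or average rupture intensity of the
#' associated time points.
#'
#' @param net a `transition_network`.
#' @param values numeric vector of length T.
#' @return numeric vector of node means.
#' @export
node_mean_overlay <- function(net, values) {
  if (length(values) != net$provenance$T) {
    stop_data("variable length ", length(values), " != T = ", net$provenance$T)
  }
  vapply(net$nodes, function(m) mean(values[m]), numeric(1))
}

#' Attach channel and annotation overlays to a network
#'
#' Computes per-node means of every session channel and every supplied
#' annotation track (expanded to time points first) and stores them in
#' `net$node_means`, from where [write_network()] and
#' [node_metrics_table()] pick them up.
#'
#' @param net a `transition_network` built from `session`.
#' @param session the originating `ts_session`.
#' @param annotations list of `annotation_track` objects and/or named numeric
#'   length-T vectors.
#' @return `net` with a `node_means` data.frame (one row per node).
#' @export
attach_overlays <- function(net, session, annotations = list()) {
  if (n_points(session) != net$provenance$T) {
    stop_data("session length does not match the network's T")
  }
  means <- data.frame(row.names = seq_len(n_nodes(net)))
  for (j in seq_along(session$channel_names)) {
    means[[session$channel_names[j]]] <-
      node_mean_overlay(net, session$values[, j])
  }
  if (length(annotations)) {
    nm <- names(annotations) %||% rep("", length(annotations))
    for (a in seq_along(annotations)) {
      ann <- annotations[[a]]
      if (inherits(ann, "annotation_track")) {
        vals <- expand_annotation(ann, session)
        label <- if (nzchar(nm[a])) nm[a] else ann$track_name
      } else {
        vals <- ann
        label <- if (nzchar(nm[a])) nm[a] else paste0("annotation", a)
      }
      means[[label]] <- node_mean_overlay(net, vals)
    }
  }
  net$node_means <- means
  net
}

#' Per-node metrics table
#'
#' One row per node: size, dwell time in seconds, loop length, and any
#' attached overlay means. `node_id` is 0-based in this table, matching the
#' file conventions of [write_network()].
#'
#' @param net a `transition_network` (optionally with overlays attached).
#' @param loop_definition see [loop_lengths()].
#' @return data.frame with columns `session_id`, `node_id`, `size`,
#'   `dwell_seconds`, `loop_length`, then one column per overlay.
#' @export
node_metrics_table <- function(net, loop_definition = "shortest_cycle") {
  sizes <- node_sizes(net)
  out <- data.frame(
    session_id = net$provenance$session_id,
    node_id = seq_along(sizes) - 1L,
    size = sizes,
    dwell_seconds = sizes * net$provenance$dt,
    loop_length = loop_lengths(net, loop_definition)
  )
  if (!is.null(net$node_means)) out <- cbind(out, net$node_means)
  rownames(out) <- NULL
  out
}

#' Session-level feature summary
#'
#' Collapses a network to the per-session quantities used by between-session
#' statistics: the unweighted mean node size, the mean loop length over nodes
#' with a defined loop (`NA` when no node has one; the number of excluded
#' nodes is reported), and the session-wide time-point average of each
#' supplied variable (computed over all T points, independent of the
#' network partition).
#'
#' @param net a `transition_network`.
#' @param variables named list of numeric length-T vectors (channels and/or
#'   expanded annotations).
#' @param loop_definition see [loop_lengths()].
#' @return one-row data.frame: `session_id`, `n_nodes`, `n_edges`,
#'   `mean_node_size`, `mean_loop_length`, `n_loop_undefined`, then
#'   `mean_<variable>` columns.
#' @export
summarize_session <- function(net, variables = list(),
                              loop_definition = "shortest_cycle") {
  sizes <- node_sizes(net)
  ll <- loop_lengths(net, loop_definition)
  defined <- !is.na(ll)
  out <- data.frame(
    session_id = net$provenance$session_id,
    n_nodes = length(sizes),
    n_edges = nrow(net$edges),
    mean_node_size = mean(sizes),
    mean_loop_length = if (any(defined)) mean(ll[defined]) else NA_real_,
    n_loop_undefined = sum(!defined)
  )
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (length(v) != net$provenance$T) {
      stop_data("variable '", nm, "' length != T")
    }
    out[[paste0("mean_", nm)]] <- mean(v)
  }
  out
}
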