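# Serialization of transition networks. All node ids and member time indices
# are written 0-based; the JSON dialect round-trips losslessly through
# read_network().

#' Write a transition network to disk
#'
#' Formats: `"json"` (canonical field order, lossless round-trip through
#' [read_network()]), `"graphml"` (directed, via igraph, member indices as a
#' comma-joined attribute), `"edgelist"` (TSV with columns source, target,
#' count). Node attributes include size, member count, member time indices
#' and any overlay means attached with [attach_overlays()]; edges carry
#' their transition count.
#'
#' @param net a `transition_network`.
#' @param path output file path.
#' @param format one of `"json"`, `"graphml"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "graphml", "edgelist")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write to '", path, "': directory does not exist")
  sizes <- node_sizes(net)
  means <- net$node_means
  if (format == "json") {
    nodes <- lapply(seq_along(net$nodes), function(i) {
      node <- list(id = i - 1L, size = sizes[[i]],
                   n_members = length(net$nodes[[i]]),
                   members = as.integer(net$nodes[[i]] - 1L))
      if (!is.null(means)) node$means <- as.list(means[i, , drop = FALSE])
      node
    })
    edges <- lapply(seq_len(nrow(net$edges)), function(r) {
      list(source = net$edges$from[r] - 1L, target = net$edges$to[r] - 1L,
           count = net$edges$count[r])
    })
    obj <- list(session_id = net$provenance$session_id,
                T = net$provenance$T, dt = net$provenance$dt,
                k = net$provenance$k, d = net$d,
                metric = net$provenance$metric,
                knn_rule = net$provenance$knn_rule,
                nodes = nodes, edges = edges)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "graphml") {
    ig <- network_igraph(net)
    igraph::V(ig)$id0 <- seq_along(net$nodes) - 1L
    igraph::V(ig)$size <- sizes
    igraph::V(ig)$n_members <- lengths(net$nodes)
    igraph::V(ig)$members <- vapply(net$nodes,
                                    function(m) paste(m - 1L, collapse = ","),
                                    character(1))
    if (!is.null(means)) {
      for (nm in names(means)) {
        igraph::vertex_attr(ig, paste0("mean_", nm)) <- means[[nm]]
      }
    }
    if (nrow(net$edges)) igraph::E(ig)$count <- net$edges$count
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    df <- data.frame(source = net$edges$from - 1L,
                     target = net$edges$to - 1L,
                     count = net$edges$count)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a transition network from its JSON serialization
#'
#' Inverse of `write_network(..., format = "json")`: recovers the node
#' partition, edge counts, contraction parameters and provenance exactly.
#'
#' @param path JSON file written by [write_network()].
#' @return a `transition_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    as.integer(unlist(nd$members)) + 1L
  })
  if (length(obj$edges)) {
    edges <- data.frame(
      from = vapply(obj$edges, function(e) as.integer(e$source), integer(1)) + 1L,
      to = vapply(obj$edges, function(e) as.integer(e$target), integer(1)) + 1L,
      count = vapply(obj$edges, function(e) as.integer(e$count), integer(1))
    )
  } else {
    edges <- data.frame(from = integer(), to = integer(), count = integer())
  }
  net <- structure(
    list(nodes = nodes, edges = edges, d = as.integer(obj$d),
         provenance = list(k = as.integer(obj$k), metric = obj$metric,
                           knn_rule = obj$knn_rule, T = as.integer(obj$T),
                           dt = as.double(obj$dt), session_id = obj$session_id)),
    class = "transition_network"
  )
  has_means <- length(obj$nodes) && !is.null(obj$nodes[[1L]]$means)
  if (has_means) {
    nm <- names(obj$nodes[[1L]]$means)
    means <- as.data.frame(lapply(nm, function(v) {
      vapply(obj$nodes, function(nd) as.double(nd$means[[v]]), numeric(1))
    }), col.names = nm)
    net$node_means <- means
  }
  net
}
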