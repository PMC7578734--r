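#' Build the acupoint co-usage network
#'
#' Undirected weighted graph over the dataset's acupoints: an edge joins two
#' acupoints iff they appear together in at least \code{min_weight}
#' prescriptions, with the co-occurrence count as edge weight. Co-usage is a
#' symmetric relation, so the graph is undirected; nodes with no retained
#' edge are dropped unless \code{keep_isolates} is set.
#'
#' @param dataset a \code{transactions} object.
#' @param min_weight minimum co-occurrence count for an edge (>= 1).
#' @param keep_isolates keep nodes with no qualifying edge (default
#'   \code{FALSE}).
#' @return An object of class \code{couse_graph} wrapping an
#'   \code{igraph} graph (element \code{graph}) plus \code{min_weight}.
#' @export
#' @examples
#' g <- build_network(build_csap_fixture())
#' graph_stats(g)
build_network <- function(dataset, min_weight = 1L, keep_isolates = FALSE) {
  stopifnot(inherits(dataset, "transactions"), min_weight >= 1L)
  cm <- cooccurrence_matrix(dataset)
  cnt <- cm$counts
  diag(cnt) <- 0L
  idx <- which(upper.tri(cnt) & cnt >= min_weight, arr.ind = TRUE)
  edges <- data.frame(from = cm$items[idx[, 1L]],
                      to = cm$items[idx[, 2L]],
                      weight = cnt[idx],
                      stringsAsFactors = FALSE)
  nodes <- if (keep_isolates) cm$items else
    intersect(cm$items, unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, min_weight = min_weight),
            class = "couse_graph")
}

as_igraph <- function(x) {
  if (inherits(x, "couse_graph")) x$graph
  else if (igraph::is_igraph(x)) x
  else stop("expected a couse_graph or igraph object")
}

#' Global network statistics
#'
#' Node and edge counts, average degree (2E/V), and unweighted shortest-path
#' statistics (mean path length over connected pairs and diameter) computed
#' by breadth-first search. On disconnected graphs the path statistics are
#' computed on the largest connected component, and the result records that
#' convention and the component size.
#'
#' @param graph a \code{couse_graph} or \code{igraph} graph.
#' @return A list of class \code{graph_stats}: \code{node_count},
#'   \code{edge_count}, \code{average_degree}, \code{average_path_length},
#'   \code{diameter}, \code{connected}, \code{component_size},
#'   \code{path_convention}. Path statistics are \code{NA} on a single-node
#'   or edgeless component.
#' @export
graph_stats <- function(graph) {
  g <- as_igraph(graph)
  V <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (V == 0L) stop("graph has no nodes")
  comps <- igraph::components(g)
  comp_size <- max(comps$csize)
  biggest <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == biggest))
  if (igraph::vcount(sub) > 1L) {
    d <- igraph::distances(sub, weights = NA)   # unweighted BFS distances
    ut <- d[upper.tri(d)]
    apl <- mean(ut)
    diam <- max(ut)
  } else {
    apl <- NA_real_
    diam <- NA_real_
  }
  structure(list(node_count = V, edge_count = E,
                 average_degree = 2 * E / V,
                 average_path_length = apl,
                 diameter = diam,
                 connected = comps$no == 1L,
                 component_size = comp_size,
                 path_convention = "largest connected component, unweighted"),
            class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat("Co-usage network statistics\n")
  cat(sprintf("  nodes: %d | edges: %d | average degree: %.2f\n",
              x$node_count, x$edge_count, x$average_degree))
  cat(sprintf("  average path length: %s | diameter: %s (%s%s)\n",
              ifelse(is.na(x$average_path_length), "NA",
                     sprintf("%.3f", x$average_path_length)),
              ifelse(is.na(x$diameter), "NA",
                     sprintf("%g", x$diameter)),
              x$path_convention,
              if (x$connected) "" else
                sprintf("; largest of several components, size %d",
                        x$component_size)))
  invisible(x)
}

#' k-core extraction and full core decomposition
#'
#' The k-core is the maximal subgraph in which every node has degree >= k
#' within the subgraph, obtained by iterative peeling: repeatedly delete
#' nodes whose current degree is below k until none remain. The full
#' decomposition assigns each node its core number (the largest k whose
#' core contains it) by peeling in order of current degree, ties broken
#' lexicographically by node name, which makes the peeling order -- not the
#' core numbers, which are order-invariant -- deterministic.
#'
#' @param graph a \code{couse_graph} or \code{igraph} graph.
#' @param k core order (>= 0).
#' @return For \code{k_core()}: list of class \code{kcore_result} with
#'   \code{k}, \code{member_nodes} (sorted), and \code{core_number} (named
#'   vector over all nodes). \code{core_decomposition()} returns the same
#'   shape with \code{k = NA} and all members.
#' @export
#' @examples
#' g <- build_network(build_csap_fixture())
#' core_decomposition(g)$core_number[["PC6"]]
k_core <- function(graph, k) {
  stopifnot(k >= 0)
  core <- core_decomposition(graph)$core_number
  structure(list(k = k,
                 member_nodes = sort.int(names(core)[core >= k], method = "radix"),
                 core_number = core),
            class = "kcore_result")
}

#' @rdname k_core
#' @export
core_decomposition <- function(graph) {
  g <- as_igraph(graph)
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(v) v$name)
  names(adj) <- nodes
  deg <- vapply(adj, length, integer(1))
  core <- stats::setNames(integer(length(nodes)), nodes)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  cur <- deg
  k <- 0L
  while (any(alive)) {
    # peel the minimum-degree node; its core number is the running maximum
    cand <- names(cur)[alive]
    cand <- cand[order(cur[cand], cand, method = "radix")]
    v <- cand[1L]
    k <- max(k, cur[[v]])
    core[[v]] <- k
    alive[[v]] <- FALSE
    for (u in adj[[v]]) if (alive[[u]]) cur[[u]] <- cur[[u]] - 1L
  }
  structure(list(k = NA_integer_,
                 member_nodes = sort.int(nodes, method = "radix"),
                 core_number = core),
            class = "kcore_result")
}

#' @export
print.kcore_result <- function(x, ...) {
  if (is.na(x$k)) {
    cat("Core decomposition of", length(x$core_number), "nodes; max core number",
        max(x$core_number), "\n")
  } else {
    cat(sprintf("%d-core: %d node(s)\n", x$k, length(x$member_nodes)))
    if (length(x$member_nodes)) cat(" ", paste(x$member_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fruchterman-Reingold force-directed layout
#'
#' Seeded wrapper around the igraph Fruchterman-Reingold implementation:
#' attractive forces along edges, repulsive forces between all node pairs,
#' with temperature cooling over the iterations. Coordinates are rescaled
#' into the square frame \code{[-area/2, area/2]^2}; the same seed always
#' yields identical coordinates.
#'
#' @param graph a \code{couse_graph} or \code{igraph} graph.
#' @param iterations number of cooling iterations (>= 1).
#' @param area side length of the square frame the layout is scaled to.
#' @param seed integer seed fixing the random initial placement.
#' @return A numeric matrix with one row per node (rownames = codes) and
#'   columns \code{x}, \code{y}.
#' @export
fr_layout <- function(graph, iterations = 150L, area = 2, seed = 42L) {
  stopifnot(iterations >= 1L, area > 0)
  g <- as_igraph(graph)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations, grid = "nogrid")
  if (igraph::vcount(g) > 1L) {
    xy <- igraph::norm_coords(xy, xmin = -area / 2, xmax = area / 2,
                              ymin = -area / 2, ymax = area / 2)
  }
  dimnames(xy) <- list(igraph::V(g)$name, c("x", "y"))
  xy
}

#' Export node and edge lists as delimited text
#'
#' Writes the node list (id, code, degree, core_number, x, y) and the edge
#' list (source, target, weight) in the layout common graph GUIs (e.g.
#' Gephi) import. Node rows are ordered by degree descending then code;
#' edge rows by weight descending then codes, so output is deterministic.
#'
#' @param graph a \code{couse_graph} or \code{igraph} graph.
#' @param layout optional coordinate matrix from [fr_layout()]; if missing,
#'   x and y are written as \code{NA}.
#' @param node_path,edge_path output file paths.
#' @param sep field separator, default comma.
#' @return Invisibly, the two paths.
#' @export
export_graph <- function(graph, layout = NULL, node_path, edge_path, sep = ",") {
  g <- as_igraph(graph)
  codes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  core <- core_decomposition(g)$core_number[codes]
  xy <- if (is.null(layout)) matrix(NA_real_, length(codes), 2L,
                                    dimnames = list(codes, c("x", "y")))
        else layout[codes, , drop = FALSE]
  ord <- order(-deg, codes, method = "radix")
  nodes <- data.frame(id = seq_along(codes), code = codes[ord],
                      degree = as.integer(deg[ord]),
                      core_number = as.integer(core[ord]),
                      x = xy[ord, 1L], y = xy[ord, 2L])
  el <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(el)) el <- data.frame(from = character(), to = character(),
                                  weight = numeric())
  if (is.null(el$weight)) el$weight <- 1
  swap <- el$from > el$to
  tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
  el <- el[order(-el$weight, el$from, el$to, method = "radix"), , drop = FALSE]
  edges <- data.frame(source = el$from, target = el$to, weight = el$weight)
  utils::write.table(nodes, node_path, sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(edges, edge_path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Re-import an exported node/edge list
#'
#' Reads files written by [export_graph()] back into a \code{couse_graph}
#' (isomorphic to the exported graph; layout coordinates are not restored).
#'
#' @param node_path,edge_path paths written by [export_graph()].
#' @param sep field separator, default comma.
#' @return A \code{couse_graph}.
#' @export
import_graph <- function(node_path, edge_path, sep = ",") {
  nodes <- utils::read.table(node_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  edges <- utils::read.table(edge_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source, to = edges$target, weight = edges$weight),
    directed = FALSE, vertices = data.frame(name = nodes$code))
  structure(list(graph = g, min_weight = NA_integer_), class = "couse_graph")
}

#' @export
print.couse_graph <- function(x, ...) {
  g <- x$graph
  cat("Acupoint co-usage network:", igraph::vcount(g), "nodes,",
      igraph::ecount(g), "edges (min co-occurrence weight",
      x$min_weight, ")\n")
  invisible(x)
}

#' @export
plot.couse_graph <- function(x, layout = fr_layout(x), ...) {
  igraph::plot.igraph(x$graph, layout = layout,
                      vertex.size = 3 + igraph::degree(x$graph) / 2,
                      edge.width = igraph::E(x$graph)$weight %||% 1, ...)
  invisible(x)
}
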