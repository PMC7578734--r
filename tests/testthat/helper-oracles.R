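# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: counting is done by direct set scans, shortest
# paths by a hand-rolled breadth-first search, and core numbers by a naive
# fixed point that recomputes degrees from scratch on every pass.

toy_tx <- function(sets) transactions(sets)

# exact count of transactions containing all `items`, by scan
oracle_count <- function(sets, items) {
  sum(vapply(sets, function(s) all(items %in% s), logical(1)))
}

# all-pairs shortest path matrix by BFS over an adjacency list
oracle_bfs_distances <- function(adj) {
  nodes <- names(adj)
  d <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

# adjacency list of an igraph-backed couse_graph
graph_adj <- function(g) {
  ig <- if (inherits(g, "couse_graph")) g$graph else g
  nodes <- igraph::V(ig)$name
  adj <- lapply(igraph::adjacent_vertices(ig, igraph::V(ig)),
                function(v) v$name)
  names(adj) <- nodes
  adj
}

# naive k-core: delete all nodes of degree < k, recompute from scratch,
# repeat until stable
oracle_k_core_members <- function(adj, k) {
  alive <- names(adj)
  repeat {
    deg <- vapply(alive, function(v) length(intersect(adj[[v]], alive)),
                  integer(1))
    drop <- alive[deg < k]
    if (!length(drop)) return(sort(alive))
    alive <- setdiff(alive, drop)
  }
}

oracle_core_numbers <- function(adj) {
  core <- stats::setNames(rep(0L, length(adj)), names(adj))
  k <- 0L
  repeat {
    k <- k + 1L
    members <- oracle_k_core_members(adj, k)
    if (!length(members)) return(core)
    core[members] <- k
  }
}

# seeded Erdos-Renyi-style couse_graph via random transactions
random_graph <- function(n_items, n_tx, seed, p = 0.35) {
  probs <- stats::setNames(rep(p, n_items), sprintf("i%02d", seq_len(n_items)))
  build_network(random_dataset(n_tx, probs, seed = seed))
}

expect_rules_equal <- function(a, b) {
  cols <- c("antecedent", "consequent", "support_pct", "confidence_pct",
            "lift", "count", "joint_count")
  expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols])
}
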