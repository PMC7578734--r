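test_that("edges carry co-occurrence counts and honour the weight floor", {
  fx <- build_csap_fixture()
  g <- build_network(fx, min_weight = 1)
  ig <- g$graph
  e <- igraph::get_edge_ids(ig, c("LU9", "PC6"))
  expect_equal(igraph::E(ig)$weight[e], 15)
  g5 <- build_network(fx, min_weight = 5)
  expect_true(all(igraph::E(g5$graph)$weight >= 5))
  gbig <- build_network(fx, min_weight = 100)
  expect_equal(igraph::ecount(gbig$graph), 0L)
})

test_that("one shared prescription yields a unit-weight triangle", {
  g <- build_network(toy_tx(list(S1 = c("a", "b", "c"))))
  expect_equal(igraph::ecount(g$graph), 3L)
  expect_true(all(igraph::E(g$graph)$weight == 1))
})

test_that("degree counts partners and degrees sum to twice the edges", {
  fx <- build_csap_fixture()
  g <- build_network(fx)
  cm <- cooccurrence_matrix(fx)
  off <- cm$counts; diag(off) <- 0L
  expect_equal(unname(igraph::degree(g$graph)[cm$items]),
               unname(rowSums(off >= 1)))
  expect_equal(sum(igraph::degree(g$graph)), 2 * igraph::ecount(g$graph))
})

test_that("closed-form statistics hold on K4 and the 3-path", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  st <- graph_stats(k4)
  expect_equal(st$average_degree, 3)
  expect_equal(st$average_path_length, 1)
  expect_equal(st$diameter, 1)

  p3 <- igraph::graph_from_literal(a - b, b - c)
  st <- graph_stats(p3)
  expect_equal(st$average_degree, 4 / 3)
  expect_equal(st$average_path_length, 4 / 3)
  expect_equal(st$diameter, 2)
})

test_that("path statistics agree with a hand-rolled BFS oracle", {
  for (seed in 1:8) {
    g <- random_graph(12, 15, seed = seed)
    adj <- graph_adj(g)
    d <- oracle_bfs_distances(adj)
    finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    st <- graph_stats(g)
    # oracle restricted to the largest component
    comp <- igraph::components(g$graph)
    if (comp$no == 1L) {
      expect_equal(st$average_path_length, mean(finite))
      expect_equal(st$diameter, max(finite))
    } else {
      keep <- names(which(comp$membership == which.max(comp$csize)))
      dd <- d[keep, keep][upper.tri(d[keep, keep])]
      expect_equal(st$average_path_length, mean(dd))
      expect_equal(st$diameter, max(dd))
    }
  }
})

test_that("single-node graphs report undefined path statistics, not errors", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "a"
  st <- graph_stats(g1)
  expect_true(is.na(st$average_path_length))
  expect_true(is.na(st$diameter))
})

test_that("k-core peeling matches the textbook case and nests", {
  g <- igraph::graph_from_literal(a - b, b - c, a - c, c - d)  # triangle + pendant
  expect_equal(k_core(g, 2)$member_nodes, c("a", "b", "c"))
  expect_equal(k_core(g, 1)$member_nodes, c("a", "b", "c", "d"))
  core <- core_decomposition(g)$core_number
  expect_equal(core[["d"]], 1L)
  expect_equal(core[["a"]], 2L)
  for (k in 0:3) {
    expect_true(all(k_core(g, k + 1)$member_nodes %in% k_core(g, k)$member_nodes))
  }
})

test_that("core decomposition equals the naive fixed-point oracle", {
  for (seed in 1:8) {
    g <- random_graph(14, 18, seed = seed)
    adj <- graph_adj(g)
    core <- core_decomposition(g)$core_number
    expect_equal(core[sort(names(core))], oracle_core_numbers(adj)[sort(names(adj))])
    # and igraph's own coreness as a second, independent implementation
    expect_equal(unname(core[igraph::V(g$graph)$name]),
                 unname(igraph::coreness(g$graph)))
    for (k in 1:4) {
      expect_equal(k_core(g, k)$member_nodes, oracle_k_core_members(adj, k))
    }
  }
})

test_that("every k-core member keeps degree >= k inside the core", {
  g <- random_graph(14, 18, seed = 99)
  for (k in 1:5) {
    kc <- k_core(g, k)
    if (!length(kc$member_nodes)) next
    sub <- igraph::induced_subgraph(g$graph, kc$member_nodes)
    expect_true(all(igraph::degree(sub) >= k))
  }
})

test_that("the layout is reproducible under a fixed seed and frame-bounded", {
  g <- build_network(build_csap_fixture())
  a <- fr_layout(g, iterations = 80, area = 2, seed = 7)
  b <- fr_layout(g, iterations = 80, area = 2, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(a) <= 1 + 1e-12))
  c_ <- fr_layout(g, iterations = 80, area = 2, seed = 8)
  expect_false(identical(a, c_))
})

test_that("the hub of a star lands nearer the leaf centroid than any leaf", {
  star <- igraph::make_star(9, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:8))
  xy <- fr_layout(star, iterations = 300, seed = 3)
  centroid <- colMeans(xy[-1, , drop = FALSE])
  d_hub <- sqrt(sum((xy["hub", ] - centroid)^2))
  d_leaves <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                              matrix(centroid, 8, 2, byrow = TRUE))^2))
  expect_true(all(d_hub < d_leaves))
})

test_that("export writes deterministic node/edge lists that round-trip", {
  fx <- build_csap_fixture()
  g <- build_network(fx)
  lay <- fr_layout(g, seed = 1)
  np <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, lay, np, ep)
  nodes <- read.csv(np)
  edges <- read.csv(ep)
  expect_equal(nrow(nodes), igraph::vcount(g$graph))
  expect_equal(nrow(edges), igraph::ecount(g$graph))
  # PC6 co-occurs with the most acupoints, so it tops the node list
  expect_equal(nodes$code[1], "PC6")
  expect_equal(nodes$degree[1], max(nodes$degree))
  g2 <- import_graph(np, ep)
  expect_true(igraph::isomorphic(g$graph, g2$graph))
  expect_equal(sort(igraph::V(g2$graph)$name), sort(igraph::V(g$graph)$name))

  np2 <- withr::local_tempfile(fileext = ".csv")
  ep2 <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, lay, np2, ep2)
  expect_identical(readLines(np2), readLines(np))  # stable write
  expect_identical(readLines(ep2), readLines(ep))
})

test_that("the fixture's co-usage network is hub-dominated", {
  st <- graph_stats(build_network(build_csap_fixture()))
  expect_lte(st$diameter, 3)
  expect_true(st$connected)
})
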