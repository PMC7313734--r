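test_that("largest_component respects size and lexicographic tie-break", {
  g <- triangle() + igraph::vertices("d")
  expect_setequal(igraph::V(largest_component(g))$name, c("a", "b", "c"))
  expect_identical(edge_key(largest_component(triangle())), edge_key(triangle()))
  two_k2 <- mk_graph(c("c", "d", "a", "b"))
  expect_setequal(igraph::V(largest_component(two_k2))$name, c("a", "b"))
})

test_that("aspl matches closed forms and rejects disconnected input", {
  expect_equal(aspl(igraph::make_full_graph(4)), 1)
  ring5 <- igraph::make_ring(5)
  expect_equal(aspl(ring5), 1.5)
  expect_equal(aspl(path3()), 4 / 3)
  for (n in c(4, 9, 20)) {
    expect_equal(aspl(igraph::make_full_graph(n)), 1)
    expect_equal(aspl(igraph::make_ring(n, circular = FALSE)), (n + 1) / 3)
  }
  expect_error(aspl(mk_graph(c("a", "b", "c", "d"))), "connected")
})

test_that("deleting an edge never decreases ASPL of a still-connected graph", {
  g <- make_reference_network(12, "random", list(m = 24), seed = 8)
  base <- aspl(g)
  el <- igraph::as_edgelist(g)
  for (e in seq_len(nrow(el))) {
    g2 <- igraph::delete_edges(g, paste(el[e, ], collapse = "|"))
    if (igraph::is_connected(g2)) expect_gte(aspl(g2), base - 1e-12)
  }
})

test_that("average local clustering matches hand enumeration", {
  expect_equal(avg_clustering(igraph::make_full_graph(4)), 1)
  expect_equal(avg_clustering(igraph::make_tree(10, mode = "undirected")), 0)
  expect_equal(avg_clustering(cycle4()), 0)
  # triangle plus pendant attached at a: locals are 1/3 (a), 1, 1, 0 (pendant)
  g <- mk_graph(c("a", "b", "b", "c", "c", "a", "a", "d"))
  expect_equal(avg_clustering(g), (1 / 3 + 1 + 1 + 0) / 4)
  # global transitivity variant: 3 triangles / triples
  expect_equal(avg_clustering(g, "transitivity"),
               igraph::transitivity(g, type = "global"))
})

test_that("modularity maximization finds the two-triangle partition", {
  g <- two_triangle_bridge()
  res <- modularity_best(g, restarts = 10, seed = 1)
  expect_equal(res$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(length(unique(res$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(res$membership[c("d", "e", "f")])), 1)

  # never below the single-community partition, never above 1
  for (s in 1:5) {
    g2 <- make_reference_network(15, "random", list(m = 25), seed = s)
    q <- modularity_best(g2, restarts = 5, seed = s)$modularity
    expect_gte(q, 0)
    expect_lte(q, 1)
  }
  expect_error(modularity_best(mk_graph(character(0), isolates = "a")),
               "edgeless")
})

test_that("modularity is deterministic given seed and restarts", {
  g <- make_reference_network(20, "communities",
                              list(block_sizes = c(10, 10), p_within = 0.5,
                                   p_between = 0.05), seed = 3)
  q1 <- modularity_best(g, restarts = 8, seed = 42)
  q2 <- modularity_best(g, restarts = 8, seed = 42)
  expect_identical(q1, q2)
})

test_that("small-world sigma is 1 on K4 and exceeds 1 for a rewired lattice", {
  k4 <- igraph::set_vertex_attr(igraph::make_full_graph(4), "name",
                                value = letters[1:4])
  expect_equal(small_world_sigma(k4, n_random = 5, seed = 1), 1)

  # high-clustering low-path graph: sigma > 1 in the clear majority of seeds
  ws <- make_reference_network(30, "ring_lattice_rewired",
                               list(nei = 3, p_rewire = 0.05), seed = 2)
  sig <- vapply(1:10, function(s) {
    small_world_sigma(largest_component(ws), n_random = 30, seed = s)
  }, numeric(1))
  expect_gte(mean(sig > 1), 0.95)
})

test_that("metrics are invariant under node relabeling", {
  g <- make_reference_network(15, "random", list(m = 30), seed = 6)
  perm <- setNames(sprintf("q%02d", 1:15), sort(igraph::V(g)$name))
  g2 <- igraph::set_vertex_attr(g, "name",
                                value = unname(perm[igraph::V(g)$name]))
  expect_equal(aspl(g2), aspl(g))
  expect_equal(avg_clustering(g2), avg_clustering(g))
  expect_equal(modularity_best(g2, 5, 9)$modularity,
               modularity_best(g, 5, 9)$modularity)
  expect_equal(small_world_sigma(g2, n_random = 20, seed = 9),
               small_world_sigma(g, n_random = 20, seed = 9))
})

test_that("network_metrics composes per-graph statistics with conventions", {
  g <- two_triangle_bridge() + igraph::vertices("zz")
  m <- network_metrics(g, restarts = 5, n_random = 10, seed = 1)
  expect_equal(m$n_nodes, 7)
  expect_equal(m$n_edges, 7)
  expect_equal(m$n_components, 2)
  expect_equal(m$lcc_size, 6)
  # aspl on the largest component only
  expect_equal(m$aspl, aspl(two_triangle_bridge()))
  # clustering on the full graph (isolated node contributes 0)
  expect_equal(m$clustering, avg_clustering(g))
  expect_equal(m$modularity, 5 / 14)

  tbl <- metrics_table(list(p1 = g, p2 = triangle()), restarts = 2,
                       n_random = 5, seed = 1)
  expect_identical(tbl$id, c("p1", "p2"))
  expect_true(is.na(tbl$small_world[2]))  # triangle below the sigma floor
})
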