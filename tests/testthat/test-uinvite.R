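test_that("initial item probability is degree-proportional", {
  expect_equal(initial_log_probability(triangle(), "a"), log(1 / 3))
  expect_equal(initial_log_probability(path3(), "b"), log(1 / 2))
  g <- path3() + igraph::vertices("d")
  expect_equal(initial_log_probability(g, "d"), -Inf)
  expect_error(initial_log_probability(path3(), "zebra"), "not a node")
})

test_that("first-hit distribution matches hand-solved and symmetric cases", {
  p <- first_hit_distribution(cycle4(), c("a", "b"), "b")
  expect_equal(p[["c"]], 2 / 3, tolerance = 1e-12)
  expect_equal(p[["d"]], 1 / 3, tolerance = 1e-12)

  star <- mk_graph(c("s", "l1", "s", "l2", "s", "l3"))
  p <- first_hit_distribution(star, c("l1", "s"), "s")
  expect_equal(unname(p[c("l2", "l3")]), c(0.5, 0.5))

  p <- first_hit_distribution(path3(), "a", "a")
  expect_equal(p[["b"]], 1)
  expect_equal(p[["c"]], 0)

  # impossible continuation: visited component sealed off
  g <- mk_graph(c("a", "b", "c", "d"))
  p <- first_hit_distribution(g, c("a", "b"), "b")
  expect_true(all(p == 0))
})

test_that("first-hit probabilities are a proper distribution over reachable nodes", {
  set.seed(7)
  for (rep in 1:20) {
    g <- make_reference_network(8, "random", list(m = 12), seed = rep)
    nodes <- igraph::V(g)$name
    k <- sample(1:6, 1)
    visited <- sample(nodes, k)
    p <- first_hit_distribution(g, visited, sample(visited, 1))
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
    expect_lte(sum(p), 1 + 1e-9)
    expect_equal(sum(p), 1, tolerance = 1e-9)  # connected graph: no trapping
  }
})

test_that("list likelihood composes initial and first-hit factors", {
  expect_equal(list_log_likelihood(path3(), c("a", "b")), log(1 / 4))
  expect_equal(list_log_likelihood(triangle(), c("a", "b", "c")),
               log(1 / 3) + log(1 / 2))
  g <- mk_graph(c("a", "b", "c", "d"))
  expect_equal(list_log_likelihood(g, c("a", "c")), -Inf)
  expect_error(list_log_likelihood(path3(), c("a", "zebra")), "not in network")
})

test_that("matrix-solve likelihood agrees with the walk-sum oracle and the compiled core", {
  set.seed(42)
  graphs <- c(
    Filter(function(g) igraph::ecount(g) > 0, all_graphs(letters[1:4])),
    lapply(1:12, function(i) make_reference_network(5, "random",
                                                    list(m = sample(4:9, 1)),
                                                    seed = 100 + i)))
  checked <- 0
  for (g in graphs) {
    nodes <- igraph::V(g)$name
    deg <- igraph::degree(g)
    pool <- nodes[deg > 0]
    if (length(pool) < 2) next
    start <- sample(pool, 1)
    items <- tryCatch(simulate_list(g, min(length(pool), 3), seed = checked + 1),
                      error = function(e) NULL)
    if (is.null(items)) next
    ll <- list_log_likelihood(g, items)
    oracle <- list_loglik_oracle(g, items)
    expect_equal(ll, oracle, tolerance = 1e-6)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    storage.mode(adj) <- "integer"
    expect_equal(fluenet:::cpp_list_loglik(adj, match(items, nodes) - 1L), ll,
                 tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("dataset likelihood is additive with absorbing -Inf", {
  lists <- list(c("a", "b"), c("a", "b"))
  expect_equal(dataset_log_likelihood(path3(), lists), 2 * log(1 / 4))
  expect_equal(dataset_log_likelihood(path3(), list()), 0)
  g <- mk_graph(c("a", "b", "c", "d"))
  expect_equal(dataset_log_likelihood(g, list(c("a", "b"), c("a", "c"))), -Inf)
})

test_that("network prior matches the forced three-node example and normalizes", {
  ref <- mk_graph(c("x", "y"))
  pr <- prior_spec(ref)
  vocab <- c("x", "y", "z")
  g1 <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(vocab)
  g1e <- igraph::add_edges(g1, c("x", "y"))
  expect_equal(network_log_prior(g1e, pr), log((2/3) * (1/2) * (1/2)))
  expect_equal(network_log_prior(g1, pr), log((1/3) * (1/2) * (1/2)))

  for (vocab_n in 3:4) {
    total <- sum(vapply(all_graphs(letters[seq_len(vocab_n)]),
                        function(g) exp(network_log_prior(g, pr)), numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
  expect_error(prior_spec(p_present = 1), "strictly")
})

test_that("initialization joins consecutive items and has finite likelihood", {
  g <- build_init_network(list(c("a", "b", "c")))
  expect_identical(edge_key(g), c("a|b", "b|c"))
  g2 <- build_init_network(list(c("a", "b"), c("b", "a")))
  expect_identical(edge_key(g2), "a|b")
  lists <- list(c("d", "b", "a", "c"), c("a", "c", "d"))
  expect_true(is.finite(dataset_log_likelihood(build_init_network(lists), lists)))
  expect_error(build_init_network(list()), "empty vocabulary")
})

test_that("the MAP search improves on the initialization and keeps forced edges", {
  lists <- rep(list(c("a", "b")), 3)
  fit <- estimate_network(lists, prior_spec(NULL), search_params(1))
  expect_identical(edge_key(fit$network), "a|b")

  truth <- make_reference_network(8, "random", list(m = 12), seed = 9)
  lists <- lapply(1:50, function(i) simulate_list(truth, 6, seed = 500 + i))
  pr <- prior_spec(truth)
  fit <- estimate_network(lists, pr, search_params(3))
  init_lp <- log_posterior(build_init_network(lists), lists, pr)
  expect_gte(fit$log_posterior, init_lp)
  # the C++ scorer and the R scorer agree on the returned network
  expect_equal(log_posterior(fit$network, lists, pr), fit$log_posterior,
               tolerance = 1e-8)
  # recovery beats the trivial graphs
  vocab <- fit$vocab
  empty <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(vocab)
  complete <- igraph::make_full_graph(length(vocab)) |>
    igraph::set_vertex_attr("name", value = vocab)
  truth_v <- igraph::induced_subgraph(truth, vocab)
  expect_gte(edge_f1(fit$network, truth_v), edge_f1(empty, truth_v))
  expect_gte(edge_f1(fit$network, truth_v), edge_f1(complete, truth_v))
})

test_that("the search is deterministic given the seed and seed-sensitive otherwise", {
  truth <- make_reference_network(7, "random", list(m = 10), seed = 2)
  lists <- lapply(1:6, function(i) simulate_list(truth, 5, seed = 40 + i))
  f1 <- estimate_network(lists, prior_spec(truth), search_params(11))
  f2 <- estimate_network(lists, prior_spec(truth), search_params(11))
  expect_identical(edge_key(f1$network), edge_key(f2$network))
  expect_identical(f1$log_posterior, f2$log_posterior)
})

test_that("estimation is invariant to node relabeling", {
  truth <- make_reference_network(6, "random", list(m = 8), seed = 5)
  lists <- lapply(1:8, function(i) simulate_list(truth, 5, seed = 70 + i))
  fit <- estimate_network(lists, prior_spec(truth), search_params(4))

  # order-preserving label bijection: the seeded sweep order then maps too
  perm <- setNames(paste0("z", 1:6), sort(igraph::V(truth)$name))
  relabel <- function(g) {
    igraph::set_vertex_attr(g, "name",
                            value = unname(perm[igraph::V(g)$name]))
  }
  lists_p <- lapply(lists, function(l) unname(perm[l]))
  fit_p <- estimate_network(lists_p, prior_spec(relabel(truth)),
                            search_params(4))
  # same posterior value and isomorphic networks under the label map
  expect_equal(fit_p$log_posterior, fit$log_posterior, tolerance = 1e-8)
  remapped <- vapply(strsplit(edge_key(fit$network), "\\|"),
                     function(e) paste(sort(perm[e]), collapse = "|"),
                     character(1))
  expect_identical(sort(remapped), edge_key(fit_p$network))
})

test_that("fit objects tidy and glance into tables", {
  lists <- rep(list(c("a", "b", "c")), 2)
  fit <- estimate_network(lists, prior_spec(NULL), search_params(2))
  td <- tidy(fit)
  expect_true(all(c("from", "to") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_nodes, 3)
  expect_true(gl$converged)
})
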