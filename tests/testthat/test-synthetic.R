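test_that("reference networks are connected, labeled, and seed-deterministic", {
  for (model in c("random", "ring_lattice_rewired", "communities")) {
    g <- make_reference_network(20, model,
                                list(m = 40, block_sizes = c(10, 10)), seed = 2)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::vcount(g), 20)
    expect_true(all(igraph::V(g)$name %in% read_lexicon()))
  }
  g1 <- make_reference_network(20, "random", list(m = 40), seed = 7)
  g2 <- make_reference_network(20, "random", list(m = 40), seed = 7)
  expect_identical(edge_key(g1), edge_key(g2))
  expect_gte(igraph::ecount(g1), 40)  # connectivity repair can only add

  # impossible inter-block probability: repaired with exactly one bridge
  g3 <- make_reference_network(16, "communities",
                               list(block_sizes = c(8, 8), p_within = 0.9,
                                    p_between = 0), seed = 5)
  expect_true(igraph::is_connected(g3))
  expect_equal(length(igraph::graph_attr(g3, "repaired_edges")), 1)
})

test_that("perturb_network hits its expected edge retention", {
  ref <- make_reference_network(20, "random", list(m = 40), seed = 1)
  expect_identical(edge_key(perturb_network(ref, 0, 0, seed = 1)),
                   edge_key(ref))
  expect_equal(igraph::ecount(perturb_network(ref, 1, 0, seed = 1)), 0)

  m_ref <- igraph::ecount(ref)
  kept <- vapply(1:300, function(s) {
    length(intersect(edge_key(perturb_network(ref, 0.2, 0, seed = s)),
                     edge_key(ref))) / m_ref
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / (m_ref * 300))
  expect_lt(abs(mean(kept) - 0.8), 3 * se)
})

test_that("simulated walks start degree-proportionally and hit first-passage targets", {
  n <- 20000
  walks <- simulate_lists(path3(), rep(1L, n), seed = 12)
  firsts <- vapply(walks, `[`, character(1), 1)
  p_hat <- table(factor(firsts, c("a", "b", "c"))) / n
  for (node in c("a", "b", "c")) {
    p_true <- c(a = 0.25, b = 0.5, c = 0.25)[[node]]
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat[[node]] - p_true), 3 * se)
  }

  # forced start: path a-b-c from a can only ever emit (a, b, c)
  full <- simulate_lists(path3(), rep(3L, 200), seed = 5)
  from_a <- Filter(function(l) l[1] == "a", full)
  expect_gt(length(from_a), 10)
  for (l in from_a) expect_identical(l, c("a", "b", "c"))
  expect_error(simulate_list(mk_graph(c("a", "b", "c", "d")), 3, seed = 1),
               "fewer than")
})

test_that("second items of simulated walks match the analytic first-hit law", {
  walks <- simulate_lists(cycle4(), rep(2L, 40000), seed = 8)
  seconds <- vapply(Filter(function(l) l[1] == "b", walks),
                    `[`, character(1), 2)
  kept <- length(seconds)
  expect_gt(kept, 5000)
  p <- first_hit_distribution(cycle4(), "b", "b")
  for (node in c("a", "c")) {
    p_hat <- mean(seconds == node)
    se <- sqrt(p[[node]] * (1 - p[[node]]) / kept)
    expect_lt(abs(p_hat - p[[node]]), 3 * se)
  }
})

test_that("cohorts reproduce the study's group structure deterministically", {
  cfg <- cohort_config(master_seed = 3L)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$scores), 92)
  expect_equal(sum(coh$scores$group %in% c("monolingual", "ES", "SE")), 66)
  expect_equal(table(coh$scores$group)[["SE"]], 28)
  expect_equal(table(coh$scores$group)[["ES"]], 13)

  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$fluency, coh2$fluency)
  expect_identical(coh$scores, coh2$scores)

  # per-participant lists regenerate bit-identically from (master_seed, id)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(coh, d1); write_cohort(coh2, d2)
  for (f in c("fluency.csv", "scores.csv", "reference.tsv", "registry.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("injected intrusion rates land near their configured value", {
  cfg <- cohort_config(master_seed = 17L)
  coh <- simulate_cohort(cfg)
  rep <- clean_lists(coh$fluency, read_lexicon())$report
  # ~0.005 of responses trigger an intrusion insertion
  expect_lt(rep$intrusion_rate, 0.012)
  expect_gt(rep$intrusion_rate, 0.0005)
  expect_lt(rep$intrusion_rate, 0.006 * 2)
})

test_that("list lengths track their group means", {
  coh <- simulate_cohort(cohort_config(master_seed = 23L))
  lens <- clean_lists(coh$fluency, read_lexicon())$lists |> fluency_counts()
  joined <- dplyr::left_join(lens, coh$scores, by = "id")
  m <- tapply(joined$mean_items, joined$group, mean)
  expect_lt(m[["SE"]], m[["ES"]])
  expect_equal(m[["SE"]], 33.3, tolerance = 0.12)  # relative
  expect_equal(m[["ES"]], 42.1, tolerance = 0.12)
})

test_that("simulated lists are likelier under their generating network than a random one", {
  wins <- 0
  for (s in 1:40) {
    truth <- make_reference_network(12, "random", list(m = 24), seed = s)
    other <- make_reference_network(12, "random", list(m = 24), seed = s + 500)
    lists <- lapply(1:3, function(i) simulate_list(truth, 8, seed = 1000 * s + i))
    ll_t <- dataset_log_likelihood(truth, lists)
    ll_o <- dataset_log_likelihood(other, lists)
    if (ll_t > ll_o) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})

test_that("infeasible correlation targets error before generation", {
  cfg <- cohort_config(master_seed = 2L,
                       target_cors = c(intelligence = 0.1, mean_items = 0.95,
                                       aspl = -0.95, clustering = 0.95,
                                       modularity = 0.95, small_world = 0.95))
  expect_error(simulate_cohort(cfg), "infeasible")
})
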