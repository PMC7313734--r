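# Shared fixtures, built in code.

# undirected graph from a flat vector of edge endpoints
mk_graph <- function(edges, isolates = character(0)) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(c(edges, isolates)))
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g
}

path3 <- function() mk_graph(c("a", "b", "b", "c"))
triangle <- function() mk_graph(c("a", "b", "b", "c", "c", "a"))
cycle4 <- function() mk_graph(c("a", "b", "b", "c", "c", "d", "d", "a"))

# two triangles joined by one bridge edge
two_triangle_bridge <- function() {
  mk_graph(c("a", "b", "b", "c", "c", "a",
             "d", "e", "e", "f", "f", "d", "a", "d"))
}

named_graph <- function(n, edges) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(letters[seq_len(n)])
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g
}

# all graphs on a fixed, named vertex set (one per subset of pairs)
all_graphs <- function(vocab) {
  pairs <- t(utils::combn(vocab, 2))
  lapply(0:(2^nrow(pairs) - 1), function(mask) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)))
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(vocab)
    if (any(sel)) g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    g
  })
}

# Independent oracle for the censored-walk step probability: explicit
# walk-length truncation. Sums, over all walk lengths L = 1, 2, ..., the
# probability that the walk is still inside the visited set after L-1 steps
# and exits to each unvisited node at step L; stops when the unabsorbed tail
# (a verified geometric bound on all longer walks) is below `tail_tol`.
# Shares no code with the (I - T_VV) linear solve it checks.
first_hit_oracle <- function(network, visited, current, tail_tol = 1e-10,
                             max_steps = 100000) {
  nodes <- igraph::V(network)$name
  adj <- as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
  dimnames(adj) <- list(nodes, nodes)
  deg <- rowSums(adj)
  unvisited <- setdiff(nodes, visited)
  if (any(deg[visited] == 0)) {
    return(setNames(rep(0, length(unvisited)), unvisited))
  }
  step <- adj / deg
  T_VV <- step[visited, visited, drop = FALSE]
  T_VU <- step[visited, unvisited, drop = FALSE]
  absorbed <- setNames(rep(0, length(unvisited)), unvisited)
  mass <- setNames(rep(0, length(visited)), visited)
  mass[current] <- 1
  for (s in seq_len(max_steps)) {
    inc <- as.numeric(mass %*% T_VU)
    absorbed <- absorbed + inc
    mass <- as.numeric(mass %*% T_VV)
    names(mass) <- visited
    if (sum(mass) < tail_tol) break  # tail bound: all longer walks < tol
    # part of the mass can be permanently trapped inside the visited set;
    # once the per-step absorbed increment is negligible, longer walks
    # contribute nothing detectable
    if (s > 50 && sum(inc) < 1e-18) break
  }
  absorbed
}

# list probability by chaining the oracle over prefixes
list_loglik_oracle <- function(network, items, tail_tol = 1e-10) {
  deg <- igraph::degree(network)
  ll <- log(deg[items[1]]) - log(sum(deg))
  if (!is.finite(ll)) return(-Inf)
  for (k in seq_along(items)[-1]) {
    p <- first_hit_oracle(network, items[seq_len(k - 1)], items[k - 1],
                          tail_tol = tail_tol)
    pk <- p[[items[k]]]
    if (is.null(pk) || pk <= 0) return(-Inf)
    ll <- ll + log(pk)
  }
  unname(ll)
}

edge_key <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  sort(apply(el, 1, function(r) paste(sort(r), collapse = "|")))
}

edge_f1 <- function(est, truth) {
  ee <- edge_key(est); et <- edge_key(truth)
  tp <- length(intersect(ee, et))
  if (length(ee) + length(et) == 0) return(1)
  2 * tp / (length(ee) + length(et))
}

tiny_fluency_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("id,listnum,position,item", rows), path)
  path
}
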