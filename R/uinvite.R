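#' Edge-prior specification for network estimation
#'
#' The prior over candidate networks is an independent Bernoulli prior per
#' node pair, anchored to a reference association network: an edge has prior
#' probability `p_present` if it exists in the reference network, `p_absent`
#' if both endpoints are reference nodes but the edge is not, and `p_unknown`
#' if either endpoint is unknown to the reference. The defaults (2/3, 2/5,
#' 1/2) are the values established for this estimator family.
#'
#' @param reference Undirected igraph reference network (named vertices), or
#'   `NULL` for a reference-free prior (every pair gets `p_unknown`).
#' @param p_present,p_absent,p_unknown Edge prior probabilities, all strictly
#'   inside (0, 1).
#' @return An object of class `fluenet_prior`.
#' @export
prior_spec <- function(reference = NULL, p_present = 2 / 3, p_absent = 2 / 5,
                       p_unknown = 1 / 2) {
  probs <- c(p_present = p_present, p_absent = p_absent, p_unknown = p_unknown)
  if (any(probs <= 0 | probs >= 1)) {
    stop("edge prior probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(reference) && !igraph::is_igraph(reference)) {
    stop("`reference` must be an igraph object or NULL", call. = FALSE)
  }
  structure(list(reference = reference, p_present = p_present,
                 p_absent = p_absent, p_unknown = p_unknown),
            class = "fluenet_prior")
}

# n x n matrix of per-pair prior edge probabilities over `vocab`
prior_probability_matrix <- function(vocab, prior) {
  n <- length(vocab)
  p <- matrix(prior$p_unknown, n, n, dimnames = list(vocab, vocab))
  if (!is.null(prior$reference)) {
    ref_nodes <- igraph::V(prior$reference)$name
    known <- vocab %in% ref_nodes
    p[known, known] <- prior$p_absent
    if (any(known)) {
      sub <- igraph::induced_subgraph(prior$reference,
                                      intersect(ref_nodes, vocab))
      el <- igraph::as_edgelist(sub)
      if (nrow(el) > 0) {
        p[el] <- prior$p_present
        p[el[, 2:1, drop = FALSE]] <- prior$p_present
      }
    }
  }
  diag(p) <- NA_real_
  p
}

# igraph over `vocab` -> 0/1 adjacency with vocab dimnames
adjacency_over_vocab <- function(network, vocab) {
  miss <- setdiff(vocab, igraph::V(network)$name)
  if (length(miss) > 0) {
    network <- igraph::add_vertices(network, length(miss), name = miss)
  }
  sub <- igraph::induced_subgraph(network, vocab)
  a <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
  a <- a[vocab, vocab, drop = FALSE]
  storage.mode(a) <- "integer"
  a
}

graph_from_adjacency <- function(adj, vocab) {
  dimnames(adj) <- list(vocab, vocab)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Log-probability of the first retrieved item
#'
#' Under the retrieval model the first item of a fluency list is chosen with
#' probability proportional to its number of semantic neighbors (its degree).
#'
#' @param network Undirected igraph network with named vertices and at least
#'   one edge.
#' @param item Node name.
#' @return `log(deg(item) / sum of degrees)`; `-Inf` for an isolated node.
#' @export
initial_log_probability <- function(network, item) {
  if (!(item %in% igraph::V(network)$name)) {
    stop("item '", item, "' is not a node of the network", call. = FALSE)
  }
  if (igraph::ecount(network) == 0) {
    stop("network has no edges; initial distribution undefined", call. = FALSE)
  }
  d <- unname(igraph::degree(network, item))
  if (d == 0) return(-Inf)
  log(d) - log(2 * igraph::ecount(network))
}

#' First-hit distribution of a censored random walk
#'
#' Probability, for each unvisited node `u`, that a random walk started at
#' `current` — stepping uniformly over neighbors and passing freely through
#' already-visited nodes — first enters the unvisited set at `u`. Computed
#' from the absorbing-chain decomposition: with `T_VV` the transition block
#' within the visited set and `T_VU` the block into the unvisited set, the
#' absorption probabilities are row `current` of `(I - T_VV)^{-1} T_VU`,
#' obtained by a linear solve (never an explicit inverse).
#'
#' @param network Undirected igraph with named vertices.
#' @param visited Character vector of visited node names (each of degree
#'   at least 1).
#' @param current Current node; must be in `visited`.
#' @return Named numeric vector over the unvisited nodes. Sums to 1 whenever
#'   some unvisited node is reachable; all zeros if the visited component has
#'   no edge into the unvisited set (impossible continuation).
#' @export
first_hit_distribution <- function(network, visited, current) {
  nodes <- igraph::V(network)$name
  if (!all(visited %in% nodes)) stop("visited nodes not in network", call. = FALSE)
  if (!(current %in% visited)) stop("`current` must be a visited node", call. = FALSE)
  unvisited <- setdiff(nodes, visited)
  if (length(unvisited) == 0) stop("no unvisited nodes remain", call. = FALSE)
  adj <- adjacency_over_vocab(network, nodes)
  deg <- rowSums(adj)
  if (any(deg[visited] == 0)) {
    return(setNames(rep(0, length(unvisited)), unvisited))
  }
  TT <- adj / deg
  T_VV <- TT[visited, visited, drop = FALSE]
  T_VU <- TT[visited, unvisited, drop = FALSE]
  A <- diag(length(visited)) - T_VV
  sol <- tryCatch(solve(A, T_VU), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    return(setNames(rep(0, length(unvisited)), unvisited))
  }
  p <- pmax(sol[match(current, visited), ], 0)
  setNames(as.numeric(p), unvisited)
}

#' Censored-random-walk log-likelihood of one fluency list
#'
#' The probability of an observed list is the probability of its first item
#' (degree-proportional) times, for each subsequent item, the probability
#' that the walk first hits it given the items produced so far (revisits to
#' produced items are censored, i.e. pass-through). Truncation is free: lists
#' are time-limited prefixes, so no stopping factor is applied.
#'
#' @param network Undirected igraph with named vertices.
#' @param items Character vector of list items, in production order; all must
#'   be network nodes and pairwise distinct.
#' @return Log-probability; `-Inf` if any step is impossible.
#' @export
list_log_likelihood <- function(network, items) {
  nodes <- igraph::V(network)$name
  miss <- setdiff(items, nodes)
  if (length(miss) > 0) {
    stop("list items not in network: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items)) stop("cleaned list has repeated items", call. = FALSE)
  ll <- initial_log_probability(network, items[1])
  if (!is.finite(ll)) return(-Inf)
  if (length(items) >= 2) {
    for (k in 2:length(items)) {
      p <- first_hit_distribution(network, items[seq_len(k - 1)], items[k - 1])
      pk <- p[[items[k]]]
      if (!is.finite(pk) || pk <= 0) return(-Inf)
      ll <- ll + log(pk)
    }
  }
  ll
}

#' Log-likelihood of all of one participant's lists
#'
#' Lists are independent restarts of the retrieval process, so the dataset
#' log-likelihood is the sum over lists.
#'
#' @param network Undirected igraph.
#' @param lists List of character vectors (cleaned fluency lists).
#' @return Sum of [list_log_likelihood()] over `lists` (0 for an empty
#'   collection); `-Inf` absorbs.
#' @export
dataset_log_likelihood <- function(network, lists) {
  if (length(lists) == 0) return(0)
  ll <- 0
  for (l in lists) {
    ll <- ll + list_log_likelihood(network, l)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Log prior probability of a candidate network
#'
#' Independent Bernoulli over unordered node pairs of the candidate
#' vocabulary, with per-pair probabilities from [prior_spec()].
#'
#' @param network Candidate undirected igraph; its vertex set is the
#'   participant vocabulary.
#' @param prior A [prior_spec()] object.
#' @return Log prior probability.
#' @export
network_log_prior <- function(network, prior) {
  vocab <- sort(igraph::V(network)$name)
  p <- prior_probability_matrix(vocab, prior)
  adj <- adjacency_over_vocab(network, vocab)
  ut <- upper.tri(p)
  sum(ifelse(adj[ut] == 1L, log(p[ut]), log1p(-p[ut])))
}

#' Log posterior score of a candidate network
#'
#' @inheritParams network_log_prior
#' @param lists List of character vectors (one participant's cleaned lists).
#' @return [dataset_log_likelihood()] + [network_log_prior()].
#' @export
log_posterior <- function(network, lists, prior) {
  ll <- dataset_log_likelihood(network, lists)
  if (!is.finite(ll)) return(-Inf)
  ll + network_log_prior(network, prior)
}

#' Initialization network for the search
#'
#' Nodes are the union of the participant's items; an edge joins every pair
#' of items adjacent in at least one list. Every observed transition is then
#' an edge, so the dataset log-likelihood of the initialization is finite.
#'
#' @param lists List of character vectors (cleaned lists).
#' @return Undirected igraph.
#' @export
build_init_network <- function(lists) {
  vocab <- sort(unique(unlist(lists)))
  if (length(vocab) == 0) stop("empty vocabulary", call. = FALSE)
  edges <- purrr::map(lists, function(items) {
    if (length(items) < 2) return(NULL)
    cbind(items[-length(items)], items[-1])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vocab)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::simplify(g)
}

#' Search parameters for network estimation
#'
#' @param seed Integer seed driving the sweep order (required; the search is
#'   deterministic given the seed).
#' @param max_sweeps Maximum number of full passes over all candidate edge
#'   toggles.
#' @param tolerance Minimum log-posterior improvement for accepting a toggle;
#'   ties reject (pure hill-climb).
#' @return An object of class `fluenet_search_params`.
#' @export
search_params <- function(seed, max_sweeps = 100L, tolerance = 1e-12) {
  stopifnot(is.numeric(seed), length(seed) == 1, max_sweeps >= 1,
            tolerance >= 0)
  structure(list(seed = as.integer(seed), max_sweeps = as.integer(max_sweeps),
                 tolerance = tolerance),
            class = "fluenet_search_params")
}

#' Estimate a participant's semantic network (MAP search)
#'
#' Starting from the consecutive-adjacency initialization
#' ([build_init_network()]), the search repeatedly sweeps all single-edge
#' toggles over the participant vocabulary in seeded-random order, accepting
#' a toggle only if it strictly improves the log posterior by more than the
#' tolerance, and stops after a full acceptance-free sweep (or `max_sweeps`).
#' The returned network's log posterior is never below the initialization's.
#'
#' @param lists List of character vectors: one participant's cleaned fluency
#'   lists (nonempty).
#' @param prior A [prior_spec()] object.
#' @param params A [search_params()] object.
#' @return An object of class `fluenet_fit`: a list with elements `network`
#'   (igraph), `log_posterior`, `log_likelihood`, `log_prior`, `sweeps`,
#'   `accepted` (number of accepted toggles), `trace` (log posterior after
#'   each sweep), `converged`, `vocab`, and `params`.
#' @export
estimate_network <- function(lists, prior, params) {
  stopifnot(inherits(prior, "fluenet_prior"),
            inherits(params, "fluenet_search_params"))
  lists <- lists[lengths(lists) > 0]
  if (length(lists) == 0) stop("no nonempty lists to fit", call. = FALSE)
  init <- build_init_network(lists)
  vocab <- igraph::V(init)$name
  adj <- adjacency_over_vocab(init, vocab)
  pmat <- prior_probability_matrix(vocab, prior)
  diag(pmat) <- 0.5  # unused by the C++ core; avoid NA propagation
  idx_lists <- purrr::map(lists, function(it) match(it, vocab) - 1L)
  res <- withr::with_seed(params$seed, {
    cpp_uinvite_search(adj, idx_lists, log(pmat), log1p(-pmat),
                       params$max_sweeps, params$tolerance)
  })
  network <- graph_from_adjacency(res$adj, vocab)
  structure(list(network = network,
                 log_posterior = res$log_posterior,
                 log_likelihood = res$log_likelihood,
                 log_prior = res$log_prior,
                 sweeps = res$sweeps,
                 accepted = res$accepted,
                 trace = res$trace,
                 converged = res$converged,
                 vocab = vocab,
                 params = params),
            class = "fluenet_fit")
}

#' @export
print.fluenet_fit <- function(x, ...) {
  cat("Semantic network MAP fit\n")
  cat("  nodes:", length(x$vocab),
      " edges:", igraph::ecount(x$network), "\n")
  cat("  log posterior:", format(x$log_posterior, digits = 6),
      " (likelihood", format(x$log_likelihood, digits = 6),
      "+ prior", format(x$log_prior, digits = 6), ")\n")
  cat("  sweeps:", x$sweeps, " accepted toggles:", x$accepted,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @rdname estimate_network
#' @param x A `fluenet_fit` object.
#' @param ... Unused.
#' @export
tidy.fluenet_fit <- function(x, ...) {
  el <- igraph::as_edgelist(x$network)
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @rdname estimate_network
#' @export
glance.fluenet_fit <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$vocab),
                 n_edges = igraph::ecount(x$network),
                 log_posterior = x$log_posterior,
                 log_likelihood = x$log_likelihood,
                 log_prior = x$log_prior,
                 sweeps = x$sweeps,
                 accepted = x$accepted,
                 converged = x$converged,
                 seed = x$params$seed)
}
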