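#' Largest connected component
#'
#' Induced subgraph on the largest connected component; ties are broken by
#' the component containing the lexicographically smallest node name.
#'
#' @param network Undirected igraph with named vertices (nonempty).
#' @return Undirected igraph.
#' @export
largest_component <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  comp <- igraph::components(network)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1) {
    # smallest name among members of each candidate component
    mins <- vapply(cand, function(ci) {
      min(igraph::V(network)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(mins)[1]]
  }
  igraph::induced_subgraph(network,
                           which(comp$membership == cand[1]))
}

#' Average shortest path length
#'
#' Unweighted breadth-first-search distances averaged over all unordered node
#' pairs. The input must be connected; callers measuring a possibly
#' disconnected network pass [largest_component()] output first.
#'
#' @param network Connected undirected igraph.
#' @return Mean shortest path length (`NaN` for a single-node graph).
#' @export
aspl <- function(network) {
  if (igraph::vcount(network) > 1 && !igraph::is_connected(network)) {
    stop("aspl requires a connected graph; reduce with largest_component() first",
         call. = FALSE)
  }
  igraph::mean_distance(network, directed = FALSE)
}

#' Average local clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient (triangles through the
#' node divided by the number of pairs of its neighbors); nodes of degree
#' below 2 contribute 0. This is the Watts-Strogatz convention dominant in
#' the semantic-network literature; set `variant = "transitivity"` for the
#' global triangle density instead.
#'
#' @param network Undirected igraph with at least one node.
#' @param variant `"local_average"` (default) or `"transitivity"`.
#' @return Coefficient in \[0, 1\].
#' @export
avg_clustering <- function(network, variant = c("local_average", "transitivity")) {
  variant <- match.arg(variant)
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  if (variant == "transitivity") {
    out <- igraph::transitivity(network, type = "global")
    return(ifelse(is.nan(out), 0, out))
  }
  out <- igraph::transitivity(network, type = "localaverage", isolates = "zero")
  ifelse(is.nan(out), 0, out)
}

#' Best-found optimal modularity
#'
#' Seeded multi-restart greedy modularity maximization: each restart runs
#' multilevel (Louvain) community detection on a random vertex relabeling,
#' and the best Newman-Girvan modularity over restarts (and over the trivial
#' single-community partition, which scores 0) is returned.
#'
#' @param network Undirected igraph with at least one edge.
#' @param restarts Number of seeded restarts.
#' @param seed Integer seed; the result is deterministic given
#'   (`seed`, `restarts`).
#' @return List with `modularity` (best Qmod) and `membership` (named integer
#'   vector, the best partition).
#' @export
modularity_best <- function(network, restarts = 10, seed = 1) {
  if (igraph::ecount(network) == 0) {
    stop("modularity is undefined for an edgeless graph", call. = FALSE)
  }
  n <- igraph::vcount(network)
  withr::with_seed(as.integer(seed), {
    best_q <- 0  # single-community partition scores 0 and is always available
    best_m <- setNames(rep(1L, n), igraph::V(network)$name)
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(network, perm)
      cl <- igraph::cluster_louvain(gp)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        mem <- igraph::membership(cl)
        best_m <- setNames(as.integer(mem[igraph::V(gp)$name]),
                           igraph::V(gp)$name)[igraph::V(network)$name]
      }
    }
    list(modularity = best_q, membership = best_m)
  })
}

#' Small-world index (sigma)
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, where `C_rand` and `L_rand` are the
#' means of the average local clustering and ASPL over `n_random` G(n, m)
#' Erdos-Renyi graphs with the observed node and edge counts (per replicate,
#' the largest component is used if the draw is disconnected). Replicates
#' with zero clustering (sigma's denominator would be degenerate) are
#' redrawn up to a retry cap. Deterministic given the seed.
#'
#' @param network Connected undirected igraph with at least 4 nodes and
#'   3 edges (callers pass [largest_component()] output).
#' @param n_random Number of null-model replicates.
#' @param seed Integer seed.
#' @param clustering_variant Passed to [avg_clustering()].
#' @param max_retries Total redraw budget across replicates.
#' @return Sigma (dimensionless; > 1 indicates small-world structure).
#' @export
small_world_sigma <- function(network, n_random = 100, seed = 1,
                              clustering_variant = "local_average",
                              max_retries = 100 * n_random) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (n < 4 || m < 3) {
    stop("small_world_sigma needs >= 4 nodes and >= 3 edges (got ", n,
         " nodes, ", m, " edges)", call. = FALSE)
  }
  C_obs <- avg_clustering(network, clustering_variant)
  L_obs <- aspl(network)
  withr::with_seed(as.integer(seed), {
    C_rand <- numeric(n_random)
    L_rand <- numeric(n_random)
    retries <- 0
    for (r in seq_len(n_random)) {
      repeat {
        g <- igraph::sample_gnm(n, m)
        g <- largest_component(igraph::set_vertex_attr(
          g, "name", value = as.character(seq_len(n))))
        cr <- avg_clustering(g, clustering_variant)
        if (cr > 0) {
          C_rand[r] <- cr
          L_rand[r] <- aspl(g)
          break
        }
        retries <- retries + 1
        if (retries > max_retries) {
          stop("null-model retry cap exhausted: G(", n, ", ", m,
               ") draws are persistently triangle-free", call. = FALSE)
        }
      }
    }
    (C_obs / mean(C_rand)) / (L_obs / mean(L_rand))
  })
}

#' All network metrics for one semantic network
#'
#' ASPL and the small-world index are computed on the largest component;
#' clustering and modularity on the full graph; counts on the full graph.
#' The small-world index is `NA` when the largest component is too small for
#' a meaningful null model (fewer than 4 nodes or 3 edges).
#'
#' @param network Undirected igraph with named vertices.
#' @param restarts Modularity restarts.
#' @param n_random Small-world null-model replicates.
#' @param seed Integer seed for modularity restarts and the null model.
#' @param clustering_variant Passed to [avg_clustering()].
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_components`, `lcc_size`,
#'   `aspl`, `clustering`, `modularity`, `small_world`.
#' @export
network_metrics <- function(network, restarts = 10, n_random = 100, seed = 1,
                            clustering_variant = "local_average") {
  lcc <- largest_component(network)
  sw <- if (igraph::vcount(lcc) >= 4 && igraph::ecount(lcc) >= 3) {
    small_world_sigma(lcc, n_random = n_random, seed = seed,
                      clustering_variant = clustering_variant)
  } else {
    NA_real_
  }
  mod <- if (igraph::ecount(network) > 0) {
    modularity_best(network, restarts = restarts, seed = seed)$modularity
  } else {
    NA_real_
  }
  tibble::tibble(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    n_components = igraph::components(network)$no,
    lcc_size = igraph::vcount(lcc),
    aspl = aspl(lcc),
    clustering = avg_clustering(network, clustering_variant),
    modularity = mod,
    small_world = sw
  )
}

#' Metrics table for a set of networks
#'
#' @param networks Named list of igraph objects (names are participant ids).
#' @param ... Passed to [network_metrics()].
#' @return Tibble with one row per network, first column `id`, of class
#'   `fluenet_metrics`.
#' @export
metrics_table <- function(networks, ...) {
  out <- purrr::imap(networks, function(g, nm) {
    dplyr::bind_cols(tibble::tibble(id = nm), network_metrics(g, ...))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("fluenet_metrics", class(out))
  out
}

#' @export
autoplot.fluenet_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[c("id", "aspl", "clustering", "modularity", "small_world")],
    -"id", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "participants",
                  title = "Distribution of semantic-network metrics")
}
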