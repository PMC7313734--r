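#' Cohort configuration for the synthetic-data generator
#'
#' Defaults reproduce the structure of the study the pipeline is designed
#' for: a 92-participant cohort of monolinguals (n = 25), English-Spanish
#' bilinguals (n = 13), Spanish-English bilinguals (n = 28) and proficiency
#' "unclassified" participants (n = 26, part of the correlation sample but
#' not of the labeled group comparisons), three animal-fluency lists per
#' participant, group list-length means of 42.1 (ES, first-language testing)
#' and 33.3 (SE, second-language testing) with SD 6.5, creativity means of
#' 14.5 (ES) and 16.7 (SE) with SD 6.5, a sub-0.6% intrusion rate, and an
#' all-null effect map except for a 0.185 intelligence-creativity
#' correlation. Monolingual/unclassified list-length (40) and creativity
#' (15.6) means are not pinned by the study summaries and sit at
#' native-language-like values.
#'
#' @param groups Tibble with columns `group`, `n`, `list_length_mean`,
#'   `list_length_sd`, `creativity_mean`, `creativity_sd`.
#' @param lists_per_participant Lists per participant.
#' @param intrusion_rate,perseveration_rate Per-response injection rates for
#'   out-of-category and repeated responses in the raw lists.
#' @param target_cors Named numeric vector of target correlations between
#'   creativity and each of `intelligence`, `mean_items`, `aspl`,
#'   `clustering`, `modularity`, `small_world` (|rho| < 1).
#' @param intelligence_mean,intelligence_sd Intelligence score distribution
#'   (12-item matrix-reasoning-like scale, clipped to 0..12).
#' @param reference_n_nodes,reference_model,reference_params Reference
#'   network used both as the shared semantic backbone and as the prior
#'   anchor; see [make_reference_network()].
#' @param p_drop,p_add Participant-level deviation from the reference: each
#'   reference edge is dropped with `p_drop`, each non-edge added with
#'   `p_add` ([perturb_network()]).
#' @param metric_restarts,metric_n_random Settings used when computing the
#'   realized ground-truth network metrics the copula conditions on.
#' @param master_seed Integer master seed; the whole cohort is reproducible
#'   from it.
#' @return An object of class `fluenet_cohort_config`.
#' @export
cohort_config <- function(
    groups = tibble::tibble(
      group = c("monolingual", "ES", "SE", "unclassified"),
      n = c(25L, 13L, 28L, 26L),
      list_length_mean = c(40, 42.1, 33.3, 40),
      list_length_sd = 6.5,
      creativity_mean = c(15.6, 14.5, 16.7, 15.6),
      creativity_sd = 6.5),
    lists_per_participant = 3L,
    intrusion_rate = 0.005,
    perseveration_rate = 0.01,
    target_cors = c(intelligence = 0.185, mean_items = 0, aspl = 0,
                    clustering = 0, modularity = 0, small_world = 0),
    intelligence_mean = 9, intelligence_sd = 2.5,
    reference_n_nodes = 60L,
    reference_model = "ring_lattice_rewired",
    reference_params = list(nei = 2, p_rewire = 0.1),
    p_drop = 0.15, p_add = 0.005,
    metric_restarts = 5L, metric_n_random = 30L,
    master_seed = 1L) {
  stopifnot(all(groups$n >= 1), lists_per_participant >= 1,
            intrusion_rate >= 0, intrusion_rate < 1,
            perseveration_rate >= 0, perseveration_rate < 1,
            all(abs(target_cors) < 1))
  needed <- c("intelligence", "mean_items", "aspl", "clustering",
              "modularity", "small_world")
  miss <- setdiff(needed, names(target_cors))
  if (length(miss) > 0) {
    target_cors[miss] <- 0
  }
  structure(list(groups = groups,
                 lists_per_participant = as.integer(lists_per_participant),
                 intrusion_rate = intrusion_rate,
                 perseveration_rate = perseveration_rate,
                 target_cors = target_cors[needed],
                 intelligence_mean = intelligence_mean,
                 intelligence_sd = intelligence_sd,
                 reference_n_nodes = as.integer(reference_n_nodes),
                 reference_model = reference_model,
                 reference_params = reference_params,
                 p_drop = p_drop, p_add = p_add,
                 metric_restarts = as.integer(metric_restarts),
                 metric_n_random = as.integer(metric_n_random),
                 master_seed = as.integer(master_seed)),
            class = "fluenet_cohort_config")
}

#' Generate a labeled reference network
#'
#' Builds a connected, labeled network over the bundled animal lexicon to
#' play the role of a group-level free-association network. Models:
#' `"random"` (G(n, m)), `"ring_lattice_rewired"` (Watts-Strogatz-style small
#' world), `"communities"` (stochastic block model). Disconnected draws are
#' repaired by adding one bridge edge per missing join between the two
#' lexicographically smallest nodes of distinct components; repairs are
#' recorded in the graph attribute `repaired_edges`.
#'
#' @param n_nodes Number of nodes (at most the bundled lexicon size, unless
#'   `labels` is supplied).
#' @param model One of `"random"`, `"ring_lattice_rewired"`, `"communities"`.
#' @param params Model parameters: `m` (random); `nei`, `p_rewire`
#'   (ring_lattice_rewired); `block_sizes`, `p_within`, `p_between`
#'   (communities).
#' @param seed Integer seed (deterministic per seed).
#' @param labels Optional character vector of node labels.
#' @return Connected undirected igraph with named vertices.
#' @export
make_reference_network <- function(n_nodes, model = c("ring_lattice_rewired",
                                                      "random", "communities"),
                                   params = list(), seed = 1,
                                   labels = NULL) {
  model <- match.arg(model)
  if (is.null(labels)) {
    lex <- read_lexicon()
    if (n_nodes > length(lex)) {
      stop("n_nodes exceeds the bundled lexicon size (", length(lex), ")",
           call. = FALSE)
    }
    labels <- sort(lex)[seq_len(n_nodes)]
  }
  stopifnot(length(labels) == n_nodes)
  withr::with_seed(as.integer(seed), {
    g <- switch(model,
      random = igraph::sample_gnm(n_nodes, params$m %||% (2 * n_nodes)),
      ring_lattice_rewired = igraph::sample_smallworld(
        1, n_nodes, params$nei %||% 2, params$p_rewire %||% 0.1),
      communities = {
        bs <- params$block_sizes %||% rep(ceiling(n_nodes / 2), 2)
        bs[length(bs)] <- n_nodes - sum(bs[-length(bs)])
        k <- length(bs)
        pm <- matrix(params$p_between %||% 0.02, k, k)
        diag(pm) <- params$p_within %||% 0.25
        igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = bs)
      })
    g <- igraph::simplify(igraph::set_vertex_attr(g, "name", value = labels))
    connect_components(g)
  })
}

# join components with bridge edges between their smallest-named members
connect_components <- function(g) {
  repaired <- character(0)
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1) break
    mins <- vapply(seq_len(comp$no), function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    ord <- order(mins)
    a <- mins[ord[1]]; b <- mins[ord[2]]
    g <- igraph::add_edges(g, c(a, b))
    repaired <- c(repaired, paste(a, b, sep = "--"))
  }
  igraph::set_graph_attr(g, "repaired_edges", repaired)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Perturb a reference network
#'
#' Each reference edge is kept with probability `1 - p_drop`; each non-edge
#' is added with probability `p_add`. Models participant-level deviation from
#' a shared semantic backbone.
#'
#' @param reference Undirected igraph with named vertices.
#' @param p_drop,p_add Probabilities in \[0, 1).
#' @param seed Optional integer seed.
#' @return Undirected igraph on the same vertex set.
#' @export
perturb_network <- function(reference, p_drop, p_add, seed = NULL) {
  stopifnot(p_drop >= 0, p_drop <= 1, p_add >= 0, p_add < 1)
  run <- function() {
    vocab <- igraph::V(reference)$name
    adj <- adjacency_over_vocab(reference, vocab)
    ut <- which(upper.tri(adj), arr.ind = TRUE)
    is_edge <- adj[ut] == 1L
    keep <- is_edge & (runif(nrow(ut)) >= p_drop)
    add <- !is_edge & (runif(nrow(ut)) < p_add)
    newadj <- matrix(0L, nrow(adj), ncol(adj))
    sel <- ut[keep | add, , drop = FALSE]
    newadj[sel] <- 1L
    newadj <- newadj + t(newadj)
    graph_from_adjacency(newadj, vocab)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# one-time precomputation shared across simulated walks on the same network
walker_state <- function(network) {
  nodes <- igraph::V(network)$name
  deg <- unname(igraph::degree(network))
  if (sum(deg) == 0) stop("network has no edges", call. = FALSE)
  comp <- igraph::components(network)
  list(nodes = nodes, deg = deg,
       nbrs = lapply(igraph::adjacent_vertices(network, nodes), as.integer),
       comp_size = comp$csize[comp$membership])
}

walk_once <- function(st, length) {
  start <- sample.int(base::length(st$nodes), 1, prob = st$deg)
  if (st$comp_size[start] < length) {
    stop("component containing the start node has fewer than ", length,
         " nodes", call. = FALSE)
  }
  visited <- logical(base::length(st$nodes))
  visited[start] <- TRUE
  out <- integer(length)
  out[1] <- start
  emitted <- 1L
  cur <- start
  while (emitted < length) {
    nb <- st$nbrs[[cur]]
    cur <- if (base::length(nb) == 1L) nb else nb[sample.int(base::length(nb), 1)]
    if (!visited[cur]) {
      visited[cur] <- TRUE
      emitted <- emitted + 1L
      out[emitted] <- cur
    }
  }
  st$nodes[out]
}

#' Simulate censored-random-walk fluency lists
#'
#' The first item is drawn with probability proportional to degree; each
#' subsequent step moves uniformly over neighbors; revisits are censored, and
#' the list is the order of first visits, truncated at the requested number
#' of items. `simulate_list()` draws one list; `simulate_lists()` draws many
#' under a single seed with shared precomputation.
#'
#' @param network Undirected igraph with named vertices and at least 1 edge.
#' @param length Number of distinct items to emit; the connected component of
#'   the start node must have at least this many nodes.
#' @param seed Optional integer seed.
#' @return For `simulate_list()`, a character vector of `length` items; for
#'   `simulate_lists()`, a list of character vectors (one per entry of
#'   `lengths`).
#' @export
simulate_list <- function(network, length, seed = NULL) {
  st <- walker_state(network)
  if (is.null(seed)) walk_once(st, length)
  else withr::with_seed(as.integer(seed), walk_once(st, length))
}

#' @rdname simulate_list
#' @param lengths Integer vector of list lengths, one simulated list each.
#' @export
simulate_lists <- function(network, lengths, seed = NULL) {
  st <- walker_state(network)
  run <- function() lapply(lengths, function(L) walk_once(st, L))
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# deterministic per-participant seed derived from the master seed (no RNG)
participant_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + index * 104729) %% 2147483587) + 1L
}

# out-of-category token pool for injected intrusions
intrusion_pool <- c("house", "unicorn", "chair", "table", "dragon", "rock",
                    "car", "tree", "phoenix", "lamp", "mermaid", "boat")

# inject intrusions/perseverations into a clean list; returns raw item vector
inject_noise <- function(items, intrusion_rate, perseveration_rate) {
  out <- character(0)
  for (k in seq_along(items)) {
    out <- c(out, items[k])
    if (runif(1) < perseveration_rate && k >= 2) {
      out <- c(out, items[sample.int(k, 1)])
    }
    if (runif(1) < intrusion_rate) {
      out <- c(out, intrusion_pool[sample.int(length(intrusion_pool), 1)])
    }
  }
  out
}

#' Simulate a full cohort
#'
#' For each participant: a ground-truth semantic network (largest component
#' of a perturbed copy of the shared reference), censored-random-walk fluency
#' lists with group-specific lengths and injected intrusions/perseverations,
#' and creativity and intelligence scores drawn from a Gaussian copula that
#' achieves the configured target correlations with the participant's
#' realized mean list length and ground-truth network statistics.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `fluenet_cohort`:
#'   \describe{
#'     \item{fluency}{raw fluency tibble (`id`, `listnum`, `position`,
#'       `item`), noise included.}
#'     \item{scores}{tibble `id`, `group`, `creativity`, `intelligence`.}
#'     \item{truth}{named list of ground-truth igraph networks.}
#'     \item{truth_metrics}{tibble of realized ground-truth covariates.}
#'     \item{reference}{the shared reference network (prior anchor).}
#'     \item{seeds}{tibble of per-participant seeds.}
#'     \item{config}{the configuration, echoed.}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "fluenet_cohort_config"))
  reference <- make_reference_network(config$reference_n_nodes,
                                      config$reference_model,
                                      config$reference_params,
                                      seed = config$master_seed)
  grp <- config$groups
  roster <- tibble::tibble(
    group = rep(grp$group, grp$n),
    list_length_mean = rep(grp$list_length_mean, grp$n),
    list_length_sd = rep(grp$list_length_sd, grp$n),
    creativity_mean = rep(grp$creativity_mean, grp$n),
    creativity_sd = rep(grp$creativity_sd, grp$n))
  n_part <- nrow(roster)
  roster$id <- sprintf("p%03d", seq_len(n_part))
  roster$seed <- participant_seed(config$master_seed, seq_len(n_part))

  flu_rows <- vector("list", n_part)
  truth <- vector("list", n_part)
  tm_rows <- vector("list", n_part)
  for (px in seq_len(n_part)) {
    rec <- withr::with_seed(roster$seed[px], {
      net <- largest_component(
        perturb_network(reference, config$p_drop, config$p_add))
      lcc_n <- igraph::vcount(net)
      lens <- pmin(pmax(round(rnorm(config$lists_per_participant,
                                    roster$list_length_mean[px],
                                    roster$list_length_sd[px])), 5L), lcc_n)
      lists <- simulate_lists(net, lens)
      raw <- lapply(lists, function(it) {
        inject_noise(it, config$intrusion_rate, config$perseveration_rate)
      })
      list(net = net, lists = lists, raw = raw)
    })
    truth[[px]] <- rec$net
    flu_rows[[px]] <- purrr::imap(rec$raw, function(items, ln) {
      tibble::tibble(id = roster$id[px], listnum = ln - 1L,
                     position = seq_along(items) - 1L, item = items)
    }) |> dplyr::bind_rows()
    met <- network_metrics(rec$net, restarts = config$metric_restarts,
                           n_random = config$metric_n_random,
                           seed = roster$seed[px])
    tm_rows[[px]] <- dplyr::bind_cols(
      tibble::tibble(id = roster$id[px],
                     mean_items = mean(lengths(rec$lists))),
      met[, c("aspl", "clustering", "modularity", "small_world")])
  }
  names(truth) <- roster$id
  truth_metrics <- dplyr::bind_rows(tm_rows)

  scores <- withr::with_seed(config$master_seed + 1L, {
    copula_scores(roster, truth_metrics, config)
  })

  structure(list(fluency = dplyr::bind_rows(flu_rows),
                 scores = scores,
                 truth = truth,
                 truth_metrics = truth_metrics,
                 reference = reference,
                 seeds = roster[, c("id", "group", "seed")],
                 config = config),
            class = "fluenet_cohort")
}

# Gaussian copula: draw a latent creativity normal whose pooled correlation
# with the normal scores of each realized covariate hits the configured
# target. Group creativity means shift the final score, and those offsets
# themselves covary with covariates such as mean list length (groups differ
# in fluency), so the latent loadings are solved with the offset covariance
# taken out; a short fixed-point handles the offset-dependent total variance.
copula_scores <- function(roster, truth_metrics, config) {
  covars <- c("mean_items", "aspl", "clustering", "modularity", "small_world")
  n <- nrow(roster)
  Z <- vapply(covars, function(v) {
    x <- truth_metrics[[v]]
    if (anyNA(x) || sd(x) == 0) return(rnorm(n))  # degenerate covariate
    qnorm(rank(x, ties.method = "average") / (n + 1))
  }, numeric(n))
  Z <- scale(Z)
  Rzz <- cor(Z)
  rho <- config$target_cors[covars]
  sdev <- roster$creativity_sd[1]
  mu <- roster$creativity_mean
  M <- mu - mean(mu)
  s_mu <- sqrt(mean(M^2))
  b <- as.numeric(crossprod(Z, M) / n)  # cov(group offset, covariate scores)
  s_tot <- sqrt(s_mu^2 + sdev^2)
  a <- rep(0, length(covars))
  for (it in 1:5) {
    target_cov <- (rho * s_tot - b) / sdev
    a <- tryCatch(solve(Rzz, target_cov), error = function(e) {
      stop("covariate correlation matrix is singular; target correlations infeasible",
           call. = FALSE)
    })
    s_tot <- sqrt(s_mu^2 + sdev^2 + 2 * sdev * sum(b * a))
  }
  res_var <- 1 - as.numeric(t(a) %*% Rzz %*% a)
  if (res_var < 0) {
    stop("target correlations are infeasible (implied residual variance < 0)",
         call. = FALSE)
  }
  C <- as.numeric(Z %*% a) + sqrt(res_var) * rnorm(n)
  latent_total <- (M + sdev * C) / s_tot
  r_ci <- config$target_cors[["intelligence"]]
  I <- r_ci * latent_total + sqrt(1 - r_ci^2) * rnorm(n)
  creativity <- pmax(round(mu + sdev * C), 0)
  intelligence <- pmin(pmax(round(config$intelligence_mean +
                                    config$intelligence_sd * I), 0), 12)
  tibble::tibble(id = roster$id, group = roster$group,
                 creativity = as.integer(creativity),
                 intelligence = as.integer(intelligence))
}

#' Write a cohort to disk
#'
#' Writes the fluency CSV, score CSV, per-participant ground-truth edge
#' lists, the reference network, and a JSON registry mapping participant ids
#' to truth files and seeds.
#'
#' @param cohort A `fluenet_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_fluency_table(cohort$fluency, file.path(dir, "fluency.csv"))
  readr::write_csv(cohort$scores, file.path(dir, "scores.csv"), progress = FALSE)
  write_edge_list(cohort$reference, file.path(dir, "reference.tsv"))
  files <- purrr::imap_chr(cohort$truth, function(g, id) {
    f <- file.path("truth", paste0(id, ".tsv"))
    write_edge_list(g, file.path(dir, f))
    f
  })
  registry <- purrr::map2(files, cohort$seeds$seed,
                          function(f, s) list(truth_file = f, seed = s))
  names(registry) <- cohort$seeds$id
  jsonlite::write_json(list(master_seed = cohort$config$master_seed,
                            participants = registry),
                       file.path(dir, "registry.json"), auto_unbox = TRUE)
  invisible(dir)
}
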