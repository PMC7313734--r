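#' Pipeline run configuration
#'
#' A run takes a cohort either in memory (`cohort`) or from files (`paths`),
#' cleans the fluency lists, estimates one semantic network per participant,
#' computes the network metrics table, and runs the Bayesian test battery.
#'
#' @param cohort Optional `fluenet_cohort` (in-memory input).
#' @param paths Optional named list with `fluency`, `scores`, `lexicon`,
#'   `reference` file paths (file input; `lexicon` defaults to the bundled
#'   animal lexicon).
#' @param out_dir Output directory; `NULL` to keep results in memory only.
#' @param prior A [prior_spec()] object, or `NULL` to anchor the prior on the
#'   cohort/reference network supplied.
#' @param p_present,p_absent,p_unknown Edge-prior probabilities used when
#'   `prior` is `NULL`.
#' @param max_sweeps,tolerance Search parameters (see [search_params()]).
#' @param restarts,n_random,clustering_variant Metric settings
#'   (see [network_metrics()]).
#' @param battery Logical: run the Bayesian test battery.
#' @param directional_predictions Named directions used for the directional
#'   correlation priors, from the prior literature this design responds to:
#'   lower ASPL, higher clustering, lower modularity, lower small-world index
#'   and more items for more creative people, and a positive
#'   intelligence-creativity correlation.
#' @param resume Reuse stage outputs already present in `out_dir` when the
#'   stage inputs are unchanged (content-hash check).
#' @param master_seed Integer seed: drives per-participant search seeds and
#'   metric seeds.
#' @return An object of class `fluenet_run_config`.
#' @export
run_config <- function(cohort = NULL, paths = NULL, out_dir = NULL,
                       prior = NULL, p_present = 2 / 3, p_absent = 2 / 5,
                       p_unknown = 1 / 2, max_sweeps = 100L,
                       tolerance = 1e-12, restarts = 10L, n_random = 100L,
                       clustering_variant = "local_average", battery = TRUE,
                       directional_predictions = c(
                         aspl = "negative", clustering = "positive",
                         modularity = "negative", small_world = "negative",
                         mean_items = "positive", intelligence = "positive"),
                       resume = TRUE, master_seed = 1L) {
  if (is.null(cohort) && is.null(paths)) {
    stop("supply either `cohort` or `paths`", call. = FALSE)
  }
  structure(list(cohort = cohort, paths = paths, out_dir = out_dir,
                 prior = prior, p_present = p_present, p_absent = p_absent,
                 p_unknown = p_unknown, max_sweeps = as.integer(max_sweeps),
                 tolerance = tolerance, restarts = as.integer(restarts),
                 n_random = as.integer(n_random),
                 clustering_variant = clustering_variant,
                 battery = isTRUE(battery),
                 directional_predictions = directional_predictions,
                 resume = isTRUE(resume),
                 master_seed = as.integer(master_seed)),
            class = "fluenet_run_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    list(fluency = config$cohort$fluency,
         scores = config$cohort$scores,
         lexicon = read_lexicon(),
         reference = config$cohort$reference)
  } else {
    p <- config$paths
    list(fluency = read_fluency_table(p$fluency),
         scores = readr::read_csv(p$scores, col_types = readr::cols(
           id = readr::col_character(), group = readr::col_character(),
           .default = readr::col_double()), progress = FALSE),
         lexicon = read_lexicon(p$lexicon %||% fluenet_file("animals.txt")),
         reference = read_edge_list(p$reference))
  }
}

content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stage_cached <- function(out_dir, stage, hash) {
  if (is.null(out_dir)) return(FALSE)
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  man <- jsonlite::read_json(mf)
  !is.null(man$stages[[stage]]) && identical(man$stages[[stage]]$hash, hash) &&
    all(file.exists(file.path(out_dir, unlist(man$stages[[stage]]$files))))
}

record_stage <- function(out_dir, stage, hash, files) {
  if (is.null(out_dir)) return(invisible(NULL))
  mf <- file.path(out_dir, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::read_json(mf) else list(stages = list())
  man$stages[[stage]] <- list(hash = hash, files = as.list(files))
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Stages run in order clean -> estimate -> metrics -> tests, each stage's
#' outputs written (when `out_dir` is set) before the next starts. A rerun
#' with an identical configuration reuses stage outputs whose inputs are
#' unchanged (content-hash check) when `resume = TRUE`. Participants whose
#' estimation fails are excluded from the metric correlations with a logged
#' reason, never silently.
#'
#' @param config A [run_config()] object.
#' @return A `fluenet_results` bundle: `networks` (named list of igraph),
#'   `fits` (glance rows per participant), `metrics` (metrics table joined
#'   with scores and mean items), `tests` (tidied Bayes-factor report, or
#'   `NULL` when the battery is off), `cleaning` (report), `excluded`
#'   (tibble id/reason), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fluenet_run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- pipeline_inputs(config)
  prior <- config$prior %||%
    prior_spec(inputs$reference, config$p_present, config$p_absent,
               config$p_unknown)

  ## stage: clean -----------------------------------------------------------
  cleaned <- clean_lists(inputs$fluency, inputs$lexicon)
  counts <- fluency_counts(cleaned$lists)
  if (!is.null(out_dir)) {
    write_fluency_table(cleaned$lists, file.path(out_dir, "cleaned.csv"))
    readr::write_csv(cleaned$report, file.path(out_dir, "cleaning_report.csv"),
                     progress = FALSE)
  }

  ## stage: estimate --------------------------------------------------------
  ids <- unique(cleaned$lists$id)
  est_hash <- content_hash(list(cleaned$lists, prior$p_present, prior$p_absent,
                                prior$p_unknown,
                                if (!is.null(prior$reference))
                                  sort(apply(igraph::as_edgelist(prior$reference), 1,
                                             function(r) paste(sort(r), collapse = "|"))),
                                config$max_sweeps, config$tolerance,
                                config$master_seed))
  net_dir <- if (!is.null(out_dir)) file.path(out_dir, "networks")
  networks <- list()
  fits <- list()
  excluded <- tibble::tibble(id = character(0), reason = character(0))
  use_cache <- config$resume && stage_cached(out_dir, "estimate", est_hash)
  if (use_cache) {
    for (pid in ids) {
      networks[[pid]] <- read_edge_list(file.path(net_dir, paste0(pid, ".tsv")))
    }
    fits <- readr::read_csv(file.path(out_dir, "fits.csv"),
                            col_types = readr::cols(id = readr::col_character(),
                                                    .default = readr::col_guess()),
                            progress = FALSE)
  } else {
    if (!is.null(net_dir)) dir.create(net_dir, showWarnings = FALSE)
    for (px in seq_along(ids)) {
      pid <- ids[px]
      lists <- fluency_list_items(cleaned$lists, pid)
      fit <- tryCatch(
        estimate_network(lists, prior,
                         search_params(seed = participant_seed(
                           config$master_seed, px))),
        error = function(e) e)
      if (inherits(fit, "error")) {
        message("estimation failed for ", pid, ": ", conditionMessage(fit))
        excluded <- dplyr::add_row(excluded, id = pid,
                                   reason = conditionMessage(fit))
        next
      }
      networks[[pid]] <- fit$network
      fits[[pid]] <- dplyr::bind_cols(tibble::tibble(id = pid), glance(fit))
      if (!is.null(net_dir)) {
        write_edge_list(fit$network, file.path(net_dir, paste0(pid, ".tsv")))
      }
    }
    fits <- dplyr::bind_rows(fits)
    if (!is.null(out_dir)) {
      readr::write_csv(fits, file.path(out_dir, "fits.csv"), progress = FALSE)
      record_stage(out_dir, "estimate", est_hash,
                   c(file.path("networks", paste0(names(networks), ".tsv")),
                     "fits.csv"))
    }
  }

  ## stage: metrics ---------------------------------------------------------
  met_hash <- content_hash(list(est_hash, config$restarts, config$n_random,
                                config$clustering_variant))
  metrics_path <- if (!is.null(out_dir)) file.path(out_dir, "metrics.csv")
  if (config$resume && stage_cached(out_dir, "metrics", met_hash)) {
    metrics <- readr::read_csv(metrics_path, col_types = readr::cols(
      id = readr::col_character(), group = readr::col_character(),
      .default = readr::col_double()), progress = FALSE)
  } else {
    seeds <- participant_seed(config$master_seed + 7L,
                              seq_along(networks))
    metrics <- purrr::imap(networks, function(g, pid) {
      dplyr::bind_cols(
        tibble::tibble(id = pid),
        network_metrics(g, restarts = config$restarts,
                        n_random = config$n_random,
                        seed = seeds[match(pid, names(networks))],
                        clustering_variant = config$clustering_variant))
    }) |> dplyr::bind_rows()
    metrics <- metrics |>
      dplyr::left_join(counts, by = "id") |>
      dplyr::left_join(inputs$scores, by = "id")
    if (!is.null(out_dir)) {
      readr::write_csv(metrics, metrics_path, progress = FALSE)
      record_stage(out_dir, "metrics", met_hash, "metrics.csv")
    }
  }

  ## stage: tests -----------------------------------------------------------
  tests <- NULL
  if (config$battery) {
    tests <- test_battery(metrics, config$directional_predictions)
    if (!is.null(out_dir)) {
      write_bf_report(tests, file.path(out_dir, "test_report.csv"))
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(master_seed = config$master_seed,
           prior = list(p_present = prior$p_present, p_absent = prior$p_absent,
                        p_unknown = prior$p_unknown),
           search = list(max_sweeps = config$max_sweeps,
                         tolerance = config$tolerance),
           metrics = list(restarts = config$restarts,
                          n_random = config$n_random,
                          clustering_variant = config$clustering_variant),
           n_participants = length(networks),
           excluded = excluded$id),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(networks = networks, fits = fits, metrics = metrics,
                 tests = tests, cleaning = cleaned$report,
                 excluded = excluded, config = config),
            class = "fluenet_results")
}

group_ttest_row <- function(scores, value, g1, g2, test_name, side = NULL) {
  x1 <- scores[[value]][scores$.grp == g1]
  x2 <- scores[[value]][scores$.grp == g2]
  summ <- summary_to_t(mean(x1), sd(x1), length(x1), mean(x2), sd(x2), length(x2))
  rows <- list(tidy(jzs_ttest_bf(summ, prior_settings(side = "two_sided"))))
  if (!is.null(side)) {
    rows <- c(rows, list(tidy(jzs_ttest_bf(summ, prior_settings(side = side)))))
  }
  dplyr::bind_rows(rows) |> dplyr::mutate(name = .env$test_name, .before = 1)
}

corr_bf_rows <- function(metrics, var, direction) {
  keep <- stats::complete.cases(metrics[, c("creativity", var)])
  r <- cor(metrics$creativity[keep], metrics[[var]][keep])
  summ <- corr_summary(r, sum(keep))
  two <- tidy(pearson_bf(summ, prior_settings(side = "two_sided")))
  dir <- tidy(pearson_bf(summ, prior_settings(side = direction)))
  dplyr::bind_rows(two, dir) |>
    dplyr::mutate(name = paste0("creativity_vs_", var), .before = 1)
}

# the study's test battery: group comparisons on creativity and fluency
# counts, plus creativity correlations with each network statistic,
# intelligence and mean items (two-sided and directional priors)
test_battery <- function(metrics, directions) {
  rows <- list()
  # group comparisons use only the proficiency-labeled groups; participants
  # outside the mono/bilingual criteria stay in the correlation sample
  s <- dplyr::filter(metrics, .data$group %in% c("monolingual", "ES", "SE"))
  if (all(c("SE", "ES") %in% s$group)) {
    s$.grp <- s$group
    rows <- c(rows,
      list(group_ttest_row(s, "creativity", "SE", "ES", "creativity_SE_vs_ES"),
           group_ttest_row(s, "mean_items", "SE", "ES", "fluency_SE_vs_ES")))
  }
  if ("monolingual" %in% s$group && any(s$group != "monolingual")) {
    s$.grp <- ifelse(s$group == "monolingual", "monolingual", "bilingual")
    rows <- c(rows, list(group_ttest_row(
      s, "creativity", "bilingual", "monolingual",
      "creativity_bilingual_vs_monolingual")))
    s$.grp <- ifelse(s$group == "SE", "non_native", "native")
    rows <- c(rows, list(group_ttest_row(
      s, "creativity", "native", "non_native",
      "creativity_native_vs_nonnative")))
  }
  for (v in c("aspl", "clustering", "modularity", "small_world",
              "mean_items", "intelligence")) {
    if (v %in% names(metrics)) {
      rows <- c(rows, list(corr_bf_rows(metrics, v, directions[[v]])))
    }
  }
  dplyr::bind_rows(rows)
}

#' Report table for a results bundle
#'
#' One row per hypothesis test, carrying the test inputs (t or r, sizes)
#' alongside BF10, BF01, the favored hypothesis and its Jeffreys label.
#'
#' @param bundle A `fluenet_results` object from [run_pipeline()].
#' @return Tibble (also the content written to `test_report.csv`).
#' @export
report_table <- function(bundle) {
  stopifnot(inherits(bundle, "fluenet_results"))
  if (is.null(bundle$tests)) {
    stop("the run was configured without the test battery", call. = FALSE)
  }
  bundle$tests
}

#' @export
print.fluenet_results <- function(x, ...) {
  cat("fluenet pipeline results:", length(x$networks), "participants\n")
  cat("  cleaning: ", x$cleaning$n_intrusions, " intrusions, ",
      x$cleaning$n_perseverations, " perseverations of ",
      x$cleaning$n_responses_total, " responses\n", sep = "")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded$id, collapse = ", "), "\n")
  }
  if (!is.null(x$tests)) {
    cat("  test battery:", nrow(x$tests), "rows\n")
  }
  invisible(x)
}

#' Forest-style plot of a Bayes-factor report
#'
#' @param rows Tidied test rows (see [report_table()]).
#' @return A ggplot object: log10 BF10 per test, shaded by Jeffreys label.
#' @export
plot_bf_report <- function(rows) {
  rows$test_id <- paste(rows$name, rows$side, sep = " / ")
  ggplot2::ggplot(rows, ggplot2::aes(x = log10(.data$bf10),
                                     y = .data$test_id,
                                     fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log10 BF10 (right favors H1)", y = NULL,
                  fill = "evidence")
}
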