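#' Read a fluency response table
#'
#' Reads a comma-separated fluency table with one row per produced response.
#' The file must have a header naming the columns `id`, `listnum`, `position`,
#' `item`. Item strings are preserved verbatim; normalization is a separate,
#' explicit step ([clean_lists()]).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `id` (character), `listnum` (integer),
#'   `position` (integer) and `item` (character).
#' @seealso [write_fluency_table()], [clean_lists()]
#' @export
read_fluency_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("id", "listnum", "position", "item")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("fluency table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::select(tab, dplyr::all_of(required))
  for (col in c("listnum", "position")) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) | x != floor(x) | x < 0)
    if (length(bad) > 0) {
      stop("non-integer ", col, " in fluency table row ", bad[1] + 1L,
           " (file ", path, ")", call. = FALSE)
    }
    tab[[col]] <- as.integer(x)
  }
  dup <- which(duplicated(tab[, c("id", "listnum", "position")]))
  if (length(dup) > 0) {
    stop("duplicate (id, listnum, position) in fluency table at row ",
         dup[1] + 1L, " (file ", path, ")", call. = FALSE)
  }
  validate_positions(tab)
  tab
}

# positions within each (id, listnum) must be consecutive from 0
validate_positions <- function(tab) {
  chk <- tab |>
    dplyr::group_by(.data$id, .data$listnum) |>
    dplyr::summarise(ok = identical(sort(.data$position),
                                    seq(0L, length(.data$position) - 1L)),
                     .groups = "drop")
  bad <- dplyr::filter(chk, !.data$ok)
  if (nrow(bad) > 0) {
    stop("positions not consecutive from 0 for participant ", bad$id[1],
         " list ", bad$listnum[1], call. = FALSE)
  }
  invisible(tab)
}

#' Write a fluency response table
#'
#' @param table A fluency table as returned by [read_fluency_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fluency_table <- function(table, path) {
  readr::write_csv(table[, c("id", "listnum", "position", "item")], path,
                   progress = FALSE)
  invisible(path)
}

#' Canonicalize a response string
#'
#' Lower-cases, strips leading/trailing whitespace, and collapses internal
#' runs of whitespace to single spaces. No spell correction or plural folding
#' is attempted; intrusion detection is purely lexicon-driven.
#'
#' @param raw Character vector of raw responses.
#' @return Character vector of canonical strings.
#' @examples
#' normalize_item(c(" Dog ", "polar  Bear"))
#' @export
normalize_item <- function(raw) {
  x <- tolower(trimws(raw))
  gsub("[[:space:]]+", " ", x)
}

#' Read a category lexicon
#'
#' Plain text, one item per line; blank lines and `#` comments are ignored.
#' Entries are normalized with [normalize_item()].
#'
#' @param path Path to the lexicon file. Defaults to the bundled toy animal
#'   lexicon.
#' @return Character vector of canonical category members.
#' @export
read_lexicon <- function(path = fluenet_file("animals.txt")) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- normalize_item(lines)
  lines <- unique(lines[nzchar(lines)])
  if (length(lines) == 0) stop("lexicon ", path, " is empty", call. = FALSE)
  lines
}

#' Path to a bundled data file
#'
#' @param ... Path components under `extdata/`.
#' @return File path.
#' @export
fluenet_file <- function(...) {
  system.file("extdata", ..., package = "fluenet", mustWork = TRUE)
}

#' Bundled synthetic reference network
#'
#' A small synthetic association network over the bundled animal lexicon
#' (60 nodes, Watts-Strogatz-style small world, generated by
#' [make_reference_network()] with seed 2026). It stands in for a group-level
#' free-association network as the anchor of the edge prior; substitute a
#' real association network via [prior_spec()] for substantive analyses.
#'
#' @return Undirected igraph with named vertices.
#' @export
synthetic_reference_network <- function() {
  read_edge_list(fluenet_file("synthetic_reference.tsv"))
}

#' Clean fluency lists
#'
#' Normalizes every response, drops responses absent from the lexicon
#' (intrusions), and drops within-list repeats of an already-produced item
#' (perseverations), preserving order otherwise. An item that is both
#' normalized-empty and repeated counts once, as an intrusion. Lists left
#' empty after cleaning are retained (length zero) and flagged in the report.
#'
#' @param table Fluency table (see [read_fluency_table()]).
#' @param lexicon Character vector of canonical category members.
#' @return A list with components:
#'   \describe{
#'     \item{lists}{tibble with one row per retained response: `id`,
#'       `listnum`, `position` (re-indexed from 0) and canonical `item`.}
#'     \item{report}{one-row tibble: `n_responses_total`, `n_intrusions`,
#'       `n_perseverations`, `intrusion_rate`, `n_empty_lists`.}
#'   }
#' @export
clean_lists <- function(table, lexicon) {
  if (length(lexicon) == 0) stop("lexicon is empty", call. = FALSE)
  validate_positions(table)
  tab <- table |>
    dplyr::mutate(item = normalize_item(.data$item)) |>
    dplyr::arrange(.data$id, .data$listnum, .data$position) |>
    dplyr::group_by(.data$id, .data$listnum) |>
    dplyr::mutate(
      intrusion = !(.data$item %in% lexicon),
      perseveration = !.data$intrusion & duplicated(.data$item)
    ) |>
    dplyr::ungroup()
  kept <- tab |>
    dplyr::filter(!.data$intrusion, !.data$perseveration) |>
    dplyr::group_by(.data$id, .data$listnum) |>
    dplyr::mutate(position = seq_along(.data$item) - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("id", "listnum", "position", "item")
  n_total <- nrow(tab)
  emptied <- tab |>
    dplyr::distinct(.data$id, .data$listnum) |>
    dplyr::anti_join(kept, by = c("id", "listnum"))
  report <- tibble::tibble(
    n_responses_total = n_total,
    n_intrusions = sum(tab$intrusion),
    n_perseverations = sum(tab$perseveration),
    intrusion_rate = if (n_total > 0) sum(tab$intrusion) / n_total else 0,
    n_empty_lists = nrow(emptied)
  )
  if (nrow(emptied) > 0) {
    warning(nrow(emptied), " list(s) empty after cleaning (first: participant ",
            emptied$id[1], " list ", emptied$listnum[1], ")", call. = FALSE)
  }
  list(lists = kept, report = report)
}

#' Per-participant fluency counts
#'
#' @param lists Cleaned fluency lists (the `lists` component of
#'   [clean_lists()]).
#' @return Tibble with one row per participant: `id`, `n_lists`,
#'   `mean_items` (mean cleaned-list length).
#' @export
fluency_counts <- function(lists) {
  if (nrow(lists) == 0) stop("no fluency lists supplied", call. = FALSE)
  lists |>
    dplyr::count(.data$id, .data$listnum, name = "n_items") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n_lists = dplyr::n(),
                     mean_items = mean(.data$n_items), .groups = "drop")
}

#' Split a cleaned fluency table into per-list item vectors
#'
#' @param lists Cleaned fluency lists tibble.
#' @param id Optional participant id; if given, only that participant's lists.
#' @return Named list of character vectors, one per (id, listnum), ordered by
#'   position. Names are `"<id>.<listnum>"`.
#' @export
fluency_list_items <- function(lists, id = NULL) {
  if (!is.null(id)) lists <- dplyr::filter(lists, .data$id %in% !!id)
  lists <- dplyr::arrange(lists, .data$id, .data$listnum, .data$position)
  split(lists$item, paste(lists$id, lists$listnum, sep = "."))
}

#' Read / write an undirected edge list
#'
#' Two-column tab-separated text, one undirected edge per row, no header.
#' Duplicate edges (in either orientation) are collapsed; self-loops are an
#' error.
#'
#' @param path File path.
#' @return For `read_edge_list()`, an undirected [igraph::graph] with
#'   character vertex names.
#' @export
read_edge_list <- function(path) {
  rows <- readr::read_tsv(path, col_names = c("from", "to"),
                          col_types = "cc", progress = FALSE)
  loops <- which(rows$from == rows$to)
  if (length(loops) > 0) {
    stop("self-loop in edge list ", path, " at row ", loops[1], call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(rows, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @rdname read_edge_list
#' @param network An undirected igraph object with named vertices.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  el <- t(apply(el, 1, sort))
  if (nrow(el) > 1) el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
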