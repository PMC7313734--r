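#' Majority-consensus creativity scores
#'
#' Each response is scored by exactly three raters; a response earns one
#' point when two or more raters awarded it, and a participant's creativity
#' total is the sum of their response points. Content screening (e.g., a
#' typical use listed on the alternative-uses task) is the raters' call and
#' is encoded as `awarded = 0` upstream.
#'
#' @param table Data frame with columns `id`, `response`, `rater`,
#'   `awarded` (0/1), one row per (response, rater).
#' @return Tibble with one row per participant: `id`, `n_responses`,
#'   `creativity` (consensus total).
#' @export
consensus_scores <- function(table) {
  stopifnot(all(c("id", "response", "rater", "awarded") %in% names(table)))
  if (!all(table$awarded %in% c(0, 1))) {
    stop("`awarded` must be binary 0/1", call. = FALSE)
  }
  per_resp <- table |>
    dplyr::group_by(.data$id, .data$response) |>
    dplyr::summarise(n_raters = dplyr::n(),
                     votes = sum(.data$awarded), .groups = "drop")
  bad <- dplyr::filter(per_resp, .data$n_raters != 3)
  if (nrow(bad) > 0) {
    stop("response ", bad$response[1], " of participant ", bad$id[1],
         " has ", bad$n_raters[1], " raters (expected 3)", call. = FALSE)
  }
  per_resp |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n_responses = dplyr::n(),
                     creativity = sum(.data$votes >= 2), .groups = "drop")
}

#' Cohen's kappa for two binary raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` computed
#' from the two raters' marginal proportions. When both raters are constant
#' and identical (`p_e = 1`, `p_o = 1`), kappa is defined as 1.
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("rater vectors differ in length", call. = FALSE)
  if (length(a) == 0) stop("empty rater vectors", call. = FALSE)
  if (!all(c(a, b) %in% c(0, 1))) stop("ratings must be binary 0/1", call. = FALSE)
  p_o <- mean(a == b)
  p1a <- mean(a); p1b <- mean(b)
  p_e <- p1a * p1b + (1 - p1a) * (1 - p1b)
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Read a rater table
#'
#' CSV with header `id,response,rater,awarded`.
#'
#' @param path File path.
#' @return Tibble suitable for [consensus_scores()].
#' @export
read_rater_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), response = readr::col_character(),
    rater = readr::col_character(), awarded = readr::col_integer()
  ), progress = FALSE)
}
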