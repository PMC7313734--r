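#' Prior settings for default Bayes-factor tests
#'
#' @param cauchy_scale Scale of the Cauchy prior on the standardized effect
#'   size in the JZS t-test (default `sqrt(2)/2`).
#' @param rho_prior_width Width of the stretched-beta prior on the population
#'   correlation; width 1 (default) is uniform on (-1, 1).
#' @param side `"two_sided"`, `"positive"`, or `"negative"`. Directional
#'   priors truncate and renormalize the symmetric prior to the stated
#'   half-line.
#' @return An object of class `fluenet_bf_prior`.
#' @export
prior_settings <- function(cauchy_scale = sqrt(2) / 2, rho_prior_width = 1,
                           side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  if (cauchy_scale <= 0) stop("cauchy_scale must be > 0", call. = FALSE)
  if (rho_prior_width <= 0 || rho_prior_width > 2) {
    stop("rho_prior_width must be in (0, 2]", call. = FALSE)
  }
  structure(list(cauchy_scale = cauchy_scale,
                 rho_prior_width = rho_prior_width, side = side),
            class = "fluenet_bf_prior")
}

#' Pooled-variance t statistic from group summaries
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return One-row tibble: `t`, `df` (= n1 + n2 - 2), `n1`, `n2`, `n_eff`
#'   (= n1 n2 / (n1 + n2)).
#' @export
summary_to_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (s1 <= 0 || s2 <= 0) stop("group SDs must be positive", call. = FALSE)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  tibble::tibble(t = (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2)),
                 df = n1 + n2 - 2, n1 = n1, n2 = n2,
                 n_eff = n1 * n2 / (n1 + n2))
}

# numerator integral of the JZS BF over one delta-interval, with the
# integrand's peak (delta_hat) used as an interior split point
jzs_numerator <- function(t, df, n_eff, scale, lower, upper) {
  f <- function(d) {
    suppressWarnings(dt(t, df, ncp = d * sqrt(n_eff))) * dcauchy(d, 0, scale)
  }
  d_hat <- t / sqrt(n_eff)
  splits <- sort(unique(c(lower, upper, d_hat[d_hat > lower & d_hat < upper])))
  total <- 0
  for (q in seq_len(length(splits) - 1)) {
    total <- total + integrate(f, splits[q], splits[q + 1],
                               rel.tol = 1e-8, abs.tol = 0,
                               stop.on.error = FALSE)$value
  }
  total
}

#' JZS Bayes factor for an independent-samples t-test
#'
#' The alternative places a Cauchy prior on the standardized effect size
#' delta; the Bayes factor is the ratio of the marginal likelihood of the
#' observed t statistic under that prior (noncentral-t likelihood with
#' noncentrality `delta * sqrt(n_eff)`, integrated by adaptive quadrature) to
#' its likelihood under delta = 0. Directional tests truncate and
#' renormalize the prior to the requested half-line.
#'
#' @param summary One-row data frame from [summary_to_t()], or any data frame
#'   with columns `t`, `n1`, `n2`.
#' @param prior A [prior_settings()] object.
#' @return A `fluenet_bf` object; see [tidy.fluenet_bf()].
#' @export
jzs_ttest_bf <- function(summary, prior = prior_settings()) {
  t <- summary$t[1]; n1 <- summary$n1[1]; n2 <- summary$n2[1]
  if (!is.finite(t)) stop("t statistic must be finite", call. = FALSE)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  sc <- prior$cauchy_scale
  num <- switch(prior$side,
    two_sided = jzs_numerator(t, df, n_eff, sc, -Inf, Inf),
    positive  = 2 * jzs_numerator(t, df, n_eff, sc, 0, Inf),
    negative  = 2 * jzs_numerator(t, df, n_eff, sc, -Inf, 0))
  log_m1 <- log(num)
  log_m0 <- dt(t, df, log = TRUE)
  new_bf(log_m1 - log_m0, prior,
         test = "jzs_ttest",
         inputs = list(t = t, n1 = n1, n2 = n2, df = df))
}

# log of the Gaussian-hypergeometric factor of the exact r sampling density
# (terms free of rho cancel in the Bayes factor):
#   h(rho) = (1-rho^2)^((n-1)/2) (1-rho r)^(-(n-3/2)) 2F1(1/2,1/2; n-1/2; (1+rho r)/2)
log_h_rho <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log_hyp2f1_half(n - 0.5, (1 + rho * r) / 2)
}

# log 2F1(1/2, 1/2; c; z) for z in [0, 1), by its power series with explicit
# convergence control (terms are positive and the ratio tends to z < 1)
log_hyp2f1_half <- function(cc, z, tol = 1e-13, maxit = 50000L) {
  vapply(z, function(zz) {
    if (zz < 0 || zz >= 1) stop("hypergeometric argument outside [0, 1)",
                                call. = FALSE)
    term <- 1; s <- 1; k <- 0
    while (k < maxit) {
      term <- term * (0.5 + k)^2 / ((cc + k) * (k + 1)) * zz
      s <- s + term
      k <- k + 1
      if (term < tol * s) break
    }
    if (k >= maxit) stop("hypergeometric series failed to converge", call. = FALSE)
    log(s)
  }, numeric(1))
}

# integral of exp(log_h - shift) over (lo, hi), split at the density mode
pearson_marginal <- function(r, n, lo, hi, shift) {
  f <- function(rho) exp(log_h_rho(rho, r, n) - shift)
  splits <- sort(unique(c(lo, hi, r[r > lo & r < hi])))
  total <- 0
  for (q in seq_len(length(splits) - 1)) {
    total <- total + integrate(f, splits[q], splits[q + 1],
                               rel.tol = 1e-8, abs.tol = 0,
                               stop.on.error = FALSE)$value
  }
  total
}

#' Bayes factor for a Pearson correlation
#'
#' Uses the exact sampling density of the Pearson correlation coefficient
#' given the population correlation rho (Gaussian-hypergeometric form,
#' evaluated in log space via its power series with explicit convergence
#' control) and a prior on rho that is uniform on (-1, 1) for width 1
#' (stretched beta, width `rho_prior_width` generally), truncated and
#' renormalized to (0, 1) or (-1, 0) for directional tests.
#'
#' @param summary Data frame with columns `r` (sample correlation, |r| < 1)
#'   and `n` (sample size >= 4); or use [corr_summary()].
#' @param prior A [prior_settings()] object.
#' @return A `fluenet_bf` object.
#' @export
pearson_bf <- function(summary, prior = prior_settings()) {
  r <- summary$r[1]; n <- summary$n[1]
  if (!is.finite(r) || abs(r) >= 1) stop("need |r| < 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  w <- prior$rho_prior_width
  a <- 1 / w  # stretched Beta(1/w, 1/w) on (-1, 1); w = 1 is uniform
  log_prior_dens <- function(rho) {
    stats::dbeta((rho + 1) / 2, a, a, log = TRUE) - log(2)
  }
  shift <- log_h_rho(r, r, n)  # density mode, for stable exponentiation
  f_num <- function(lo, hi) {
    g <- function(rho) {
      exp(log_h_rho(rho, r, n) - shift + log_prior_dens(rho))
    }
    splits <- sort(unique(c(lo, hi, r[r > lo & r < hi])))
    total <- 0
    for (q in seq_len(length(splits) - 1)) {
      total <- total + integrate(g, splits[q], splits[q + 1],
                                 rel.tol = 1e-8, abs.tol = 0,
                                 stop.on.error = FALSE)$value
    }
    total
  }
  num <- switch(prior$side,
    two_sided = f_num(-1, 1),
    positive  = 2 * f_num(0, 1),
    negative  = 2 * f_num(-1, 0))
  log_m1 <- log(num) + shift
  log_m0 <- log_h_rho(0, r, n)
  new_bf(log_m1 - log_m0, prior,
         test = "pearson_correlation", inputs = list(r = r, n = n))
}

#' Correlation summary helper
#'
#' @param r Sample Pearson correlation.
#' @param n Sample size.
#' @return One-row tibble with columns `r`, `n`.
#' @export
corr_summary <- function(r, n) tibble::tibble(r = r, n = n)

#' One-sided p-value for a Pearson correlation
#'
#' Classical t transform: `t = r sqrt(n-2) / sqrt(1-r^2)` against Student t
#' with n-2 degrees of freedom, single tail.
#'
#' @param summary Data frame with columns `r` and `n`.
#' @param side `"positive"` or `"negative"`.
#' @return p-value.
#' @export
pearson_one_sided_p <- function(summary, side = c("positive", "negative")) {
  side <- match.arg(side)
  r <- summary$r[1]; n <- summary$n[1]
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  pt(tval, n - 2, lower.tail = (side == "negative"))
}

new_bf <- function(log_bf10, prior, test, inputs) {
  structure(list(bf10 = exp(log_bf10), bf01 = exp(-log_bf10),
                 log_bf10 = log_bf10, side = prior$side, prior = prior,
                 test = test, inputs = inputs),
            class = "fluenet_bf")
}

#' Jeffreys evidence label for a Bayes factor
#'
#' Labels the strength of the favored hypothesis with the conventional
#' cutoffs: `ambiguous` (BF = 1), `anecdotal` (1 < BF < 3), `substantial`
#' (3 <= BF < 10), `strong` (BF >= 10), applied to whichever of BF10 / BF01
#' exceeds 1.
#'
#' @param bf10 Bayes factor(s) for H1 over H0.
#' @return Character vector of labels.
#' @export
bf_label <- function(bf10) {
  bf <- pmax(bf10, 1 / bf10)
  dplyr::case_when(bf < 1 + 1e-12 ~ "ambiguous",
                   bf < 3 ~ "anecdotal",
                   bf < 10 ~ "substantial",
                   TRUE ~ "strong")
}

#' @export
print.fluenet_bf <- function(x, ...) {
  cat("Bayes factor (", x$test, ", ", x$side, ")\n", sep = "")
  cat("  BF10 =", format(x$bf10, digits = 4),
      "  BF01 =", format(x$bf01, digits = 4),
      " [", bf_label(x$bf10), "]\n")
  cat("  inputs:", paste(names(x$inputs), unlist(x$inputs), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Bayes-factor result
#'
#' @param x A `fluenet_bf` object.
#' @param ... Unused.
#' @return One-row tibble with the test name, inputs, side, BF10, BF01 and
#'   the Jeffreys label.
#' @export
tidy.fluenet_bf <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(test = x$test),
    tibble::as_tibble(x$inputs),
    tibble::tibble(side = x$side, bf10 = x$bf10, bf01 = x$bf01,
                   favors = ifelse(x$bf10 >= 1, "H1", "H0"),
                   label = bf_label(x$bf10))
  )
}

#' @rdname tidy.fluenet_bf
#' @export
glance.fluenet_bf <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, bf01 = x$bf01, log_bf10 = x$log_bf10,
                 side = x$side, test = x$test)
}

#' Write a Bayes-factor report table
#'
#' @param rows Tibble of tidied Bayes-factor rows (see [tidy.fluenet_bf()]),
#'   typically from [report_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bf_report <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
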