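#' Significance stars for a p value
#'
#' Thresholds 0.05 / 0.01 / 0.001 / 0.0001 map to `*` / `**` / `***` /
#' `****`; values at or above 0.05 map to `"ns"`.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Two-sided two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two event-time samples (e.g. rounding times of a control and an
#' exposed condition) with the two-sided two-sample KS test. The statistic is
#' `D = sup |ECDF_a - ECDF_b|` and the p value comes from the asymptotic
#' two-sample KS law. Samples are pooled event times per condition.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return An object of class `ks_comparison` with fields `statistic`,
#'   `p_value`, `n1`, `n2` and `significance_stars`.
#' @export
ks_two_sided <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort("Both samples must be non-empty.")
  }
  ht <- suppressWarnings(
    ks.test(sample_a, sample_b, alternative = "two.sided", exact = FALSE))
  p <- unname(ht$p.value)
  structure(
    list(statistic = unname(ht$statistic), p_value = p,
         n1 = length(sample_a), n2 = length(sample_b),
         significance_stars = significance_stars(p)),
    class = "ks_comparison"
  )
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("<ks_comparison> D = %.4f, p = %.3g (%s), n = %d vs %d\n",
              x$statistic, x$p_value, x$significance_stars, x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.ks_comparison <- function(x, ...) {
  tibble(ks_statistic = x$statistic, p_value = x$p_value, n1 = x$n1,
         n2 = x$n2, significance_stars = x$significance_stars)
}

#' @export
glance.ks_comparison <- function(x, ...) tidy(x)

#' Percentile bootstrap confidence interval for a mean
#'
#' Per-FOV summaries (peak times, cumulative activities) are reported as a
#' mean with a percentile-bootstrap confidence interval.
#'
#' @param values Numeric vector with at least 2 values.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional seed for reproducible intervals.
#' @return A tibble with `mean`, `lower`, `upper`, `level`, `n`, `n_boot`.
#' @export
bootstrap_ci_mean <- function(values, level = 0.95, n_boot = 1000,
                              seed = NULL) {
  if (length(values) < 2L) abort("Need at least 2 values to bootstrap.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  local_seed(seed, {
    n <- length(values)
    boots <- colMeans(matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                             nrow = n))
    q <- unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
    tibble(mean = mean(values), lower = q[1], upper = q[2], level = level,
           n = n, n_boot = n_boot)
  })
}
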