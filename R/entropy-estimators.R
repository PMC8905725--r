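#' Summarise a count vector into its occupancy histogram
#'
#' The sufficient statistic for every linear entropy estimator in this package
#' is the occupancy vector \eqn{h_j}: the number of expression levels (bins)
#' that are held by exactly \eqn{j} of the \eqn{N} cells in a window. This
#' function bins one gene's raw counts across a window of cells and tallies
#' the occupancies.
#'
#' @param counts non-negative integer vector of raw counts, one per cell
#'   (length \eqn{N}).
#' @param m_policy how the bin count \eqn{m} is chosen:
#'   `"max_plus_one"` (default) uses the expression levels
#'   `0..max(counts)`, so \eqn{m = \max + 1} and the zero level is always a
#'   bin; `"observed_support"` uses only the distinct observed values.
#' @param m optional explicit bin count. When the support of the underlying
#'   distribution is known (e.g. in simulations), pass it here; levels are
#'   then `0..m-1` and must cover all observed counts.
#' @return an object of class `"histogram_summary"`: a list with elements
#'   `N`, `m`, `h` (numeric vector of length `N + 1`, `h[j + 1]` counting the
#'   bins occupied by exactly `j` cells) and `observed_bins`.
#' @examples
#' summarize_histogram(c(0, 1, 1, 2))
#' @export
summarize_histogram <- function(counts,
                                m_policy = c("max_plus_one", "observed_support"),
                                m = NULL) {
  m_policy <- match.arg(m_policy)
  if (length(counts) == 0L) stop_data("'counts' is empty")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_data("'counts' must be non-negative integers")
  counts <- as.integer(round(counts))
  N <- length(counts)
  mx <- max(counts)
  if (!is.null(m)) {
    m <- as.integer(m)
    if (m < mx + 1L)
      stop_config("explicit m = ", m, " does not cover observed maximum ", mx)
    level_counts <- tabulate(counts + 1L, nbins = m)
  } else if (m_policy == "max_plus_one") {
    m <- mx + 1L
    level_counts <- tabulate(counts + 1L, nbins = m)
  } else {
    level_counts <- as.integer(table(counts))
    m <- length(level_counts)
  }
  h <- tabulate(level_counts + 1L, nbins = N + 1L)
  observed_bins <- sum(level_counts > 0L)
  h[1L] <- m - observed_bins   # bins seen by zero cells
  structure(list(N = N, m = m, h = as.numeric(h),
                 observed_bins = observed_bins),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("Histogram summary: N = %d cells, m = %d bins, %d occupied\n",
              x$N, x$m, x$observed_bins))
  invisible(x)
}

check_hist <- function(hist) {
  if (!inherits(hist, "histogram_summary"))
    stop_config("expected a 'histogram_summary' (see summarize_histogram)")
  hist
}

#' Plugin (maximum-likelihood) entropy estimate
#'
#' \eqn{\hat H = -\sum_{j \ge 1} h_j (j/N) \log(j/N)}, i.e. the Shannon
#' entropy of the empirical frequencies, in nats.
#'
#' @param hist a [summarize_histogram()] result.
#' @return entropy estimate in nats (numeric scalar).
#' @export
plugin_entropy <- function(hist) {
  check_hist(hist)
  j <- which(hist$h[-1L] > 0)         # occupancies 1..N present
  if (!length(j)) return(0)
  p <- j / hist$N
  -sum(hist$h[j + 1L] * p * log(p))
}

#' Miller-Madow bias-corrected entropy estimate
#'
#' Plugin estimate plus the first-order bias correction
#' \eqn{(\mathrm{observed\ bins} - 1) / (2N)}.
#'
#' @inheritParams plugin_entropy
#' @return entropy estimate in nats.
#' @export
miller_madow_entropy <- function(hist) {
  check_hist(hist)
  plugin_entropy(hist) + (hist$observed_bins - 1) / (2 * hist$N)
}

#' Jackknife entropy estimate
#'
#' \eqn{N \hat H - \frac{N-1}{N} \sum_i \hat H_{(-i)}} where
#' \eqn{\hat H_{(-i)}} is the plugin estimate with cell \eqn{i} removed
#' (over the same level set, which does not affect plugin values).
#' Cells sharing an expression level have identical leave-one-out estimates,
#' so the sum is taken over distinct levels weighted by their occupancy.
#'
#' @param counts non-negative integer count vector (length \eqn{N \ge 2}).
#' @return entropy estimate in nats.
#' @export
jackknife_entropy <- function(counts) {
  if (length(counts) < 2L) stop_data("jackknife requires N >= 2")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_data("'counts' must be non-negative integers")
  N <- length(counts)
  cnt <- as.integer(table(counts))     # per-level occupancies, all >= 1
  H_full <- {
    p <- cnt / N
    -sum(p * log(p))
  }
  plugin_of <- function(v) {
    v <- v[v > 0]
    p <- v / (N - 1)
    -sum(p * log(p))
  }
  loo_sum <- 0
  for (k in seq_along(cnt)) {
    v <- cnt
    v[k] <- v[k] - 1L
    loo_sum <- loo_sum + cnt[k] * plugin_of(v)
  }
  N * H_full - ((N - 1) / N) * loo_sum
}

#' BUB entropy estimate from precomputed coefficients
#'
#' The Best Upper Bound estimator is linear in the occupancy vector:
#' \eqn{\hat H = \sum_{j=0}^{N} a_j h_j}. Coefficients come from
#' [bub_coefficients()] (usually via [bub_cache()]), solved for the same
#' \eqn{(N, m)} as the histogram. A degenerate single-bin histogram
#' (\eqn{m = 1}, e.g. an all-zero gene) has entropy 0 by definition.
#'
#' @param hist a [summarize_histogram()] result.
#' @param coeffs a [bub_coefficients()] result with matching `N` and `m`.
#' @return entropy estimate in nats.
#' @export
bub_entropy <- function(hist, coeffs) {
  check_hist(hist)
  if (hist$m == 1L) return(0)
  if (coeffs$N != hist$N || coeffs$m != hist$m)
    stop_config("coefficient table is for (N = ", coeffs$N, ", m = ", coeffs$m,
                "), histogram has (N = ", hist$N, ", m = ", hist$m, ")")
  sum(coeffs$a * hist$h)
}

#' One-call entropy estimation on a raw count vector
#'
#' Convenience wrapper: summarise the counts and apply the chosen estimator.
#'
#' @param counts non-negative integer count vector.
#' @param estimator one of `"bub"`, `"plugin"`, `"miller_madow"`,
#'   `"jackknife"`.
#' @param cache a [bub_cache()] used to obtain (and memoise) BUB coefficients;
#'   required for `estimator = "bub"`. A fresh cache is created if omitted.
#' @inheritParams summarize_histogram
#' @return entropy estimate in nats.
#' @export
estimate_entropy <- function(counts,
                             estimator = c("bub", "plugin", "miller_madow",
                                           "jackknife"),
                             cache = NULL,
                             m_policy = "max_plus_one", m = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "jackknife") return(jackknife_entropy(counts))
  hist <- summarize_histogram(counts, m_policy = m_policy, m = m)
  switch(estimator,
         plugin = plugin_entropy(hist),
         miller_madow = miller_madow_entropy(hist),
         bub = {
           if (hist$m == 1L) return(0)
           if (is.null(cache)) cache <- bub_cache()
           bub_entropy(hist, cache_get(cache, hist$N, hist$m))
         })
}
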