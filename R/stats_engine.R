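# Shared statistical machinery: permutation framework and wrappers that
# give every analysis the same reporting surface (a `coda_test` record).

#' Construct a test result record
#'
#' @param method name of the procedure.
#' @param statistic observed statistic.
#' @param null_value central value of the resampled null, where one exists.
#' @param p_value the p value.
#' @param n sample size (scalar or named vector of group sizes).
#' @param n_resamples number of resamples, `NA` for exact tests.
#' @param seed RNG seed used, `NA` for deterministic tests.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param details free-form list of extra quantities.
#' @return list of class `coda_test`.
#' @export
test_result <- function(method, statistic, null_value = NA_real_, p_value,
                        n, n_resamples = NA_integer_, seed = NA_integer_,
                        alternative, details = list()) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(method = method, statistic = statistic,
                 null_value = null_value, p_value = p_value, n = n,
                 n_resamples = n_resamples, seed = seed,
                 alternative = alternative, details = details),
            class = "coda_test")
}

#' @export
print.coda_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$null_value)) cat(sprintf(", null = %.4g", x$null_value))
  cat(sprintf(", p = %.4g (%s), n = %s", x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  if (!is.na(x$n_resamples)) cat(sprintf(", resamples = %d", x$n_resamples))
  cat("\n")
  invisible(x)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. NULL seed = use (and advance) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Monte Carlo permutation test
#'
#' Compares an observed statistic against statistics recomputed on
#' resampled data. The p value uses the add-one convention
#' `(extreme + 1) / (n_resamples + 1)`, so it is bounded below by
#' `1 / (n_resamples + 1)` (0.0001 at the default 10,000 resamples) and
#' never exactly zero.
#'
#' @param observed observed scalar statistic.
#' @param resampler a `function(i)` returning one resampled statistic;
#'   called `n_resamples` times under the seeded RNG stream.
#' @param n_resamples number of resamplings (default 10,000).
#' @param alternative `"less"` rejects when the observed value is small
#'   relative to the null, `"greater"` when large, `"two.sided"` on
#'   absolute deviation from the null mean.
#' @param seed integer seed governing the resampling stream; the same seed
#'   reproduces the test bit-for-bit.
#' @param method label stored in the result.
#' @param n sample size to report.
#' @param details extra quantities to carry in the result.
#' @return a `coda_test` with `null_value` the mean resampled statistic.
#' @export
permutation_test <- function(observed, resampler, n_resamples = 10000L,
                             alternative = c("less", "greater", "two.sided"),
                             seed = NULL, method = "permutation", n = NA,
                             details = list()) {
  alternative <- match.arg(alternative)
  if (!is.finite(observed)) stop("observed statistic is not finite")
  if (n_resamples < 100) {
    warning("fewer than 100 resamples gives a coarse p value")
  }
  null_stats <- with_seed(seed,
    vapply(seq_len(n_resamples), function(i) resampler(i), numeric(1)))
  if (anyNA(null_stats) || any(!is.finite(null_stats))) {
    stop("resampler produced non-finite statistics")
  }
  extreme <- switch(alternative,
    less = sum(null_stats <= observed),
    greater = sum(null_stats >= observed),
    two.sided = sum(abs(null_stats - mean(null_stats)) >=
                      abs(observed - mean(null_stats))))
  test_result(method, observed, null_value = mean(null_stats),
              p_value = (extreme + 1) / (n_resamples + 1), n = n,
              n_resamples = as.integer(n_resamples),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              alternative = alternative,
              details = c(details, list(null_sd = stats::sd(null_stats))))
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; the two-sided p value uses
#' the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return a `coda_test` (statistic = r).
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant input: rank correlation undefined")
  }
  r <- stats::cor(rx, ry)
  if (abs(r) >= 1) {
    p <- 2 / factorial(min(n, 170))  # exact for a perfectly monotone tie-free pattern
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  test_result("spearman", r, p_value = max(p, .Machine$double.xmin), n = n,
              alternative = "two.sided")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute gap between the two empirical CDFs over the
#' pooled sample points; the p value is the asymptotic two-sided
#' approximation.
#'
#' @param a,b numeric samples.
#' @return a `coda_test` (statistic = D, `n` = the two group sizes).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  d <- max(abs(stats::ecdf(a)(pooled) - stats::ecdf(b)(pooled)))
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  test_result("ks_two_sample", d,
              p_value = max(kt$p.value, .Machine$double.xmin),
              n = c(n_a = length(a), n_b = length(b)),
              alternative = "two.sided")
}

#' Fisher's exact test on a 2x2 table
#'
#' Reports the sample odds ratio `(a*d)/(b*c)` alongside the exact
#' two-sided p value (probability method: sum of hypergeometric
#' probabilities no larger than the observed table's). A zero cell makes
#' the sample OR degenerate; it is then reported with the
#' Haldane-Anscombe 0.5 correction and flagged, the exact p unaffected.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return a `coda_test` (statistic = odds ratio; `details$haldane` flags
#'   the correction).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  haldane <- any(tab == 0)
  or_tab <- if (haldane) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  test_result("fisher_exact", or, p_value = max(min(p, 1), .Machine$double.xmin),
              n = sum(tab), alternative = "two.sided",
              details = list(table = tab, haldane = haldane))
}
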