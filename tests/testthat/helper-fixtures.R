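# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately naive re-derivations (enumeration, direct formulas) kept
# free of the package's own code paths.

sim_cache <- new.env()

# small hand-built ordered exchange: two whales, known structure
fixture_exchange <- function() {
  coda_set(
    ici = list(
      c(0.25, 0.25, 0.25, 0.25),   # w1 @ 0, dur 1.0, 5 clicks
      c(0.24, 0.26, 0.25, 0.25),   # w2 @ 0.5 overlaps w1
      c(0.25, 0.25, 0.26, 0.24),   # w1 @ 4, adjacent follow-up
      c(0.2, 0.3),                 # w2 @ 5.6, 3 clicks
      c(0.25, 0.25, 0.25, 0.25),   # w1 @ 30 after a long gap
      c(0.25, 0.25, 0.25, 0.25, 0.3)  # w1 @ 34: one extra click (ornament)
    ),
    coda_id = sprintf("f%02d", 1:6),
    whale_id = c("w1", "w2", "w1", "w2", "w1", "w1"),
    onset_time_s = c(0, 0.5, 4, 5.6, 30, 34))
}

random_coda <- function(k) stats::runif(k, 0.05, 0.4)

# --- oracles -----------------------------------------------------------

# element-by-element accumulation (duration oracle)
oracle_sum <- function(v) {
  acc <- 0
  for (el in v) acc <- acc + el
  acc
}

# O(n^2) maximal-run segmentation oracle over onsets of one whale
oracle_sequences <- function(onsets, gap) {
  n <- length(onsets)
  id <- integer(n)
  cur <- 1L
  id[1] <- cur
  for (i in seq_len(n - 1)) {
    if (onsets[i + 1] - onsets[i] > gap) cur <- cur + 1L
    id[i + 1] <- cur
  }
  id
}

# brute-force two-sample KS statistic: max ECDF gap over pooled points
oracle_ks_D <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Spearman r via the classic d^2 formula (tie-free vectors only)
oracle_spearman_r <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Fisher two-sided p by full hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive two-group permutation p (alternative: mean(groupA) small)
oracle_perm_p_less <- function(values, is_a) {
  n_a <- sum(is_a)
  obs <- mean(values[is_a])
  combos <- utils::combn(length(values), n_a)
  stats <- apply(combos, 2, function(idx) mean(values[idx]))
  mean(stats <= obs + 1e-12)
}
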