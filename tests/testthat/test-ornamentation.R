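orn_fixture <- function() {
  if (is.null(sim_cache$orn)) {
    # two recorded hours: the Fisher contingency tests need ~1000 leader
    # codas for adequate power at the configured effect sizes
    sim <- generate_exchange(generator_config(duration_s = 7200, seed = 8))
    cs <- filter_clicks(sim$codas, 10)
    sim_cache$orn <- list(sim = sim, cs = cs, orn = detect_ornaments(cs),
                          truth = sim$truth[match(cs$coda_id,
                                                  sim$truth$coda_id), ])
  }
  sim_cache$orn
}

test_that("a coda with one extra click vs its neighbours is flagged", {
  # one 6-click coda followed by 5-click codas 4 s apart
  x <- coda_set(list(rep(0.2, 5), rep(0.2, 4), rep(0.2, 4), rep(0.2, 4)),
                whale_id = "w1", onset_time_s = c(0, 4, 8, 12))
  orn <- detect_ornaments(x)
  expect_equal(orn$ornament, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(orn$ornament_click_index[1], 6L)
  expect_equal(orn$comparison_id[1], x$coda_id[2])
  # all codas the same click count: rule unsatisfiable
  y <- coda_set(list(rep(0.2, 4), rep(0.2, 4)), whale_id = "w1",
                onset_time_s = c(0, 4))
  expect_false(any(detect_ornaments(y)$ornament))
  # outside the 10 s window (span-to-span gap 11.2 s): no flag
  z <- coda_set(list(rep(0.2, 5), rep(0.2, 4)), whale_id = "w1",
                onset_time_s = c(0, 12))
  expect_false(any(detect_ornaments(z)$ornament))
})

test_that("detection is symmetric under time reversal", {
  f <- orn_fixture()
  x <- f$cs
  rev_x <- coda_set(lapply(x$ici, rev), coda_id = x$coda_id,
                    whale_id = x$whale_id,
                    onset_time_s = max(termination_time(x)) -
                      termination_time(x))
  fwd <- detect_ornaments(x)
  bwd <- detect_ornaments(rev_x)
  expect_equal(fwd$ornament[match(bwd$coda_id, fwd$coda_id)], bwd$ornament)
})

test_that("injected ornaments are recovered with high recall and precision", {
  f <- orn_fixture()
  tp <- sum(f$orn$ornament & f$truth$ornament)
  expect_gte(tp / sum(f$truth$ornament), 0.95)
  expect_gte(tp / sum(f$orn$ornament), 0.95)
  # prevalence near the configured 4% rate (boundary enrichment raises it)
  expect_gt(ornament_fraction(f$orn), 0.02)
  expect_lt(ornament_fraction(f$orn), 0.10)
})

test_that("final-ICI statistic follows its formula and is scale-invariant", {
  expect_equal(final_ici_stat(rep(0.2, 5)), 0)
  expect_equal(final_ici_stat(c(0.2, 0.2, 0.3)), 0.5)
  expect_true(is.na(final_ici_stat(c(0.2, 0.3))))
  set.seed(61)
  for (i in 1:30) {
    v <- random_coda(sample(3:9, 1))
    expect_equal(final_ici_stat(v), final_ici_stat(2 * v), tolerance = 1e-12)
    expect_equal(final_ici_stat(v),
                 (v[length(v)] - v[length(v) - 1]) / v[length(v) - 1])
  }
})

test_that("ornamented codas separate from plain ones in final-ICI space", {
  f <- orn_fixture()
  res <- final_ici_ks_test(f$cs, f$orn)
  expect_gt(res$statistic, 0.3)
  expect_lt(res$p_value, 1e-4)
  # identical groups give D = 0 through the same code path
  same <- ks_two_sample(1:20, 1:20)
  expect_equal(same$statistic, 0)
})

test_that("removing the ornament restores the neighbour's rhythm", {
  # coda = neighbour centroid + appended click: stripped MSE is exactly 0
  ctr <- c(0.25, 0.25, 0.25, 0.25)
  model <- rhythm_model(tibble::tibble(
    rhythm_id = c("r5", "r6"), click_count = c(5, 6),
    centroid = list(ctr, c(0.2, 0.2, 0.2, 0.2, 0.2))))
  base <- ctr * 0.9
  ici <- list(c(base, 0.3), base, base,
              c(base, 0.3), base, base,
              c(base, 0.3), base, base)
  x <- coda_set(ici, whale_id = "w1", onset_time_s = seq(0, 32, by = 4))
  res <- ornament_centroid_test(x, model, n_resamples = 199, seed = 62)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_gt(res$null_value, 0)
})

test_that("simulated ornaments sit closer to neighbours than to their own
           assigned rhythm", {
  f <- orn_fixture()
  kk <- c("4" = 1, "5" = 2, "6" = 1, "8" = 1, "9" = 1)
  rm5 <- fit_rhythm_model(f$cs, kk)
  res <- ornament_centroid_test(f$cs, rm5, f$orn, n_resamples = 999,
                                seed = 63)
  expect_lt(res$statistic, res$null_value)
  expect_lte(res$p_value, 0.01)
})

test_that("boundary-enriched ornaments are positionally over-represented", {
  f <- orn_fixture()
  pos <- positional_tests(f$cs, f$orn)
  expect_gt(pos$initial$statistic, 1)
  expect_gt(pos$final$statistic, 1)
  # degenerate table: every ornament sequence-initial
  x <- coda_set(list(rep(0.2, 5), rep(0.2, 4), rep(0.2, 4), rep(0.2, 4)),
                whale_id = "w1", onset_time_s = c(0, 4, 8, 12))
  orn <- detect_ornaments(x)
  res <- positional_tests(x, orn)
  expect_true(res$initial$details$haldane)
})

test_that("leader ornaments predict follower chorusing changes", {
  f <- orn_fixture()
  res <- chorus_change_test(f$cs, f$orn)
  expect_gt(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
})
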