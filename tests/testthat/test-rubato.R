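rubato_fixture <- function() {
  if (is.null(sim_cache$rub)) {
    sim <- generate_exchange(generator_config(duration_s = 1800, seed = 7))
    cs <- filter_clicks(sim$codas, 10)
    tm <- fit_tempo_model(coda_duration(cs), bandwidth = 0.05)
    rm5 <- fit_rhythm_model(cs, c("4" = 1, "5" = 2, "6" = 1, "8" = 1))
    sim_cache$rub <- list(sim = sim, cs = cs,
                          types = assign_types(cs, tm, rm5),
                          orn = detect_ornaments(cs))
  }
  sim_cache$rub
}

test_that("tempo drift is the signed duration difference, antisymmetric", {
  expect_equal(tempo_drift(c(0.4, 0.4), c(0.4, 0.4)), 0)
  expect_equal(tempo_drift(0.8, 1.0), 0.2)
  set.seed(51)
  for (i in 1:30) {
    a <- random_coda(4); b <- random_coda(6)
    expect_equal(tempo_drift(a, b), -tempo_drift(b, a))
    expect_equal(tempo_drift(a, b), sum(b) - sum(a))
  }
})

test_that("smooth simulated rubato gives adjacent drift below the null", {
  f <- rubato_fixture()
  res <- adjacent_drift_test(f$cs, f$types, n_resamples = 999, seed = 71,
                             ornaments = f$orn)
  expect_lt(res$statistic, res$null_value)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$n, 50)
  # bit-reproducible under the same seed
  res2 <- adjacent_drift_test(f$cs, f$types, n_resamples = 999, seed = 71,
                              ornaments = f$orn)
  expect_identical(res$p_value, res2$p_value)
})

test_that("drift magnitude increases with the configured rubato scale", {
  obs <- vapply(c(0.01, 0.03, 0.05), function(sd) {
    cfg <- generator_config(duration_s = 900, rubato_sd = sd, seed = 52)
    sim <- generate_exchange(cfg)
    cs <- filter_clicks(sim$codas, 10)
    tm <- fit_tempo_model(coda_duration(cs), bandwidth = 0.05)
    rm5 <- fit_rhythm_model(cs, c("4" = 1, "5" = 2, "6" = 1, "8" = 1))
    adjacent_drift_test(cs, assign_types(cs, tm, rm5), 199,
                        seed = 53)$statistic
  }, numeric(1))
  expect_true(all(diff(obs) > 0))
})

test_that("sustained drift yields a positive triple correlation; i.i.d.
           durations do not", {
  f <- rubato_fixture()
  res <- triple_correlation(f$cs, f$types, ornaments = f$orn)
  expect_gt(res$statistic, 0.2)
  expect_lt(res$p_value, 0.001)
  # i.i.d. durations: consecutive drifts share the middle duration with
  # opposite signs, so the null correlation is -1/2, not 0
  nul <- null_exchange(generator_config(duration_s = 3600, seed = 54))
  ns <- filter_clicks(nul$codas, 10)
  tm <- fit_tempo_model(coda_duration(ns), bandwidth = 0.05)
  rm5 <- fit_rhythm_model(ns, c("4" = 1, "5" = 2, "6" = 1, "8" = 1))
  nres <- triple_correlation(ns, assign_types(ns, tm, rm5))
  expect_gt(nres$statistic, -0.65)
  expect_lt(nres$statistic, -0.35)
})

test_that("duration imitation makes overlapping pairs match closely", {
  f <- rubato_fixture()
  res <- chorus_matching_test(f$cs, f$types, n_resamples = 999, seed = 72,
                              ornaments = f$orn)
  expect_lt(res$statistic, res$null_value)
  expect_lte(res$p_value, 0.01)
})

test_that("rubato classification follows the net-change rule", {
  expect_equal(classify_rubato(c(0.8, 0.85, 0.9), 0.05), "increasing")
  expect_equal(classify_rubato(c(0.8, 0.8, 0.8), 0.05), "constant")
  expect_equal(classify_rubato(c(0.9, 0.7), 0.05), "decreasing")
  expect_error(classify_rubato(0.8), "unclassifiable")
  set.seed(55)
  for (i in 1:50) {
    d <- stats::runif(sample(2:8, 1), 0.3, 1.5)
    net <- d[length(d)] - d[1]
    want <- if (net > 0.05) "increasing" else if (net < -0.05) "decreasing"
            else "constant"
    expect_equal(classify_rubato(d, 0.05), want)
  }
})

test_that("per-coda rubato classes match the generator's truth labels", {
  f <- rubato_fixture()
  rub <- rubato_classes(f$cs)
  truth <- f$sim$truth[match(f$cs$coda_id, f$sim$truth$coda_id), ]
  agree <- mean(rub$rubato_class == truth$rubato_class, na.rm = TRUE)
  expect_gt(agree, 0.8)
})
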