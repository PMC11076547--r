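test_that("tempo modes of a two-component mixture are recovered", {
  set.seed(41)
  durations <- c(stats::rnorm(250, 0.4, 0.05), stats::rnorm(250, 1.0, 0.05))
  tm <- fit_tempo_model(durations)
  expect_equal(tm$n_modes, 2)
  expect_equal(tm$mode_locations, c(0.4, 1.0), tolerance = 0.05 / 0.4)
  expect_length(tm$boundaries, 1)
  expect_true(tm$boundaries > tm$mode_locations[1] &&
                tm$boundaries < tm$mode_locations[2])
  # single tight cluster: one mode, no boundaries
  tm1 <- fit_tempo_model(stats::rnorm(100, 0.7, 0.02))
  expect_equal(tm1$n_modes, 1)
  expect_length(tm1$boundaries, 0)
  expect_error(fit_tempo_model(stats::rnorm(10)), "at least 50")
})

test_that("tempo assignment follows the boundary intervals exactly", {
  set.seed(42)
  durations <- c(stats::rnorm(300, 0.4, 0.05), stats::rnorm(300, 1.0, 0.05))
  tm <- fit_tempo_model(durations)
  # a duration exactly at a mode gets that mode's class
  expect_equal(assign_tempo(tm$mode_locations, tm), seq_len(tm$n_modes))
  # a duration exactly on the boundary takes the lower class
  expect_equal(assign_tempo(tm$boundaries[1], tm), 1L)
  # random durations agree with a brute-force interval scan
  d <- stats::runif(500, 0, 2)
  scan <- vapply(d, function(t) {
    sum(t > tm$boundaries) + 1L
  }, integer(1))
  expect_equal(assign_tempo(d, tm), scan)
})

test_that("refitting a tempo model on data simulated from its own modes
           recovers the mode structure", {
  set.seed(43)
  modes <- c(0.35, 0.65, 1.0, 1.4, 1.8)
  durations <- stats::rnorm(1500, sample(modes, 1500, replace = TRUE), 0.05)
  tm <- fit_tempo_model(durations, bandwidth = 0.05)
  expect_equal(tm$n_modes, 5)
  expect_equal(tm$mode_locations, modes, tolerance = 0.05 / 0.35)
})

test_that("rhythm clustering recovers well-separated templates", {
  set.seed(44)
  t1 <- c(0.4, 0.3, 0.3)
  t2 <- c(0.2, 0.2, 0.6)
  mk <- function(tpl, n) {
    lapply(seq_len(n), function(i) {
      s <- pmax(tpl + stats::rnorm(3, 0, 0.01), 0.01)
      (s / sum(s)) * stats::runif(1, 0.5, 1.5)
    })
  }
  x <- coda_set(c(mk(t1, 80), mk(t2, 80)))
  rm2 <- fit_rhythm_model(x, c("4" = 2), seed = 7)
  cent <- do.call(rbind, rm2$centroids$centroid)
  cent <- cent[order(cent[, 1]), ]
  expect_lt(sqrt(sum((cent[1, ] - t2)^2)), 1e-2 * 10)
  expect_lt(sqrt(sum((cent[2, ] - t1)^2)), 1e-2 * 10)
  # degenerate k = 1 returns the group mean
  one <- fit_rhythm_model(coda_set(mk(t1, 30)), c("4" = 1), seed = 7)
  expect_equal(one$centroids$centroid[[1]],
               t1 / sum(t1), tolerance = 0.02)
})

test_that("rhythm assignment is a nearest-centroid scan, scale-invariant", {
  model <- rhythm_model(tibble::tibble(
    rhythm_id = c("a", "b", "c"), click_count = c(4, 4, 5),
    centroid = list(c(0.4, 0.3, 0.3), c(0.2, 0.2, 0.6),
                    c(0.25, 0.25, 0.25, 0.25))))
  # a coda equal to a centroid: that id, distance 0
  x <- coda_set(list(c(0.4, 0.3, 0.3), c(0.8, 0.6, 0.6), rep(0.3, 4),
                     rep(0.2, 6)))
  res <- assign_rhythm(x, model)
  expect_equal(res$rhythm_id[1], "a")
  expect_equal(res$mse[1], 0)
  # scaled by 2: same id (standardisation)
  expect_equal(res$rhythm_id[2], "a")
  expect_equal(res$rhythm_id[3], "c")
  # no centroid with 7 clicks: flagged unassignable
  expect_true(is.na(res$rhythm_id[4]))
  # random codas agree with an exhaustive distance scan
  set.seed(45)
  for (i in 1:50) {
    v <- random_coda(3)
    s <- v / sum(v)
    d <- c(mean((s - c(0.4, 0.3, 0.3))^2), mean((s - c(0.2, 0.2, 0.6))^2))
    got <- assign_rhythm(coda_set(list(v)), model)
    expect_equal(got$rhythm_id, c("a", "b")[which.min(d)])
    expect_equal(got$mse, min(d))
  }
})

test_that("rhythm model files round-trip and validate", {
  model <- synthetic_reference_centroids()
  expect_equal(nrow(model$centroids), 18)
  expect_true(all(vapply(model$centroids$centroid,
                         function(v) abs(sum(v) - 1) < 1e-9, logical(1))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rhythm_model(model, path)
  back <- read_rhythm_model(path)
  expect_equal(nrow(back$centroids), 18)
  for (i in 1:18) {
    expect_equal(back$centroids$centroid[[i]], model$centroids$centroid[[i]],
                 tolerance = 1e-9)
  }
  expect_error(rhythm_model(tibble::tibble(rhythm_id = "x", click_count = 5,
                                           centroid = list(c(0.5, 0.5)))),
               "schema error")
})

test_that("every analysed coda gets exactly one discrete type or a flag", {
  sim <- generate_exchange(generator_config(duration_s = 900, seed = 6))
  cs <- filter_clicks(sim$codas, 10)
  tm <- fit_tempo_model(coda_duration(cs), bandwidth = 0.05)
  rm5 <- fit_rhythm_model(cs, c("4" = 1, "5" = 2, "6" = 1, "8" = 1))
  types <- assign_types(cs, tm, rm5)
  expect_equal(nrow(types), nrow(cs))
  expect_equal(sum(!is.na(types$discrete_type)) + sum(is.na(types$discrete_type)),
               nrow(cs))
  # rhythm assignment is time-scale invariant, tempo assignment is not
  scaled <- coda_set(lapply(cs$ici, function(v) v * 2),
                     coda_id = cs$coda_id)
  rh1 <- assign_rhythm(cs, rm5)
  rh2 <- assign_rhythm(scaled, rm5)
  expect_equal(rh1$rhythm_id, rh2$rhythm_id)
  expect_false(all(assign_tempo(coda_duration(cs) * 2, tm) ==
                     assign_tempo(coda_duration(cs), tm)))
})
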