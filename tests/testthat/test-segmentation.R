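test_that("call sequences split at the 8 s gap and partition the data", {
  x <- coda_set(list(c(0.2, 0.2), c(0.2, 0.2), c(0.2, 0.2)),
                whale_id = "w1", onset_time_s = c(0, 5, 20))
  s <- call_sequences(x)
  expect_equal(length(unique(s$sequence_id)), 2)
  expect_equal(s$seq_len, c(2, 2, 1))
  # singleton
  s1 <- call_sequences(coda_set(list(c(0.2, 0.2)), whale_id = "a",
                                onset_time_s = 3))
  expect_equal(s1$seq_len, 1L)
  expect_error(call_sequences(coda_set(list(c(0.2, 0.2)))), "ordered")
})

test_that("segmentation matches the brute-force maximal-run oracle", {
  set.seed(31)
  for (rep in 1:10) {
    onsets <- sort(stats::runif(200, 0, 2000))
    x <- coda_set(replicate(200, c(0.2, 0.2), simplify = FALSE),
                  whale_id = "w1", onset_time_s = onsets)
    s <- call_sequences(x)
    oracle <- oracle_sequences(onsets, 8)
    # same partition: sequence ids induce identical groupings
    expect_equal(as.integer(factor(s$sequence_id, levels = unique(s$sequence_id))),
                 oracle)
    # partition property: every coda in exactly one sequence
    expect_setequal(s$coda_id, x$coda_id)
    expect_equal(anyDuplicated(s$coda_id), 0)
  }
})

test_that("pair classification is exclusive, exhaustive and respects bounds", {
  expect_equal(classify_pair(0, 1.0, 0.5), "overlapping")
  expect_equal(classify_pair(0, 1.0, 1.5), "adjacent")
  expect_equal(classify_pair(0, 1.0, 3.5), "none")
  # boundary conventions: onset at termination is adjacent with gap 0;
  # gap exactly 2 s is adjacent (closed interval)
  expect_equal(classify_pair(0, 1.0, 1.0), "adjacent")
  expect_equal(classify_pair(0, 1.0, 3.0), "adjacent")
  expect_error(classify_pair(1, 1, 0.5), "precede")
  set.seed(32)
  rel <- classify_pair(0, 1, stats::runif(500, 0, 5))
  expect_true(all(rel %in% c("overlapping", "adjacent", "none")))
})

test_that("choruses are the components of the cross-whale link graph", {
  x <- fixture_exchange()
  ch <- choruses(x)
  # f01/f02 overlap; f03/f04 are turn-taking (the f02->f03 gap is 2.5 s,
  # too long to chain them); f05/f06 are single-whale
  expect_equal(nrow(ch$summary), 2)
  expect_equal(ch$summary$n_whales, c(2, 2))
  member <- ch$membership
  expect_setequal(member$coda_id[!is.na(member$chorus_id)],
                  c("f01", "f02", "f03", "f04"))
  # two whales 60 s apart never chorus
  y <- coda_set(list(c(0.2, 0.2), c(0.2, 0.2)), whale_id = c("a", "b"),
                onset_time_s = c(0, 60))
  expect_equal(nrow(choruses(y)$summary), 0)
})

test_that("random interleavings match a brute-force component oracle", {
  set.seed(33)
  for (rep in 1:8) {
    n <- 60
    x <- coda_set(replicate(n, stats::runif(4, 0.1, 0.4), simplify = FALSE),
                  whale_id = sample(c("a", "b"), n, replace = TRUE),
                  onset_time_s = sort(stats::runif(n, 0, 600)))
    ch <- choruses(x)
    # brute-force: all cross-whale linked pairs, then flood fill
    dur <- coda_duration(x)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (x$whale_id[i] == x$whale_id[j]) next
      first <- if (x$onset_time_s[i] <= x$onset_time_s[j]) i else j
      second <- i + j - first
      rel <- classify_pair(x$onset_time_s[first], dur[first],
                           x$onset_time_s[second])
      if (rel != "none") adj[i, j] <- adj[j, i] <- TRUE
    }
    comp <- rep(NA_integer_, n)
    cur <- 0
    for (i in 1:n) {
      if (!is.na(comp[i])) next
      cur <- cur + 1
      stack <- i
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cur
        stack <- c(stack, which(adj[v, ] & is.na(comp)))
      }
    }
    sizes <- table(comp)
    oracle_in_chorus <- vapply(seq_len(n), function(i) {
      members <- which(comp == comp[i])
      length(members) > 1 && length(unique(x$whale_id[members])) > 1
    }, logical(1))
    expect_equal(!is.na(ch$membership$chorus_id), oracle_in_chorus)
  }
})

test_that("leader/follower roles recover the generated leader", {
  sim <- generate_exchange(generator_config(duration_s = 1200, seed = 5))
  cs <- filter_clicks(sim$codas, 10)
  roles <- leader_follower(cs)
  roles <- roles[!is.na(roles$role), ]
  # whale 1 initiates every sequence in the generator
  w1_leader <- roles$whale_id[roles$role == "leader"]
  expect_gte(mean(w1_leader == "w1"), 0.95)
  # single-whale data yields no roles
  solo <- coda_set(list(c(0.2, 0.2), c(0.2, 0.2)), whale_id = "a",
                   onset_time_s = c(0, 4))
  expect_equal(nrow(leader_follower(solo)), 0)
})
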