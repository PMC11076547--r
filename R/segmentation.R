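# Conversational structure of ordered exchanges: single-whale call
# sequences, turn-taking / overlap links, choruses, leader/follower roles.

#' Segment each whale's codas into call sequences
#'
#' A call sequence is a maximal run of one whale's codas in which every
#' consecutive pair occurs within `gap_s` seconds (default 8 s, twice the
#' average response time). The gap is measured onset-to-onset by default,
#' matching the response-time framing; `anchor = "termination"` measures
#' previous-termination to next-onset instead.
#'
#' @param x an ordered `coda_set`.
#' @param gap_s maximum within-sequence gap in seconds.
#' @param anchor `"onset"` (default) or `"termination"`.
#' @return tibble with one row per coda: `coda_id`, `whale_id`,
#'   `sequence_id`, `seq_index` (position within the sequence) and
#'   `seq_len`; the rows partition the dataset.
#' @export
call_sequences <- function(x, gap_s = 8, anchor = c("onset", "termination")) {
  assert_ordered(x, "call_sequences()")
  anchor <- match.arg(anchor)
  term <- termination_time(x)
  out <- vector("list", 0L)
  seq_counter <- 0L
  for (w in unique(x$whale_id)) {
    idx <- which(x$whale_id == w)
    onset <- x$onset_time_s[idx]
    ref <- if (anchor == "onset") onset else term[idx]
    # gap between coda i and i+1: next onset minus this coda's anchor
    new_seq <- c(TRUE, (onset[-1] - ref[-length(idx)]) > gap_s)
    sid <- seq_counter + cumsum(new_seq)
    seq_counter <- max(sid)
    out[[length(out) + 1L]] <- tibble::tibble(
      coda_id = x$coda_id[idx], whale_id = w,
      sequence_id = sprintf("s%04d", sid),
      seq_index = stats::ave(sid, sid, FUN = seq_along)
    )
  }
  res <- do.call(rbind, out)
  len <- table(res$sequence_id)
  res$seq_len <- as.integer(len[res$sequence_id])
  res[match(x$coda_id, res$coda_id), ]
}

#' Classify the relation between two codas
#'
#' Given the earlier coda's onset and duration and the later coda's onset:
#' *overlapping* if the second onset falls after the first onset but
#' before the first termination; *adjacent* (turn-taking) if it falls
#' after the termination but within `turn_window_s` seconds of it (closed
#' interval; an onset exactly at the termination counts as adjacent with
#' gap 0); *none* otherwise. Vectorised.
#'
#' @param onset1,duration1 first coda's onset and duration (seconds).
#' @param onset2 second coda's onset; must be `>= onset1`.
#' @param turn_window_s turn-taking window (default 2 s).
#' @return character vector in `{"overlapping","adjacent","none"}`.
#' @export
classify_pair <- function(onset1, duration1, onset2, turn_window_s = 2) {
  if (any(onset2 < onset1)) stop("second onset must not precede the first")
  term1 <- onset1 + duration1
  ifelse(onset2 > onset1 & onset2 < term1, "overlapping",
         ifelse(onset2 >= term1 & onset2 - term1 <= turn_window_s,
                "adjacent", "none"))
}

#' All adjacent / overlapping links in an exchange
#'
#' Enumerates ordered coda pairs (first onset before second) whose
#' relation is adjacent or overlapping, with the inter-onset gap.
#'
#' @param x an ordered `coda_set`.
#' @param turn_window_s turn-taking window in seconds.
#' @param cross_whale_only keep only links between different whales
#'   (the links that define choruses).
#' @return tibble `first_id`, `second_id`, `first_whale`, `second_whale`,
#'   `relation`, `gap_s` (second onset minus first termination; negative
#'   when overlapping).
#' @export
coda_links <- function(x, turn_window_s = 2, cross_whale_only = FALSE) {
  assert_ordered(x, "coda_links()")
  n <- nrow(x)
  onset <- x$onset_time_s
  dur <- coda_duration(x)
  rows <- list()
  for (i in seq_len(n)) {
    j <- i + 1L
    # candidate partners: onset within duration + window of coda i's onset
    while (j <= n && onset[j] <= onset[i] + dur[i] + turn_window_s) {
      rel <- classify_pair(onset[i], dur[i], onset[j], turn_window_s)
      if (rel != "none" &&
          (!cross_whale_only || x$whale_id[i] != x$whale_id[j])) {
        rows[[length(rows) + 1L]] <- list(
          first_id = x$coda_id[i], second_id = x$coda_id[j],
          first_whale = x$whale_id[i], second_whale = x$whale_id[j],
          relation = rel, gap_s = onset[j] - (onset[i] + dur[i]))
      }
      j <- j + 1L
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(first_id = character(), second_id = character(),
                          first_whale = character(), second_whale = character(),
                          relation = character(), gap_s = numeric()))
  }
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

# union-find over coda indices
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Identify choruses
#'
#' A chorus is a maximal period in which more than a single whale is
#' producing codas: the connected components of the cross-whale
#' adjacent/overlapping link graph, grown transitively through any link
#' so a chorus spans the whole connected stretch of exchange.
#'
#' @param x an ordered `coda_set`.
#' @param turn_window_s turn-taking window in seconds.
#' @return list with `membership` (tibble `coda_id`, `chorus_id`; `NA`
#'   chorus for codas in no multi-whale component) and `summary` (tibble
#'   `chorus_id`, `start_s`, `end_s`, `n_codas`, `n_whales`, `whales`).
#' @export
choruses <- function(x, turn_window_s = 2) {
  assert_ordered(x, "choruses()")
  links <- coda_links(x, turn_window_s, cross_whale_only = TRUE)
  n <- nrow(x)
  parent <- seq_len(n)
  idx <- stats::setNames(seq_len(n), x$coda_id)
  for (r in seq_len(nrow(links))) {
    a <- uf_find(parent, idx[[links$first_id[r]]])
    b <- uf_find(parent, idx[[links$second_id[r]]])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp_sizes <- table(root)
  multi <- as.integer(names(comp_sizes))[comp_sizes > 1]
  chorus_id <- rep(NA_character_, n)
  summ <- list()
  term <- termination_time(x)
  k <- 0L
  for (rt in multi[order(vapply(multi, function(r) min(x$onset_time_s[root == r]), numeric(1)))]) {
    members <- which(root == rt)
    if (length(unique(x$whale_id[members])) < 2) next
    k <- k + 1L
    cid <- sprintf("ch%03d", k)
    chorus_id[members] <- cid
    summ[[k]] <- tibble::tibble(
      chorus_id = cid, start_s = min(x$onset_time_s[members]),
      end_s = max(term[members]), n_codas = length(members),
      n_whales = length(unique(x$whale_id[members])),
      whales = paste(sort(unique(x$whale_id[members])), collapse = "+"))
  }
  list(membership = tibble::tibble(coda_id = x$coda_id, chorus_id = chorus_id),
       summary = if (k) do.call(rbind, summ) else
         tibble::tibble(chorus_id = character(), start_s = numeric(),
                        end_s = numeric(), n_codas = integer(),
                        n_whales = integer(), whales = character()))
}

#' Assign leader/follower roles within choruses
#'
#' Within each cross-whale link the whale with the earlier onset leads;
#' a whale's role in a chorus is its modal pairwise role. Pairs whose
#' onsets coincide within 1 ms are excluded, and a whale tied between
#' roles gets `NA`.
#'
#' @param x an ordered `coda_set`.
#' @param chorus result of [choruses()] (recomputed when omitted).
#' @param turn_window_s turn-taking window in seconds.
#' @return tibble `chorus_id`, `whale_id`, `role` in
#'   `{"leader","follower",NA}`.
#' @export
leader_follower <- function(x, chorus = NULL, turn_window_s = 2) {
  assert_ordered(x, "leader_follower()")
  if (is.null(chorus)) chorus <- choruses(x, turn_window_s)
  links <- coda_links(x, turn_window_s, cross_whale_only = TRUE)
  onset <- stats::setNames(x$onset_time_s, x$coda_id)
  cid <- stats::setNames(chorus$membership$chorus_id, chorus$membership$coda_id)
  out <- list()
  for (ch in chorus$summary$chorus_id) {
    l <- links[!is.na(cid[links$first_id]) & cid[links$first_id] == ch, ]
    tied <- abs(onset[l$first_id] - onset[l$second_id]) < 1e-3
    l <- l[!tied, ]
    whales <- sort(unique(c(l$first_whale, l$second_whale)))
    for (w in whales) {
      leads <- sum(l$first_whale == w)
      follows <- sum(l$second_whale == w)
      role <- if (leads > follows) "leader"
              else if (follows > leads) "follower" else NA_character_
      out[[length(out) + 1L]] <- tibble::tibble(
        chorus_id = ch, whale_id = w, role = role)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chorus_id = character(), whale_id = character(),
                          role = character()))
  }
  do.call(rbind, out)
}
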