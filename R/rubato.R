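# Rubato: smooth modulation of coda duration across consecutive codas.
# Three analyses establish that within-type duration variation is
# context-dependent: adjacent same-whale pairs drift less than random
# same-type pairs; drift is positively correlated across coda triples;
# and overlapping cross-whale pairs match durations more closely than
# random same-type cross-whale pairs.

#' Tempo drift between two codas
#'
#' Signed difference in duration, second minus first, in seconds.
#'
#' @param c1,c2 numeric ICI vectors, durations, or `coda_set`s of equal
#'   size.
#' @return signed seconds.
#' @export
tempo_drift <- function(c1, c2) {
  d <- function(z) if (inherits(z, "coda_set")) coda_duration(z)
                   else if (length(z) > 1) sum(z) else z
  d(c2) - d(c1)
}

# Consecutive same-whale, same-discrete-type coda index pairs within call
# sequences. `types` is the assign_types() tibble aligned to x.
same_type_adjacent_pairs <- function(x, types, gap_s = 8, ornamented = NULL) {
  seqs <- call_sequences(x, gap_s = gap_s)
  ord <- order(x$whale_id, x$onset_time_s)
  sid <- seqs$sequence_id[match(x$coda_id, seqs$coda_id)]
  dtype <- types$discrete_type[match(x$coda_id, types$coda_id)]
  if (!is.null(ornamented)) dtype[ornamented] <- NA_character_
  i <- ord[-length(ord)]
  j <- ord[-1]
  keep <- sid[i] == sid[j] & !is.na(dtype[i]) & !is.na(dtype[j]) &
    dtype[i] == dtype[j]
  tibble::tibble(i = i[keep], j = j[keep], type = dtype[i[keep]],
                 whale = x$whale_id[i[keep]])
}

#' Adjacent-pair drift permutation test
#'
#' Observed statistic: mean absolute tempo drift over consecutive
#' same-whale coda pairs of the same discrete type (within 8 s call
#' sequences). Null: drift depends only on the discrete type — durations
#' are permuted within each (whale, discrete type) group and the same
#' adjacency pattern re-measured, i.e. random same-type pairs from the
#' same whale, each resample using distinct pairs. One-sided: smooth
#' rubato makes the observed mean smaller than the null.
#'
#' @param x an ordered `coda_set`.
#' @param types discrete-type annotations from [assign_types()].
#' @param n_resamples permutation count (default 10,000).
#' @param seed RNG seed.
#' @param gap_s call-sequence gap in seconds.
#' @param ornaments result of [detect_ornaments()]; detected ornamented
#'   codas are excluded from the drift pools because the appended click
#'   inflates duration by a full ICI, which is an ornamentation effect,
#'   not tempo modulation. Recomputed when `NULL`; pass `FALSE` to keep
#'   every coda.
#' @return a `coda_test`; `details` carries the per-pair drifts.
#' @export
adjacent_drift_test <- function(x, types, n_resamples = 10000L, seed = NULL,
                                gap_s = 8, ornaments = NULL) {
  assert_ordered(x, "adjacent_drift_test()")
  orn_flag <- resolve_ornament_flag(x, ornaments)
  pairs <- same_type_adjacent_pairs(x, types, gap_s, orn_flag)
  if (nrow(pairs) < 2) stop("insufficient data: no qualifying adjacent pairs")
  dur <- coda_duration(x)
  observed <- mean(abs(dur[pairs$j] - dur[pairs$i]))
  dtype_vec <- types$discrete_type[match(x$coda_id, types$coda_id)]
  if (!is.null(orn_flag)) dtype_vec[orn_flag] <- NA_character_
  grp <- interaction(x$whale_id, dtype_vec, drop = TRUE)
  grp_idx <- split(seq_len(nrow(x)), grp)
  resampler <- function(r) {
    perm <- dur
    for (g in grp_idx) if (length(g) > 1) perm[g] <- dur[sample(g)]
    mean(abs(perm[pairs$j] - perm[pairs$i]))
  }
  permutation_test(observed, resampler, n_resamples, alternative = "less",
                   seed = seed, method = "adjacent_drift", n = nrow(pairs),
                   details = list(drift = dur[pairs$j] - dur[pairs$i]))
}

#' Triple drift correlation
#'
#' Collects consecutive same-whale, same-discrete-type coda triples and
#' correlates the drift across the first pair with the drift across the
#' second (Spearman, two-sided). A positive correlation shows rubato is
#' sustained over runs of codas rather than reset pair by pair.
#'
#' @inheritParams adjacent_drift_test
#' @param min_triples minimum number of triples (default 10).
#' @param ornaments as in [adjacent_drift_test()].
#' @return a `coda_test` (statistic = Spearman r).
#' @export
triple_correlation <- function(x, types, gap_s = 8, min_triples = 10L,
                               ornaments = NULL) {
  assert_ordered(x, "triple_correlation()")
  orn_flag <- resolve_ornament_flag(x, ornaments)
  pairs <- same_type_adjacent_pairs(x, types, gap_s, orn_flag)
  # a triple is two chained pairs: (i,j) then (j,k)
  first <- match(pairs$j, pairs$i)
  keep <- !is.na(first)
  if (sum(keep) < min_triples) {
    stop("insufficient data: fewer than ", min_triples, " qualifying triples")
  }
  dur <- coda_duration(x)
  d12 <- dur[pairs$j[keep]] - dur[pairs$i[keep]]
  nxt <- pairs[first[keep], ]
  d23 <- dur[nxt$j] - dur[nxt$i]
  res <- spearman_correlation(d12, d23)
  res$method <- "triple_drift_correlation"
  res
}

#' Chorus duration-matching permutation test
#'
#' Observed statistic: mean absolute duration difference over
#' overlapping cross-whale coda pairs. Null: chorusing whales match only
#' discrete coda type — for each observed pair, a random non-overlapping
#' cross-whale pair of the same discrete type is drawn (distinct pairs
#' within a resample). One-sided: imitation makes the observed mean
#' smaller.
#'
#' @inheritParams adjacent_drift_test
#' @param turn_window_s turn-taking window for the link graph.
#' @return a `coda_test`.
#' @export
chorus_matching_test <- function(x, types, n_resamples = 10000L, seed = NULL,
                                 turn_window_s = 2, ornaments = NULL) {
  assert_ordered(x, "chorus_matching_test()")
  orn_flag <- resolve_ornament_flag(x, ornaments)
  links <- coda_links(x, turn_window_s, cross_whale_only = TRUE)
  ov <- links[links$relation == "overlapping", ]
  dtype <- stats::setNames(types$discrete_type, types$coda_id)
  if (!is.null(orn_flag)) dtype[x$coda_id[orn_flag]] <- NA_character_
  ov <- ov[!is.na(dtype[ov$first_id]) & !is.na(dtype[ov$second_id]), ]
  if (nrow(ov) < 2) stop("insufficient data: no overlapping cross-whale pairs")
  dur <- stats::setNames(coda_duration(x), x$coda_id)
  observed <- mean(abs(dur[ov$second_id] - dur[ov$first_id]))

  # overlap partner sets, to exclude overlapping pairs from the null pool
  overlap_key <- paste(pmin(ov$first_id, ov$second_id),
                       pmax(ov$first_id, ov$second_id))
  # null pool: per discrete type, ornamented codas excluded above
  keep <- !is.na(dtype)
  pool <- split(names(dtype)[keep], dtype[keep])
  whale <- stats::setNames(x$whale_id, x$coda_id)
  obs_types <- dtype[ov$first_id]
  resampler <- function(r) {
    diffs <- vapply(obs_types, function(tt) {
      ids <- pool[[tt]]
      for (try in 1:50) {
        pick <- sample(ids, 2L)
        if (whale[pick[1]] != whale[pick[2]] &&
            !(paste(min(pick), max(pick)) %in% overlap_key)) {
          return(abs(dur[pick[1]] - dur[pick[2]]))
        }
      }
      NA_real_
    }, numeric(1))
    mean(diffs, na.rm = TRUE)
  }
  permutation_test(observed, resampler, n_resamples, alternative = "less",
                   seed = seed, method = "chorus_duration_matching",
                   n = nrow(ov))
}

#' Classify the rubato of a call sequence
#'
#' Net duration change over the sequence's same-type codas against a
#' symmetric threshold: increasing above `+threshold_s`, decreasing below
#' `-threshold_s`, otherwise constant.
#'
#' @param durations the sequence's coda durations, in order (at least 2).
#' @param threshold_s net-change threshold in seconds (default 0.05,
#'   the scale of adjacent-pair drift).
#' @return `"increasing"`, `"decreasing"` or `"constant"`.
#' @export
classify_rubato <- function(durations, threshold_s = 0.05) {
  if (length(durations) < 2) stop("unclassifiable: fewer than 2 codas")
  net <- durations[length(durations)] - durations[1]
  if (net > threshold_s) "increasing"
  else if (net < -threshold_s) "decreasing"
  else "constant"
}

#' Rubato class of every analysed coda
#'
#' Classifies each call sequence by its net duration change and
#' propagates the class to member codas; singleton sequences are
#' unclassifiable (`NA`).
#'
#' @param x an ordered `coda_set`.
#' @param threshold_s see [classify_rubato()].
#' @param gap_s call-sequence gap in seconds.
#' @return tibble `coda_id`, `sequence_id`, `rubato_class`.
#' @export
rubato_classes <- function(x, threshold_s = 0.05, gap_s = 8) {
  seqs <- call_sequences(x, gap_s = gap_s)
  dur <- coda_duration(x)
  cls <- vapply(split(seq_len(nrow(x)), seqs$sequence_id), function(idx) {
    idx <- idx[order(x$onset_time_s[idx])]
    if (length(idx) < 2) return(NA_character_)
    classify_rubato(dur[idx], threshold_s)
  }, character(1))
  tibble::tibble(coda_id = x$coda_id, sequence_id = seqs$sequence_id,
                 rubato_class = unname(cls[seqs$sequence_id]))
}

# logical index of detected-ornamented codas, or NULL for no exclusion
resolve_ornament_flag <- function(x, ornaments) {
  if (isFALSE(ornaments)) return(NULL)
  if (is.null(ornaments)) ornaments <- detect_ornaments(x)
  ornaments$ornament[match(x$coda_id, ornaments$coda_id)]
}
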