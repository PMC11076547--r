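# Ornamentation: an 'extra' final click appended to a coda whose
# remaining clicks match neighbouring codas. Detection plus four
# analyses: centroid-MSE comparison, final-ICI distribution test,
# positional enrichment within call sequences, and prediction of changes
# in chorusing behaviour.

#' Detect ornamented codas
#'
#' An ornament is the final click of a coda containing exactly one more
#' click than the nearest preceding or the nearest following coda within
#' a window of ten seconds (the average-response-time scale), whichever
#' matches. The window is measured between coda spans (next onset minus
#' previous termination), which makes the rule exactly symmetric under
#' time reversal. The default scope compares a coda against the same
#' whale's codas (an ornament is defined relative to the caller's own
#' pattern), `scope = "any_whale"` against all codas.
#'
#' @param x an ordered `coda_set`.
#' @param window_s comparison window in seconds (default 10).
#' @param scope `"same_whale"` (default) or `"any_whale"`.
#' @return tibble `coda_id`, `ornament` (logical), `comparison_id` (the
#'   nearest coda used, `NA` when none in window),
#'   `ornament_click_index` (the flagged final click's index).
#' @export
detect_ornaments <- function(x, window_s = 10, scope = c("same_whale", "any_whale")) {
  assert_ordered(x, "detect_ornaments()")
  scope <- match.arg(scope)
  k <- click_counts(x)
  onset <- x$onset_time_s
  term <- termination_time(x)
  n <- nrow(x)
  ornament <- logical(n)
  comparison <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pool <- setdiff(seq_len(n), i)
    if (scope == "same_whale") {
      pool <- pool[x$whale_id[pool] == x$whale_id[i]]
    }
    if (!length(pool)) next
    # span-to-span gap to each candidate (negative when overlapping)
    gap_prev <- onset[i] - term[pool]   # candidate precedes i
    gap_next <- onset[pool] - term[i]   # candidate follows i
    is_prev <- onset[pool] < onset[i] |
      (onset[pool] == onset[i] & pool < i)
    gap <- ifelse(is_prev, gap_prev, gap_next)
    cand <- pool[gap <= window_s]
    if (!length(cand)) next
    cg <- gap[gap <= window_s]
    cp <- is_prev[gap <= window_s]
    # nearest preceding and nearest following comparison codas
    nearest <- c(if (any(cp)) cand[cp][which.min(cg[cp])],
                 if (any(!cp)) cand[!cp][which.min(cg[!cp])])
    near_gap <- c(if (any(cp)) min(cg[cp]), if (any(!cp)) min(cg[!cp]))
    hit <- k[i] == k[nearest] + 1L
    if (any(hit)) {
      ornament[i] <- TRUE
      comparison[i] <- x$coda_id[nearest[hit][which.min(near_gap[hit])]]
    } else {
      comparison[i] <- x$coda_id[nearest[which.min(near_gap)]]
    }
  }
  tibble::tibble(coda_id = x$coda_id, ornament = ornament,
                 comparison_id = comparison,
                 ornament_click_index = ifelse(ornament, k, NA_integer_))
}

#' Ornament prevalence
#' @param ornaments result of [detect_ornaments()].
#' @return fraction of codas flagged ornamented.
#' @export
ornament_fraction <- function(ornaments) mean(ornaments$ornament)

#' Strip the ornament from an ICI vector
#' @param ici numeric ICI vector (at least 2 elements).
#' @return the vector without its final element.
#' @export
remove_ornament <- function(ici) {
  if (length(ici) < 2) stop("cannot remove the only ICI")
  ici[-length(ici)]
}

#' Ornament centroid-MSE permutation test
#'
#' For each ornamented coda with a same-whale adjacent coda: quantity A
#' is the mean squared distance between the standardised coda (ornament
#' retained) and the centroid of its assigned rhythm type (the null
#' hypothesis that ornamented codas are ordinary members of a
#' longer-click type); quantity B is the mean squared distance between
#' the standardised coda with the ornament removed and the rhythm
#' centroid of its adjacent same-whale codas (the hypothesis that
#' ornamented codas match their neighbours). The one-sided p value that
#' B < A comes from a paired sign-flip permutation of the per-coda
#' (A, B) quantities.
#'
#' @param x an ordered `coda_set`.
#' @param rhythm_model a `rhythm_model` containing centroids for both the
#'   ornamented and the stripped click counts.
#' @param ornaments result of [detect_ornaments()] (recomputed when
#'   omitted).
#' @param n_resamples sign-flip resamples (default 10,000).
#' @param seed RNG seed.
#' @param gap_s call-sequence gap defining same-whale adjacency.
#' @return a `coda_test`: statistic = mean B, `null_value` = mean A,
#'   `details$mse_retained` / `details$mse_removed` the per-coda values.
#' @export
ornament_centroid_test <- function(x, rhythm_model, ornaments = NULL,
                                   n_resamples = 10000L, seed = NULL,
                                   gap_s = 8) {
  assert_ordered(x, "ornament_centroid_test()")
  if (is.null(ornaments)) ornaments <- detect_ornaments(x)
  rh <- assign_rhythm(x, rhythm_model)
  cent <- stats::setNames(rhythm_model$centroids$centroid,
                          rhythm_model$centroids$rhythm_id)
  seqs <- call_sequences(x, gap_s = gap_s)
  sid <- seqs$sequence_id[match(x$coda_id, seqs$coda_id)]
  rid <- stats::setNames(rh$rhythm_id, rh$coda_id)

  a_vals <- c(); b_vals <- c()
  ord <- order(x$whale_id, x$onset_time_s)
  pos_in_ord <- match(seq_len(nrow(x)), ord)
  for (i in which(ornaments$ornament)) {
    own <- rid[[x$coda_id[i]]]
    if (is.na(own)) next
    std <- x$ici[[i]] / sum(x$ici[[i]])
    a <- mean((std - cent[[own]])^2)
    # adjacent same-whale codas: predecessor/successor in the same call sequence
    p <- pos_in_ord[i]
    nb <- c(if (p > 1) ord[p - 1], if (p < nrow(x)) ord[p + 1])
    nb <- nb[x$whale_id[nb] == x$whale_id[i] & sid[nb] == sid[i]]
    nb_rids <- unique(stats::na.omit(rid[x$coda_id[nb]]))
    if (!length(nb_rids)) next
    stripped <- remove_ornament(x$ici[[i]])
    stripped <- stripped / sum(stripped)
    b <- min(vapply(nb_rids, function(rr) {
      ctr <- cent[[rr]]
      if (length(ctr) != length(stripped)) return(NA_real_)
      mean((stripped - ctr)^2)
    }, numeric(1)), na.rm = TRUE)
    if (!is.finite(b)) next
    a_vals <- c(a_vals, a); b_vals <- c(b_vals, b)
  }
  if (length(a_vals) < 3) {
    stop("insufficient data: too few ornamented codas with same-whale ",
         "adjacent codas")
  }
  diffs <- b_vals - a_vals
  observed <- mean(diffs)
  resampler <- function(r) mean(diffs * sample(c(-1, 1), length(diffs),
                                               replace = TRUE))
  res <- permutation_test(observed, resampler, n_resamples,
                          alternative = "less", seed = seed,
                          method = "ornament_centroid_mse",
                          n = length(a_vals),
                          details = list(mse_retained = a_vals,
                                         mse_removed = b_vals))
  res$statistic <- mean(b_vals)
  res$null_value <- mean(a_vals)
  res
}

#' Final-ICI statistic
#'
#' The difference between the final two ICIs normalised by the
#' penultimate ICI, `(last - penultimate) / penultimate`; scale-invariant
#' and defined only for codas with at least three ICIs.
#'
#' @param ici numeric ICI vector.
#' @return dimensionless ratio, `NA` when fewer than three ICIs.
#' @export
final_ici_stat <- function(ici) {
  m <- length(ici)
  if (m < 3) return(NA_real_)
  (ici[m] - ici[m - 1]) / ici[m - 1]
}

#' Final-ICI distribution test
#'
#' Two-sample Kolmogorov-Smirnov test comparing the final-ICI statistic
#' of ornamented vs non-ornamented codas restricted to click counts that
#' occur in both groups (so the comparison is between codas with the same
#' number of clicks).
#'
#' @param x an ordered `coda_set`.
#' @param ornaments result of [detect_ornaments()] (recomputed when
#'   omitted).
#' @return a `coda_test` (statistic = D; `n` = the two group sizes).
#' @export
final_ici_ks_test <- function(x, ornaments = NULL) {
  if (is.null(ornaments)) ornaments <- detect_ornaments(x)
  stat <- vapply(x$ici, final_ici_stat, numeric(1))
  k <- click_counts(x)
  orn <- ornaments$ornament[match(x$coda_id, ornaments$coda_id)]
  ok <- !is.na(stat)
  shared <- intersect(unique(k[ok & orn]), unique(k[ok & !orn]))
  sel <- ok & k %in% shared
  a <- stat[sel & orn]; b <- stat[sel & !orn]
  if (!length(a) || !length(b)) {
    stop("insufficient data: one final-ICI group is empty")
  }
  res <- ks_two_sample(a, b)
  res$method <- "final_ici_ks"
  res
}

#' Positional enrichment of ornaments in call sequences
#'
#' Two Fisher's exact tests on 2x2 tables crossing ornamented status with
#' (a) sequence-initial and (b) sequence-final position. Singleton
#' sequences are excluded by default (a coda that is both first and last
#' carries no positional information).
#'
#' @param x an ordered `coda_set`.
#' @param ornaments result of [detect_ornaments()].
#' @param include_singletons count length-1 sequences?
#' @param gap_s call-sequence gap in seconds.
#' @return list with `coda_test` elements `initial` and `final`.
#' @export
positional_tests <- function(x, ornaments = NULL, include_singletons = FALSE,
                             gap_s = 8) {
  assert_ordered(x, "positional_tests()")
  if (is.null(ornaments)) ornaments <- detect_ornaments(x)
  seqs <- call_sequences(x, gap_s = gap_s)
  orn <- ornaments$ornament[match(seqs$coda_id, ornaments$coda_id)]
  keep <- if (include_singletons) rep(TRUE, nrow(seqs)) else seqs$seq_len > 1
  tab <- function(pos_flag) {
    matrix(c(sum(orn & pos_flag & keep), sum(orn & !pos_flag & keep),
             sum(!orn & pos_flag & keep), sum(!orn & !pos_flag & keep)),
           2, 2, byrow = TRUE,
           dimnames = list(ornamented = c("yes", "no"),
                           position = c("at", "elsewhere")))
  }
  initial <- fisher_exact(tab(seqs$seq_index == 1))
  final <- fisher_exact(tab(seqs$seq_index == seqs$seq_len))
  initial$method <- "ornament_position_initial"
  final$method <- "ornament_position_final"
  list(initial = initial, final = final)
}

#' Do ornaments predict changes in chorusing behaviour?
#'
#' Leader and follower roles are the modal pairwise roles across the
#' recording's choruses. A leader coda enters the test when it occurs in
#' an active exchange context — the follower vocalised within `gap_s`
#' before its onset or within `gap_s` after its termination. A change in
#' chorusing behaviour after the coda is one of three follower events:
#' it *begins* chorusing (no follower coda in the `gap_s` window before,
#' one within `gap_s` after), *pauses* (next follower coda more than
#' `gap_s` after the coda's termination, vocalising resuming later), or
#' *ceases* (no further follower codas in the recording). Fisher's exact
#' test crosses leader-coda ornamentation with followed-by-change.
#'
#' @param x an ordered `coda_set`.
#' @param ornaments result of [detect_ornaments()].
#' @param gap_s response-gap constant (default 8 s, as for call
#'   sequences).
#' @param turn_window_s turn-taking window for chorus construction.
#' @return a `coda_test` (statistic = odds ratio); `details$table` the
#'   2x2 counts.
#' @export
chorus_change_test <- function(x, ornaments = NULL, gap_s = 8,
                               turn_window_s = 2) {
  assert_ordered(x, "chorus_change_test()")
  if (is.null(ornaments)) ornaments <- detect_ornaments(x)
  ch <- choruses(x, turn_window_s)
  roles <- leader_follower(x, ch, turn_window_s)
  roles <- roles[!is.na(roles$role), ]
  if (!nrow(roles)) stop("insufficient data: no leader codas in choruses")
  lead_score <- tapply(roles$role == "leader", roles$whale_id, mean)
  leader <- names(lead_score)[which.max(lead_score)]
  follower <- setdiff(unique(roles$whale_id), leader)
  if (!length(follower)) stop("insufficient data: no follower whale")

  orn <- stats::setNames(ornaments$ornament, ornaments$coda_id)
  term <- termination_time(x)
  fol_onsets <- sort(x$onset_time_s[x$whale_id %in% follower])
  lead_idx <- which(x$whale_id == leader)
  rows <- list()
  for (i in lead_idx) {
    before <- any(fol_onsets >= x$onset_time_s[i] - gap_s &
                    fol_onsets < x$onset_time_s[i])
    nxt <- fol_onsets[fol_onsets >= term[i]]
    after <- length(nxt) > 0 && min(nxt) - term[i] <= gap_s
    if (!before && !after) next  # no exchange context around this coda
    begins <- !before && after
    ceases <- length(nxt) == 0
    pauses <- length(nxt) > 0 && min(nxt) - term[i] > gap_s
    rows[[length(rows) + 1L]] <- list(
      ornamented = orn[[x$coda_id[i]]],
      change = begins || ceases || pauses)
  }
  if (!length(rows)) stop("insufficient data: no leader codas in context")
  df <- do.call(rbind, lapply(rows, as.data.frame))
  tab <- matrix(c(sum(df$ornamented & df$change),
                  sum(df$ornamented & !df$change),
                  sum(!df$ornamented & df$change),
                  sum(!df$ornamented & !df$change)), 2, 2, byrow = TRUE,
                dimnames = list(ornamented = c("yes", "no"),
                                change = c("yes", "no")))
  res <- fisher_exact(tab)
  res$method <- "ornament_chorus_change"
  res$n <- nrow(df)
  res
}
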