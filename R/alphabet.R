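# The phonetic alphabet: rhythm x tempo co-occurrence with per-cell
# rubato and ornamentation annotations, and information-capacity
# summaries.

#' Combine per-coda annotations
#'
#' Joins discrete types, ornament flags and rubato classes into the
#' per-coda table the alphabet is built from.
#'
#' @param types result of [assign_types()].
#' @param ornaments result of [detect_ornaments()], or `NULL` (no
#'   ornament annotation).
#' @param rubato result of [rubato_classes()], or `NULL`.
#' @return tibble `coda_id`, `rhythm_id`, `tempo_type`, `ornament`,
#'   `rubato_class`.
#' @export
feature_annotations <- function(types, ornaments = NULL, rubato = NULL) {
  out <- tibble::tibble(
    coda_id = types$coda_id, rhythm_id = types$rhythm_id,
    tempo_type = types$tempo_type,
    ornament = if (is.null(ornaments)) FALSE else
      ornaments$ornament[match(types$coda_id, ornaments$coda_id)],
    rubato_class = if (is.null(rubato)) NA_character_ else
      rubato$rubato_class[match(types$coda_id, rubato$coda_id)])
  out
}

#' Build the rhythm x tempo alphabet matrix
#'
#' One cell per realised (rhythm, tempo) combination, with the number of
#' codas, the split of codas occurring with vs without rubato (with = in
#' a sequence classified increasing or decreasing), and the ornament
#' count. Codas without a rhythm assignment are excluded with a logged
#' count.
#'
#' @param annotations result of [feature_annotations()].
#' @return tibble of class `coda_alphabet`: `rhythm_id`, `tempo_type`,
#'   `count`, `rubato_with`, `rubato_without`, `ornament_count`,
#'   `ornament_fraction` (fraction of all ornaments in that cell); the
#'   `n_untyped` attribute counts excluded codas.
#' @export
build_alphabet <- function(annotations) {
  typed <- annotations[!is.na(annotations$rhythm_id) &
                         !is.na(annotations$tempo_type), ]
  n_untyped <- nrow(annotations) - nrow(typed)
  if (n_untyped > 0) {
    message(n_untyped, " untyped coda(s) excluded from the alphabet")
  }
  if (!nrow(typed)) {
    out <- tibble::tibble(rhythm_id = character(), tempo_type = integer(),
                          count = integer(), rubato_with = integer(),
                          rubato_without = integer(),
                          ornament_count = integer(),
                          ornament_fraction = numeric())
    return(structure(out, class = c("coda_alphabet", class(out)),
                     n_untyped = n_untyped))
  }
  key <- interaction(typed$rhythm_id, typed$tempo_type, drop = TRUE)
  cells <- lapply(split(typed, key), function(g) {
    with_rub <- !is.na(g$rubato_class) & g$rubato_class %in%
      c("increasing", "decreasing")
    tibble::tibble(
      rhythm_id = g$rhythm_id[1], tempo_type = g$tempo_type[1],
      count = nrow(g), rubato_with = sum(with_rub),
      rubato_without = sum(!with_rub),
      ornament_count = sum(g$ornament, na.rm = TRUE))
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$tempo_type, out$rhythm_id), ]
  total_orn <- sum(out$ornament_count)
  out$ornament_fraction <- if (total_orn > 0)
    out$ornament_count / total_orn else 0
  structure(out, class = c("coda_alphabet", class(out)),
            n_untyped = n_untyped)
}

#' Count frequently realised feature combinations
#'
#' Number of distinct feature tuples with at least `min_count`
#' occurrences. With `include_features = TRUE` (default) the tuple is
#' (rhythm, tempo, ornamented?, rubato class); otherwise plain
#' (rhythm, tempo) cells are counted.
#'
#' @param annotations result of [feature_annotations()].
#' @param min_count occurrence threshold defining "frequently realised".
#' @param include_features include ornament and rubato dimensions?
#' @return integer count.
#' @export
count_realized <- function(annotations, min_count = 5L,
                           include_features = TRUE) {
  typed <- annotations[!is.na(annotations$rhythm_id) &
                         !is.na(annotations$tempo_type), ]
  key <- if (include_features) {
    paste(typed$rhythm_id, typed$tempo_type,
          ifelse(is.na(typed$ornament), FALSE, typed$ornament),
          ifelse(is.na(typed$rubato_class), "constant", typed$rubato_class))
  } else {
    paste(typed$rhythm_id, typed$tempo_type)
  }
  sum(table(key) >= min_count)
}

#' Sweep the realised-combination count across thresholds
#'
#' @inheritParams count_realized
#' @param min_counts thresholds to evaluate.
#' @return tibble `min_count`, `n_realized` (monotone non-increasing).
#' @export
realized_sweep <- function(annotations, min_counts = 1:20,
                           include_features = TRUE) {
  tibble::tibble(
    min_count = min_counts,
    n_realized = vapply(min_counts, count_realized,
                        annotations = annotations,
                        include_features = include_features, integer(1)))
}

#' Information capacity of a discrete repertoire
#'
#' Base-2 logarithm of the number of distinguishable types, with the
#' whole-bit ceiling (the usual "at most b bits per symbol" reading).
#'
#' @param n_types number of types (at least 1).
#' @return list `bits` and `bits_ceiling`.
#' @export
capacity_bits <- function(n_types) {
  if (!is.numeric(n_types) || n_types < 1) {
    stop("n_types must be a positive integer")
  }
  list(bits = log2(n_types), bits_ceiling = ceiling(log2(n_types)))
}

#' Capacity of the combinatorial feature system
#'
#' With independent rhythm, tempo, optional ornamentation and a rubato
#' class, the number of distinguishable codas is the product of the
#' factor cardinalities; the capacity is its base-2 logarithm, which by
#' additivity equals the sum of the per-factor capacities.
#'
#' @param n_rhythm,n_tempo,ornament_levels,rubato_levels factor
#'   cardinalities (defaults 18, 5, 2, 3).
#' @return bits (numeric scalar).
#' @export
feature_capacity <- function(n_rhythm = 18, n_tempo = 5,
                             ornament_levels = 2, rubato_levels = 3) {
  factors <- c(n_rhythm, n_tempo, ornament_levels, rubato_levels)
  if (any(factors < 1)) stop("all factor cardinalities must be >= 1")
  log2(prod(factors))
}
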