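#' Construct a coda set
#'
#' A coda is a short burst of clicks; its temporal structure is the ordered
#' vector of inter-click intervals (ICIs), in seconds. A coda set collects
#' codas from one recording, optionally with speaker identity and the
#' absolute onset time of the first click, in which case the set is
#' *ordered* and conversational structure (call sequences, turn-taking,
#' overlap, choruses) can be derived from it.
#'
#' @param ici list of numeric vectors, one per coda; every element must be
#'   a strictly positive duration in seconds and each vector must have at
#'   least one element (a k-click coda has k-1 ICIs).
#' @param coda_id character vector of unique identifiers; generated when
#'   omitted.
#' @param whale_id character vector of speaker identifiers, or `NULL` for
#'   repertoire-style data without attribution.
#' @param onset_time_s numeric vector of first-click times in seconds from
#'   the start of the recording, or `NULL`.
#' @param recording_id optional character scalar or vector.
#' @param metadata optional named list attached as an attribute.
#'
#' @return A tibble of class `coda_set` with columns `coda_id`,
#'   `recording_id`, `whale_id`, `onset_time_s` and the list-column `ici`,
#'   sorted by onset time when ordered. The `ordered` attribute is `TRUE`
#'   iff all codas carry both a whale id and an onset time.
#' @export
coda_set <- function(ici, coda_id = NULL, whale_id = NULL,
                     onset_time_s = NULL, recording_id = NA_character_,
                     metadata = list()) {
  if (is.numeric(ici)) ici <- list(ici)
  stopifnot(is.list(ici))
  n <- length(ici)
  if (is.null(coda_id)) coda_id <- sprintf("c%05d", seq_len(n))
  coda_id <- as.character(coda_id)
  if (anyDuplicated(coda_id)) stop("coda_id values must be unique")
  if (is.null(whale_id)) whale_id <- rep(NA_character_, n)
  if (is.null(onset_time_s)) onset_time_s <- rep(NA_real_, n)
  whale_id <- rep_len(as.character(whale_id), n)
  onset_time_s <- rep_len(as.numeric(onset_time_s), n)
  recording_id <- rep_len(as.character(recording_id), n)

  bad <- vapply(ici, function(v) {
    length(v) < 1L || !is.numeric(v) || anyNA(v) || any(v <= 0)
  }, logical(1))
  if (any(bad)) {
    stop("invalid coda(s): ", paste(coda_id[bad], collapse = ", "),
         " (ICIs must be a non-empty vector of positive durations)")
  }
  ici <- lapply(ici, as.numeric)

  x <- tibble::tibble(
    coda_id = coda_id, recording_id = recording_id,
    whale_id = whale_id, onset_time_s = onset_time_s, ici = ici
  )
  ordered <- n > 0 && !anyNA(whale_id) && !anyNA(onset_time_s)
  if (ordered) x <- x[order(x$onset_time_s, x$coda_id), ]
  structure(x, class = c("coda_set", class(tibble::tibble())),
            ordered = ordered, metadata = metadata)
}

#' @export
print.coda_set <- function(x, ...) {
  cat(sprintf("<coda_set> %d codas, %s\n", nrow(x),
              if (isTRUE(attr(x, "ordered"))) "ordered (onset + speaker)"
              else "unordered repertoire"))
  NextMethod()
}

new_coda_subset <- function(x, idx) {
  y <- x[idx, ]
  structure(y, class = class(x), ordered = attr(x, "ordered"),
            metadata = attr(x, "metadata"))
}

#' Is a coda set ordered?
#' @param x a `coda_set`.
#' @return logical scalar.
#' @export
is_ordered <- function(x) isTRUE(attr(x, "ordered"))

assert_ordered <- function(x, what) {
  if (!is_ordered(x)) {
    stop(what, " requires an ordered coda set (onset times and whale ids)")
  }
}

#' Number of clicks per coda
#' @param x a `coda_set` or a single numeric ICI vector.
#' @return integer vector (length of each ICI vector plus one).
#' @export
click_counts <- function(x) {
  if (is.numeric(x)) return(length(x) + 1L)
  lengths(x$ici) + 1L
}

#' Coda duration
#'
#' The duration of a coda is the sum of its absolute ICIs (first click to
#' last click), in seconds.
#'
#' @param x a `coda_set` or a single numeric ICI vector.
#' @return numeric vector of durations, one per coda.
#' @export
coda_duration <- function(x) {
  if (is.numeric(x)) {
    if (length(x) < 1L) stop("a single click is not a coda: empty ICI vector")
    return(sum(x))
  }
  vapply(x$ici, sum, numeric(1))
}

#' Standardised absolute ICIs
#'
#' Divides each ICI by the coda's total duration, yielding a unit-sum
#' vector that conserves rhythm and discards tempo: a uniformly
#' time-scaled coda maps to the same standardised vector.
#'
#' @param x a `coda_set` or a single numeric ICI vector.
#' @return a numeric vector (single coda) or list of vectors, each summing
#'   to one.
#' @export
standardize_ici <- function(x) {
  if (is.numeric(x)) return(x / coda_duration(x))
  lapply(x$ici, function(v) v / sum(v))
}

#' Cumulative ICIs
#'
#' The time of clicks 2..k relative to the first click. When
#' `standardized`, the cumulative sums are divided by the duration so the
#' final element equals one.
#'
#' @param x a `coda_set` or a single numeric ICI vector.
#' @param standardized divide by total duration?
#' @return numeric vector (single coda) or list of strictly increasing
#'   vectors.
#' @export
cumulative_ici <- function(x, standardized = FALSE) {
  f <- function(v) {
    cs <- cumsum(v)
    if (standardized) cs / cs[length(cs)] else cs
  }
  if (is.numeric(x)) return(f(x))
  lapply(x$ici, f)
}

#' Termination time of each coda
#' @param x an ordered `coda_set`.
#' @return numeric vector: onset plus duration.
#' @export
termination_time <- function(x) x$onset_time_s + coda_duration(x)

# ---- canonical table I/O ----------------------------------------------

#' The canonical coda-table schema
#'
#' Columns `coda_id, recording_id, whale_id, onset_time_s, ici_1..ici_9`
#' (seconds, `.` decimal separator, UTF-8, header row); shorter codas
#' leave trailing ICI cells empty. Nine ICI columns cover codas of up to
#' ten clicks, the analysis ceiling used throughout.
#' @keywords internal
#' @name canonical_schema
NULL

CANONICAL_MAX_ICI <- 9L

#' Read a coda table
#'
#' @param path CSV file in the canonical dialect (see
#'   [canonical_schema]).
#' @param min_clicks codas with fewer clicks are rejected (logged with a
#'   warning); 2 by default at I/O, analysis functions are stricter.
#' @return a `coda_set`; the `ordered` attribute is set iff every row has
#'   both a whale id and an onset time. Rows with non-positive or missing
#'   leading ICIs are rejected with a warning, never silently dropped.
#' @export
read_codas <- function(path, min_clicks = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("coda_id", "recording_id", "whale_id", "onset_time_s")
  if (!all(req %in% names(df))) {
    stop("schema error: missing column(s) ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  ici_cols <- paste0("ici_", seq_len(CANONICAL_MAX_ICI))
  if (!any(ici_cols %in% names(df))) stop("schema error: no ici_* columns")
  as_coda_set(df, ici_cols = intersect(ici_cols, names(df)),
              min_clicks = min_clicks)
}

#' Coerce a wide data frame to a coda set
#'
#' Adapter from arbitrary wide coda tables (one ICI per column) onto the
#' canonical schema. Trailing `NA` cells delimit each coda's ICI vector;
#' rows whose ICI prefix contains non-positive values or interior gaps are
#' rejected with a warning naming the row.
#'
#' @param df a data frame.
#' @param ici_cols names of the ICI columns, in click order.
#' @param id_col,whale_col,onset_col,recording_col column names in `df`;
#'   pass `NULL` where the layout lacks them.
#' @param min_clicks minimum clicks accepted at ingest.
#' @return a `coda_set`.
#' @export
as_coda_set <- function(df, ici_cols, id_col = "coda_id",
                        whale_col = "whale_id", onset_col = "onset_time_s",
                        recording_col = "recording_id", min_clicks = 2L) {
  get_col <- function(nm, default) {
    if (!is.null(nm) && nm %in% names(df)) df[[nm]] else default
  }
  n <- nrow(df)
  ids <- as.character(get_col(id_col, sprintf("row%05d", seq_len(n))))
  mat <- as.matrix(df[, ici_cols, drop = FALSE])
  mode(mat) <- "numeric"

  ici <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    v <- mat[i, ]
    last <- max(c(0L, which(!is.na(v))))
    prefix <- v[seq_len(last)]
    valid <- last >= 1L && !anyNA(prefix) && all(prefix > 0) &&
      last + 1L >= min_clicks
    if (valid) {
      ici[[i]] <- unname(prefix)
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(sum(!ok), " row(s) rejected (non-positive, gapped or too-short",
            " ICIs): ", paste(ids[!ok], collapse = ", "))
  }
  coda_set(ici[ok], coda_id = ids[ok],
           whale_id = get_col(whale_col, NULL)[ok],
           onset_time_s = get_col(onset_col, NULL)[ok],
           recording_id = get_col(recording_col, NA_character_)[ok])
}

#' Write a coda table in the canonical dialect
#'
#' @param x a `coda_set`; codas longer than ten clicks cannot be
#'   represented and raise an error (filter first with [filter_clicks()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_codas <- function(x, path) {
  k <- click_counts(x)
  if (any(k - 1L > CANONICAL_MAX_ICI)) {
    stop("codas with more than ", CANONICAL_MAX_ICI + 1L,
         " clicks cannot be written in the canonical dialect")
  }
  mat <- matrix(NA_real_, nrow(x), CANONICAL_MAX_ICI,
                dimnames = list(NULL, paste0("ici_", seq_len(CANONICAL_MAX_ICI))))
  for (i in seq_len(nrow(x))) mat[i, seq_along(x$ici[[i]])] <- x$ici[[i]]
  out <- data.frame(coda_id = x$coda_id, recording_id = x$recording_id,
                    whale_id = x$whale_id, onset_time_s = x$onset_time_s,
                    mat, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Exclude rare long codas
#'
#' Codas with more than `max_clicks` clicks (rare, long codas) are
#' excluded from analysis; order is preserved and the operation is
#' idempotent.
#'
#' @param x a `coda_set`.
#' @param max_clicks analysis ceiling on the click count (default 10).
#' @return the filtered `coda_set`.
#' @export
filter_clicks <- function(x, max_clicks = 10L) {
  if (max_clicks < 2) stop("max_clicks must be at least 2")
  new_coda_subset(x, click_counts(x) <= max_clicks)
}

#' Load the deposited field dataset
#'
#' The study's annotated coda tables are deposited in an external
#' repository and are not bundled with this package; analyses of the field
#' data require placing them, converted to the canonical dialect, at the
#' given path.
#'
#' @param path path to the converted field coda table.
#' @return a `coda_set`.
#' @export
load_deposited_codas <- function(path = NULL) {
  if (is.null(path) || !file.exists(path %||% "")) {
    stop("the deposited field coda tables are not bundled with this ",
         "package; convert them to the canonical dialect and pass their ",
         "path explicitly")
  }
  read_codas(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
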