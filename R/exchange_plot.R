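# Exchange plots: time-time scatter of clicks (exchange time on the
# horizontal axis, time since coda onset on the vertical), the
# visualisation that exposes coda-internal structure in conversational
# context.

#' Click coordinates for an exchange plot
#'
#' For click j of a coda with onset t0, x = t0 plus the cumulative ICI up
#' to j (x = t0 for the first click) and y = x - t0, so the vertical axis
#' magnifies coda-internal structure: the first click of every coda sits
#' at y = 0 and a coda's y values are its cumulative ICIs.
#'
#' @param x an ordered `coda_set`.
#' @return tibble `x`, `y`, `whale_id`, `coda_id`, `click_index`.
#' @export
exchange_coordinates <- function(x) {
  assert_ordered(x, "exchange_coordinates()")
  rows <- lapply(seq_len(nrow(x)), function(i) {
    yy <- c(0, cumsum(x$ici[[i]]))
    wid <- x$whale_id[i]
    cid <- x$coda_id[i]
    tibble::tibble(x = x$onset_time_s[i] + yy, y = yy, whale_id = wid,
                   coda_id = cid, click_index = seq_along(yy))
  })
  do.call(rbind, rows)
}

#' Segments linking matching clicks of adjacent codas
#'
#' Links click i of each coda to click i of the same whale's next coda
#' in the same call sequence, up to the smaller click count; extra
#' (ornament) clicks remain unlinked, which is what makes them visible
#' on the plot.
#'
#' @param x an ordered `coda_set`.
#' @param gap_s call-sequence gap in seconds.
#' @return tibble `x0`, `y0`, `x1`, `y1`, `whale_id`, `first_id`,
#'   `second_id`, `click_index`.
#' @export
link_adjacent <- function(x, gap_s = 8) {
  assert_ordered(x, "link_adjacent()")
  seqs <- call_sequences(x, gap_s = gap_s)
  sid <- seqs$sequence_id[match(x$coda_id, seqs$coda_id)]
  ord <- order(x$whale_id, x$onset_time_s)
  out <- list()
  for (p in seq_len(length(ord) - 1)) {
    i <- ord[p]; j <- ord[p + 1]
    if (x$whale_id[i] != x$whale_id[j] || sid[i] != sid[j]) next
    yi <- c(0, cumsum(x$ici[[i]])); yj <- c(0, cumsum(x$ici[[j]]))
    m <- min(length(yi), length(yj))
    out[[length(out) + 1L]] <- tibble::tibble(
      x0 = x$onset_time_s[i] + yi[1:m], y0 = yi[1:m],
      x1 = x$onset_time_s[j] + yj[1:m], y1 = yj[1:m],
      whale_id = x$whale_id[i], first_id = x$coda_id[i],
      second_id = x$coda_id[j], click_index = 1:m)
  }
  if (!length(out)) {
    return(tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), whale_id = character(),
                          first_id = character(), second_id = character(),
                          click_index = integer()))
  }
  do.call(rbind, out)
}

#' Draw an exchange plot
#'
#' @param x an ordered `coda_set`.
#' @param from,to time window in seconds (defaults to the full
#'   recording); aborts if the window contains no coda.
#' @param link draw lines connecting matching clicks of adjacent codas?
#' @param ornaments optional [detect_ornaments()] result; flagged final
#'   clicks are drawn as open triangles.
#' @return a ggplot object.
#' @export
plot_exchange <- function(x, from = NULL, to = NULL, link = FALSE,
                          ornaments = NULL) {
  coords <- exchange_coordinates(x)
  from <- from %||% min(coords$x)
  to <- to %||% max(coords$x)
  coords <- coords[coords$x >= from & coords$x <= to, ]
  if (!nrow(coords)) stop("the requested window contains no coda")
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = x, y = y,
                                            colour = whale_id)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time in exchange (s)", y = "time since coda onset (s)",
                  colour = "whale") +
    ggplot2::theme_minimal()
  if (link) {
    segs <- link_adjacent(x)
    segs <- segs[segs$x0 >= from & segs$x1 <= to, ]
    if (nrow(segs)) {
      p <- p + ggplot2::geom_segment(
        data = segs,
        ggplot2::aes(x = x0, y = y0, xend = x1,
                     yend = y1, colour = whale_id),
        linewidth = 0.2, alpha = 0.5, inherit.aes = FALSE)
    }
  }
  if (!is.null(ornaments)) {
    orn_ids <- ornaments$coda_id[ornaments$ornament]
    last_click <- coords[coords$coda_id %in% orn_ids, ]
    last_click <- do.call(rbind, lapply(split(last_click, last_click$coda_id),
                                        function(g) g[which.max(g$click_index), ]))
    if (!is.null(last_click) && nrow(last_click)) {
      p <- p + ggplot2::geom_point(data = last_click, shape = 2, size = 2.5,
                                   stroke = 0.8)
    }
  }
  p
}

#' Render an exchange plot to file
#'
#' @inheritParams plot_exchange
#' @param path output file; format from the extension (`.png`, `.pdf`,
#'   `.svg` where the platform supports it).
#' @param width,height,dpi device settings passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_exchange <- function(x, path, from = NULL, to = NULL, link = FALSE,
                            ornaments = NULL, width = 10, height = 4,
                            dpi = 150) {
  p <- plot_exchange(x, from, to, link, ornaments)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
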