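#' Labeled-segment tables
#'
#' The pipeline's central exchange format: one row per labeled interval on a
#' fiber, columns `fiber_id`, `channel` (DNA counterstain or a pulse label),
#' `start_kb`, `end_kb`. All intervals are half-open `[start, end)` in 0-based
#' kb fiber coordinates. Same-channel intervals on one fiber must be pairwise
#' disjoint; `merge = TRUE` coalesces overlapping or abutting ones.
#'
#' @param df data frame with the four columns above.
#' @param merge coalesce overlapping/abutting same-channel intervals.
#' @return a `segment_table` (a data frame).
#' @export
as_segment_table <- function(df, merge = FALSE) {
  need <- c("fiber_id", "channel", "start_kb", "end_kb")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_data("segment table needs columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  df$fiber_id <- as.character(df$fiber_id)
  df$channel <- as.character(df$channel)
  if (nrow(df)) {
    if (anyNA(df) || any(!is.finite(df$start_kb)) || any(!is.finite(df$end_kb)))
      stop_data("segment table contains missing or non-finite values")
    if (any(df$start_kb >= df$end_kb))
      stop_data("segment intervals must satisfy start_kb < end_kb")
    df <- df[order(df$fiber_id, df$channel, df$start_kb), , drop = FALSE]
    if (merge) df <- merge_segments(df)
    # disjointness within fiber x channel
    by <- paste(df$fiber_id, df$channel, sep = "\r")
    for (g in split(seq_len(nrow(df)), by)) {
      if (length(g) > 1L) {
        s <- df$start_kb[g]; e <- df$end_kb[g]
        if (any(s[-1] < e[-length(e)] - 1e-9))
          stop_data("overlapping same-channel segments on fiber '%s'",
                    df$fiber_id[g[1]])
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

merge_segments <- function(df, tol = 1e-9) {
  by <- paste(df$fiber_id, df$channel, sep = "\r")
  out <- lapply(split(df, factor(by, unique(by))), function(g) {
    g <- g[order(g$start_kb), , drop = FALSE]
    keep_s <- g$start_kb[1]; keep_e <- g$end_kb[1]
    ss <- numeric(0); ee <- numeric(0)
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start_kb[i] <= keep_e + tol) {
        keep_e <- max(keep_e, g$end_kb[i])
      } else {
        ss <- c(ss, keep_s); ee <- c(ee, keep_e)
        keep_s <- g$start_kb[i]; keep_e <- g$end_kb[i]
      }
    }
    data.frame(fiber_id = g$fiber_id[1], channel = g$channel[1],
               start_kb = c(ss, keep_s), end_kb = c(ee, keep_e),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df[order(df$fiber_id, df$channel, df$start_kb), , drop = FALSE]
}

#' Per-fiber extent of a segment table
#'
#' Fiber extent is taken from the DNA counterstain when present (the assay's
#' definition of fiber continuity), otherwise from the span of all segments.
#'
#' @param segments a [segment_table].
#' @return data frame with columns `fiber_id`, `lo_kb`, `hi_kb`.
#' @export
fiber_extents <- function(segments) {
  out <- lapply(split(segments, factor(segments$fiber_id,
                                       unique(segments$fiber_id))), function(g) {
    d <- g[g$channel == "DNA", , drop = FALSE]
    if (nrow(d) == 0L) d <- g
    data.frame(fiber_id = g$fiber_id[1], lo_kb = min(d$start_kb),
               hi_kb = max(d$end_kb), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write / read segment tables (TSV, 3-decimal fixed point kb)
#'
#' @param segments a [segment_table].
#' @param path TSV path.
#' @return `write_segments` returns `path` invisibly; `read_segments` a
#'   [segment_table].
#' @export
write_segments <- function(segments, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_data("directory does not exist for path '%s'", path)
  df <- as.data.frame(segments)
  df$start_kb <- fmt_kb(df$start_kb)
  df$end_kb <- fmt_kb(df$end_kb)
  write_tsv(df, path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- read_tsv(path, colClasses = c(fiber_id = "character"))
  as_segment_table(df)
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("segment_table: %d segments on %d fibers (%s)\n",
              nrow(x), length(unique(x$fiber_id)),
              paste(sort(unique(x$channel)), collapse = ", ")))
  NextMethod()
}

#' Plot labeled fibers
#'
#' Draws each fiber as a horizontal line (DNA counterstain, grey) with its
#' label tracks as coloured bars (first pulse red, second pulse green, the
#' conventional rendering of combing images).
#'
#' @param x a [segment_table].
#' @param max_fibers draw at most this many fibers.
#' @param protocol a [labeling_protocol()] naming the pulse channels.
#' @param ... unused.
#' @export
plot.segment_table <- function(x, max_fibers = 25,
                               protocol = labeling_protocol(), ...) {
  ids <- utils::head(unique(x$fiber_id), max_fibers)
  x <- x[x$fiber_id %in% ids, , drop = FALSE]
  n <- length(ids)
  graphics::plot(NULL, xlim = c(0, max(x$end_kb)), ylim = c(0.5, n + 0.5),
                 xlab = "fiber position (kb)", ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_len(n), labels = ids, las = 2, cex.axis = 0.6)
  cols <- stats::setNames(c("grey70", "firebrick", "forestgreen"),
                          c("DNA", protocol$pulse1_label, protocol$pulse2_label))
  for (i in seq_len(n)) {
    g <- x[x$fiber_id == ids[i], , drop = FALSE]
    h <- ifelse(g$channel == "DNA", 0.08, 0.28)
    graphics::rect(g$start_kb, i - h, g$end_kb, i + h,
                   col = cols[g$channel], border = NA)
  }
  invisible(x)
}
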