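#' Detection configuration
#'
#' Parameters of the 1-D track detector: per-channel thresholding method
#' (Otsu on the column-max projection, or a fixed intensity), gap merging
#' (same-channel runs separated by less than `max_gap_kb` are fused, bridging
#' speckle dropouts) and a minimum track length filter.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold; required when
#'   `threshold_method = "fixed"`, and used as the fallback when Otsu
#'   degenerates (channel dynamic range below twice the background sd).
#' @param min_segment_kb drop detected runs shorter than this (kb).
#' @param max_gap_kb merge same-channel runs separated by less than this (kb).
#' @param kb_per_px scale override when image metadata lacks one.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(threshold_method = c("otsu", "fixed"),
                          fixed_threshold = NULL,
                          min_segment_kb = 1,
                          max_gap_kb = 0.5,
                          kb_per_px = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && !is_number(fixed_threshold))
    stop_config("fixed threshold_method requires a numeric fixed_threshold")
  if (!is_number(min_segment_kb) || min_segment_kb < 0)
    stop_config("min_segment_kb must be non-negative")
  if (!is_number(max_gap_kb) || max_gap_kb < 0)
    stop_config("max_gap_kb must be non-negative")
  if (!is.null(kb_per_px) && (!is_number(kb_per_px) || kb_per_px <= 0))
    stop_config("kb_per_px must be NULL or positive")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_segment_kb = min_segment_kb,
                 max_gap_kb = max_gap_kb,
                 kb_per_px = kb_per_px),
            class = "detect_config")
}

# Otsu's threshold on a numeric vector (256-bin histogram, maximises
# between-class variance); returns a cut strictly inside the range.
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  br[which.max(sb) + 1L]
}

#' Detect labeled segments in a fiber image strip
#'
#' Per channel: column-wise max projection, thresholding, 1-D connected runs,
#' gap merging, minimum-length filtering, and pixel-to-kb conversion. An
#' all-background channel yields no segments (not an error). The DNA channel
#' is detected like any other, providing the fiber extent downstream.
#'
#' @param image a `fiber_image` (from [render_fiber()] or
#'   [read_fiber_images()]).
#' @param config a [detect_config()].
#' @return a [segment_table] for this fiber.
#' @export
detect_segments <- function(image, config = detect_config()) {
  if (any(!is.finite(image))) stop_data("image contains non-finite pixels")
  s <- config$kb_per_px %||% attr(image, "kb_per_px")
  if (is.null(s))
    stop_data("image has no kb_per_px metadata; supply detect_config(kb_per_px=)")
  fiber_id <- attr(image, "fiber_id") %||% "fiber"
  chans <- dimnames(image)[[3]]
  rows <- list()
  for (ch in chans) {
    m <- image[, , ch, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    proj <- apply(m, 2, max)
    # Threshold level is learned from the full channel matrix: every column
    # contains background rows (the fiber band occupies a few central rows),
    # so the matrix is bimodal whenever signal exists, whereas the max
    # projection of a channel whose fiber spans the whole strip (DNA) is
    # all-signal. Background level and noise come from the strip's border
    # rows, which are outside the fiber band by construction.
    bd <- if (nrow(m) > 4) m[c(1:2, nrow(m) - 1:0), ] else m
    bg <- stats::median(bd)
    bg_sd <- stats::mad(bd)
    rng <- diff(range(m))
    thr <- if (rng > 0) otsu_threshold(as.numeric(m)) else NA_real_
    degenerate <- rng == 0 || rng < 2 * bg_sd ||
      (bg_sd > 0 && thr < bg + 2 * bg_sd)  # Otsu landed inside the noise
    if (config$threshold_method == "fixed" || degenerate) {
      thr <- config$fixed_threshold
      if (is.null(thr)) next  # no signal and no fallback: empty channel
    }
    r <- rle(proj > thr)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    iv <- cbind((starts[on] - 1) * s, ends[on] * s)
    # merge gaps shorter than max_gap_kb
    if (nrow(iv) > 1L) {
      keep <- list(iv[1, ])
      for (i in 2:nrow(iv)) {
        last <- keep[[length(keep)]]
        if (iv[i, 1] - last[2] < config$max_gap_kb)
          keep[[length(keep)]] <- c(last[1], iv[i, 2])
        else keep[[length(keep) + 1L]] <- iv[i, ]
      }
      iv <- do.call(rbind, keep)
    }
    iv <- iv[iv[, 2] - iv[, 1] >= config$min_segment_kb, , drop = FALSE]
    if (nrow(iv))
      rows[[length(rows) + 1L]] <- data.frame(
        fiber_id = fiber_id, channel = ch,
        start_kb = iv[, 1], end_kb = iv[, 2], stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiber_id = character(0), channel = character(0),
               start_kb = numeric(0), end_kb = numeric(0))
  as_segment_table(df)
}

#' @rdname detect_segments
#' @param images list of `fiber_image` strips.
#' @export
detect_all <- function(images, config = detect_config()) {
  tabs <- lapply(images, detect_segments, config = config)
  as_segment_table(do.call(rbind, lapply(tabs, as.data.frame)))
}

#' Match detected segments against ground truth
#'
#' Greedy one-to-one matching by decreasing overlap within each fiber and
#' channel; a candidate pair is accepted when both boundaries agree within
#' `tol_kb`. Summarises recovery as counts and the mean absolute boundary
#' error over matched pairs.
#'
#' @param detected,truth [segment_table]s over the same fiber set (detected
#'   fibers must be a subset of truth fibers).
#' @param tol_kb boundary tolerance (kb).
#' @return a `match_report`: list with `n_truth`, `n_detected`, `n_matched`,
#'   `boundary_mae_kb` and a per-pair `matches` data frame.
#' @export
match_to_truth <- function(detected, truth, tol_kb) {
  extra <- setdiff(unique(detected$fiber_id), unique(truth$fiber_id))
  if (length(extra))
    stop_data("detected fibers absent from truth: %s",
              paste(extra, collapse = ", "))
  det <- as.data.frame(detected); tru <- as.data.frame(truth)
  det$.id <- seq_len(nrow(det)); tru$.id <- seq_len(nrow(tru))
  pairs <- merge(det, tru, by = c("fiber_id", "channel"),
                 suffixes = c("_d", "_t"))
  if (nrow(pairs)) {
    pairs$overlap <- pmax(0, pmin(pairs$end_kb_d, pairs$end_kb_t) -
                             pmax(pairs$start_kb_d, pairs$start_kb_t))
    pairs <- pairs[pairs$overlap > 0, , drop = FALSE]
    pairs <- pairs[order(-pairs$overlap), , drop = FALSE]
  }
  used_d <- logical(nrow(det)); used_t <- logical(nrow(tru))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    di <- pairs$.id_d[i]; ti <- pairs$.id_t[i]
    if (used_d[di] || used_t[ti]) next
    if (abs(pairs$start_kb_d[i] - pairs$start_kb_t[i]) <= tol_kb &&
        abs(pairs$end_kb_d[i] - pairs$end_kb_t[i]) <= tol_kb) {
      keep[i] <- TRUE
      used_d[di] <- TRUE; used_t[ti] <- TRUE
    }
  }
  matches <- pairs[keep, c("fiber_id", "channel", "start_kb_t", "end_kb_t",
                           "start_kb_d", "end_kb_d"), drop = FALSE]
  rownames(matches) <- NULL
  mae <- if (nrow(matches))
    mean(c(abs(matches$start_kb_d - matches$start_kb_t),
           abs(matches$end_kb_d - matches$end_kb_t))) else NA_real_
  structure(list(n_truth = nrow(tru), n_detected = nrow(det),
                 n_matched = nrow(matches), boundary_mae_kb = mae,
                 matches = matches),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: %d/%d truth segments matched (%d detected), MAE %.4g kb\n",
              x$n_matched, x$n_truth, x$n_detected, x$boundary_mae_kb))
  invisible(x)
}
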