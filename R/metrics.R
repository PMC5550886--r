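#' Symmetry classification thresholds
#'
#' The three-way fork scoring scheme: a replication unit is symmetric when
#' the left/right speed difference is below `symmetric_below_pct` (default
#' 30), asymmetric between that and 100, and unidirectional at exactly 100,
#' i.e. when only one fork departs from the origin. The percent difference is
#' normalised by the faster fork, `|vL - vR| / max(vL, vR) * 100`, the only
#' normalisation under which "difference of 100%" coincides with an absent
#' partner fork.
#'
#' @param symmetric_below_pct symmetric/asymmetric cut (percent, exclusive).
#' @param unidirectional_at_pct fixed at 100.
#' @return a `symmetry_thresholds` object.
#' @export
symmetry_thresholds <- function(symmetric_below_pct = 30,
                                unidirectional_at_pct = 100) {
  if (!is_number(symmetric_below_pct) || symmetric_below_pct <= 0 ||
      symmetric_below_pct >= unidirectional_at_pct)
    stop_config("need 0 < symmetric_below_pct < unidirectional_at_pct")
  if (unidirectional_at_pct != 100)
    stop_config("unidirectional_at_pct is fixed at 100")
  structure(list(symmetric_below_pct = symmetric_below_pct,
                 unidirectional_at_pct = 100),
            class = "symmetry_thresholds")
}

#' Replication fork speed from labeled track lengths
#'
#' Implements the two measurement rules of the assay. When the second-label
#' (CldU) track is flanked by DNA counterstain, both labels measure the fork:
#' `(idu + cldu) / (pulse1 + pulse2)`. When the CldU track runs off the fiber
#' end (unflanked), its length is censored and the speed uses the first label
#' only: `idu / pulse1`. Vectorised.
#'
#' @param idu_len_kb first-label track length (kb), must be > 0.
#' @param cldu_len_kb second-label track length (kb), 0 if absent.
#' @param cldu_flanked logical: CldU distal end abuts counterstain, not the
#'   fiber end.
#' @param protocol a [labeling_protocol()].
#' @return fork speed in kb/min.
#' @export
fork_speed <- function(idu_len_kb, cldu_len_kb = 0, cldu_flanked = FALSE,
                       protocol = labeling_protocol()) {
  if (any(is.na(idu_len_kb)) || any(idu_len_kb <= 0))
    stop_data("idu_len_kb must be strictly positive")
  t1 <- protocol$pulse1_duration_min
  ifelse(cldu_flanked,
         (idu_len_kb + cldu_len_kb) / (t1 + protocol$pulse2_duration_min),
         idu_len_kb / t1)
}

#' Call individual forks from a segment table
#'
#' Every first-label (IdU) track spawns fork calls. A second-label (CldU)
#' track adjacent on one side (gap at most `adjacency_tol_kb`) orients the
#' fork toward it; CldU on both sides is the contiguous-origin pattern and
#' splits the IdU block at its midpoint into two diverging forks; an IdU
#' track with no adjacent CldU has no direction basis and is recorded as an
#' unclassifiable fork (speed `NA`, possibly rescued by unit pairing);
#' CldU-only tracks produce no call. `cldu_flanked` is true when the CldU
#' distal boundary lies at least `end_margin_kb` inside the fiber extent.
#'
#' @param segments a [segment_table] (DNA rows define fiber extents).
#' @param protocol a [labeling_protocol()].
#' @param adjacency_tol_kb maximum IdU-CldU gap for pairing (kb).
#' @param end_margin_kb minimum distance from the fiber end for a boundary to
#'   count as counterstain-flanked (kb).
#' @return a `fork_calls` data frame.
#' @export
call_forks <- function(segments, protocol = labeling_protocol(),
                       adjacency_tol_kb = 1, end_margin_kb = 2) {
  ext <- fiber_extents(segments)
  out <- list()
  for (fi in seq_len(nrow(ext))) {
    fid <- ext$fiber_id[fi]; lo <- ext$lo_kb[fi]; hi <- ext$hi_kb[fi]
    g <- segments[segments$fiber_id == fid, , drop = FALSE]
    idu <- g[g$channel == protocol$pulse1_label, , drop = FALSE]
    cld <- g[g$channel == protocol$pulse2_label, , drop = FALSE]
    idu <- idu[order(idu$start_kb), , drop = FALSE]
    cld <- cld[order(cld$start_kb), , drop = FALSE]
    cld_used <- logical(nrow(cld))
    mk <- function(direction, is0, ie0, ci) {
      cs <- if (is.na(ci)) NA_real_ else cld$start_kb[ci]
      ce <- if (is.na(ci)) NA_real_ else cld$end_kb[ci]
      clen <- if (is.na(ci)) 0 else ce - cs
      flank <- if (is.na(ci)) FALSE
               else if (direction == "leftward") (cs - lo) >= end_margin_kb
               else (hi - ce) >= end_margin_kb
      speed <- if (is.na(direction)) NA_real_
               else fork_speed(ie0 - is0, clen, flank, protocol)
      data.frame(fiber_id = fid, unit_id = NA_character_,
                 direction = direction,
                 idu_start_kb = is0, idu_end_kb = ie0,
                 idu_len_kb = ie0 - is0, cldu_len_kb = clen,
                 cldu_start_kb = cs, cldu_end_kb = ce,
                 cldu_flanked = flank, speed_kb_min = speed,
                 pair_id = NA_character_, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(idu))) {
      is0 <- idu$start_kb[i]; ie0 <- idu$end_kb[i]
      lc <- which(!cld_used & cld$start_kb < is0 &
                    (is0 - cld$end_kb) <= adjacency_tol_kb &
                    cld$end_kb <= is0 + adjacency_tol_kb)
      lc <- if (length(lc)) lc[which.max(cld$end_kb[lc])] else NA_integer_
      rc <- which(!cld_used & cld$end_kb > ie0 &
                    (cld$start_kb - ie0) <= adjacency_tol_kb &
                    cld$start_kb >= ie0 - adjacency_tol_kb)
      rc <- if (length(rc)) rc[which.min(cld$start_kb[rc])] else NA_integer_
      if (!is.na(lc)) cld_used[lc] <- TRUE
      if (!is.na(rc)) cld_used[rc] <- TRUE
      if (!is.na(lc) && !is.na(rc)) {
        mid <- (is0 + ie0) / 2
        fl <- mk("leftward", is0, mid, lc)
        fr <- mk("rightward", mid, ie0, rc)
        fl$pair_id <- fr$pair_id <- sprintf("%s.p%d", fid, i)
        out[[length(out) + 1L]] <- rbind(fl, fr)
      } else if (!is.na(lc)) {
        out[[length(out) + 1L]] <- mk("leftward", is0, ie0, lc)
      } else if (!is.na(rc)) {
        out[[length(out) + 1L]] <- mk("rightward", is0, ie0, rc)
      } else {
        out[[length(out) + 1L]] <- mk(NA_character_, is0, ie0, NA_integer_)
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(fiber_id = character(0), unit_id = character(0),
               direction = character(0), idu_start_kb = numeric(0),
               idu_end_kb = numeric(0), idu_len_kb = numeric(0),
               cldu_len_kb = numeric(0), cldu_start_kb = numeric(0),
               cldu_end_kb = numeric(0), cldu_flanked = logical(0),
               speed_kb_min = numeric(0), pair_id = character(0))
  rownames(df) <- NULL
  class(df) <- c("fork_calls", "data.frame")
  attr(df, "protocol") <- protocol
  df
}

# proximal (origin-side) IdU boundary of a fork call
proximal_kb <- function(fork_row) {
  if (identical(fork_row$direction, "leftward")) fork_row$idu_end_kb
  else fork_row$idu_start_kb
}

#' Group fork calls into replication units
#'
#' Pairing rules, applied per fiber left to right (greedy): (a) the two
#' halves of a midpoint-split contiguous-origin pattern form a unit; (b) a
#' leftward fork followed by a rightward fork diverging across an unlabeled
#' gap of at most `origin_gap_max_kb` form a unit -- a directionless fork
#' (IdU with no CldU, e.g. stalled during pulse 1) may be rescued into such a
#' pair, taking its direction from the geometry and an IdU-only speed; (c) a
#' lone fork whose origin-proximal boundary is flanked by counterstain (at
#' least `end_margin_kb` from the fiber end) is a one-fork unit, the
#' signature of a unidirectional origin; (d) a lone fork at the fiber end is
#' censored (unclassifiable), as are directionless forks that no rule
#' orients.
#'
#' @param forks a `fork_calls` data frame from [call_forks()].
#' @param segments the [segment_table] the forks were called from.
#' @param protocol a [labeling_protocol()].
#' @param origin_gap_max_kb largest unlabeled gap bridged by rule (b).
#' @param end_margin_kb counterstain margin of rules (c)/(d).
#' @param thresholds a [symmetry_thresholds()].
#' @return a `unit_calls` data frame: one row per replication unit with
#'   columns `fiber_id`, `unit_id`, `v_left`, `v_right`,
#'   `percent_difference`, `sym_class` (symmetric, asymmetric,
#'   unidirectional or unclassifiable) and `n_forks`.
#' @export
group_units <- function(forks, segments, protocol = labeling_protocol(),
                        origin_gap_max_kb = 200, end_margin_kb = 2,
                        thresholds = symmetry_thresholds()) {
  ext <- fiber_extents(segments)
  lab <- segments[segments$channel != "DNA", , drop = FALSE]
  units <- list()
  forks$unit_id <- NA_character_
  add_unit <- function(fid, vl, vr, n_forks, class_override = NULL) {
    nm <- names(units)
    if (is.null(nm)) nm <- character(0)
    uid <- sprintf("%s.u%d", fid, sum(startsWith(nm, paste0(fid, ".u"))) + 1L)
    cls <- if (!is.null(class_override)) {
      data.frame(percent_difference = NA_real_, sym_class = class_override)
    } else classify_symmetry(vl, vr, thresholds)
    units[[uid]] <<- data.frame(
      fiber_id = fid, unit_id = uid,
      v_left = vl, v_right = vr,
      percent_difference = cls$percent_difference,
      sym_class = cls$sym_class, n_forks = n_forks,
      stringsAsFactors = FALSE)
    uid
  }
  gap_unlabeled <- function(fid, a, b) {
    s <- lab[lab$fiber_id == fid, , drop = FALSE]
    !any(s$start_kb < b - 1e-9 & s$end_kb > a + 1e-9)
  }
  for (fi in seq_len(nrow(ext))) {
    fid <- ext$fiber_id[fi]; lo <- ext$lo_kb[fi]; hi <- ext$hi_kb[fi]
    idx <- which(forks$fiber_id == fid)
    if (!length(idx)) next
    f <- forks[idx, , drop = FALSE]
    # (a) midpoint-split pairs
    for (p in unique(stats::na.omit(f$pair_id))) {
      pr <- which(f$pair_id %in% p)
      l <- pr[f$direction[pr] == "leftward"]; r <- pr[f$direction[pr] == "rightward"]
      uid <- add_unit(fid, f$speed_kb_min[l], f$speed_kb_min[r], 2L)
      forks$unit_id[idx[pr]] <- uid
    }
    rem <- which(is.na(f$pair_id))
    rem <- rem[order(f$idu_start_kb[rem])]
    k <- 1L
    lone <- integer(0)
    while (k <= length(rem)) {
      i1 <- rem[k]
      paired <- FALSE
      if (k < length(rem)) {
        i2 <- rem[k + 1L]
        d1 <- f$direction[i1]; d2 <- f$direction[i2]
        ok_dir <- (identical(d1, "leftward") || is.na(d1)) &&
                  (identical(d2, "rightward") || is.na(d2))
        if (ok_dir) {
          p1 <- f$idu_end_kb[i1]; p2 <- f$idu_start_kb[i2]
          gap <- p2 - p1
          if (gap >= -1e-9 && gap <= origin_gap_max_kb &&
              gap_unlabeled(fid, p1, p2)) {
            if (is.na(d1) && is.na(d2)) {
              # two directionless tracks across one gap: a single unit whose
              # orientation cannot be scored (both forks lack a second label)
              uid <- add_unit(fid, NA_real_, NA_real_, 2L, "unclassifiable")
              forks$unit_id[idx[c(i1, i2)]] <- uid
              paired <- TRUE
              k <- k + 2L
              next
            }
            # rescue directionless partner: orientation from the geometry,
            # IdU-only speed (its CldU is absent)
            for (ii in c(i1, i2)) {
              if (is.na(f$direction[ii])) {
                f$direction[ii] <- if (ii == i1) "leftward" else "rightward"
                f$speed_kb_min[ii] <-
                  fork_speed(f$idu_len_kb[ii], 0, FALSE, protocol)
                forks$direction[idx[ii]] <- f$direction[ii]
                forks$speed_kb_min[idx[ii]] <- f$speed_kb_min[ii]
              }
            }
            uid <- add_unit(fid, f$speed_kb_min[i1], f$speed_kb_min[i2], 2L)
            forks$unit_id[idx[c(i1, i2)]] <- uid
            paired <- TRUE
          }
        }
      }
      if (paired) k <- k + 2L else { lone <- c(lone, i1); k <- k + 1L }
    }
    for (i1 in lone) {
      d1 <- f$direction[i1]
      if (is.na(d1)) {
        uid <- add_unit(fid, NA_real_, NA_real_, 1L, "unclassifiable")
      } else {
        prox <- if (d1 == "leftward") f$idu_end_kb[i1] else f$idu_start_kb[i1]
        internal <- if (d1 == "leftward") (hi - prox) >= end_margin_kb
                    else (prox - lo) >= end_margin_kb
        if (internal) {
          # one-fork unit: the partner never departed (speed 0)
          vl <- if (d1 == "leftward") f$speed_kb_min[i1] else NA_real_
          vr <- if (d1 == "rightward") f$speed_kb_min[i1] else NA_real_
          uid <- add_unit(fid, vl, vr, 1L)
        } else {
          uid <- add_unit(fid, NA_real_, NA_real_, 1L, "unclassifiable")
        }
      }
      forks$unit_id[idx[i1]] <- uid
    }
  }
  udf <- if (length(units)) do.call(rbind, units) else
    data.frame(fiber_id = character(0), unit_id = character(0),
               v_left = numeric(0), v_right = numeric(0),
               percent_difference = numeric(0), sym_class = character(0),
               n_forks = integer(0))
  rownames(udf) <- NULL
  class(udf) <- c("unit_calls", "data.frame")
  attr(udf, "forks") <- forks
  udf
}

#' Classify replication-unit symmetry
#'
#' Percent difference is `|vL - vR| / max(vL, vR) * 100` (the absent partner
#' of a one-fork unit counts as speed 0, giving 100). Classes: below
#' `symmetric_below_pct` symmetric; from there up to (excluding) 100
#' asymmetric; unidirectional is the structural one-fork case, never a
#' floating-point equality test.
#'
#' @param v_left,v_right fork speeds (kb/min); `NA` marks an absent fork.
#' @param thresholds a [symmetry_thresholds()].
#' @return data frame with `percent_difference` and `sym_class`.
#' @export
classify_symmetry <- function(v_left, v_right,
                              thresholds = symmetry_thresholds()) {
  n <- max(length(v_left), length(v_right))
  v_left <- rep_len(v_left, n); v_right <- rep_len(v_right, n)
  if (any(is.na(v_left) & is.na(v_right)))
    stop_data("cannot classify a unit with zero forks")
  one <- is.na(v_left) | is.na(v_right)
  d <- ifelse(one, 100,
              abs(v_left - v_right) / pmax(v_left, v_right) * 100)
  cls <- ifelse(one, "unidirectional",
                ifelse(d < thresholds$symmetric_below_pct, "symmetric",
                       "asymmetric"))
  data.frame(percent_difference = d, sym_class = cls,
             stringsAsFactors = FALSE)
}

#' One-step fork and unit measurement
#'
#' Convenience wrapper running [call_forks()] then [group_units()].
#'
#' @inheritParams call_forks
#' @inheritParams group_units
#' @return list with elements `forks` (unit ids filled in) and `units`.
#' @export
measure_segments <- function(segments, protocol = labeling_protocol(),
                             adjacency_tol_kb = 1, origin_gap_max_kb = 200,
                             end_margin_kb = 2,
                             thresholds = symmetry_thresholds()) {
  forks <- call_forks(segments, protocol, adjacency_tol_kb, end_margin_kb)
  units <- group_units(forks, segments, protocol, origin_gap_max_kb,
                       end_margin_kb, thresholds)
  list(forks = attr(units, "forks"), units = units)
}

#' Write / read fork and unit tables (TSV)
#'
#' @param forks,units outputs of [measure_segments()].
#' @param path TSV path.
#' @name fork_tables
#' @export
write_forks <- function(forks, path) {
  df <- as.data.frame(forks)[c("fiber_id", "unit_id", "direction",
                               "idu_len_kb", "cldu_len_kb", "cldu_flanked",
                               "speed_kb_min")]
  df$idu_len_kb <- fmt_kb(df$idu_len_kb)
  df$cldu_len_kb <- fmt_kb(df$cldu_len_kb)
  write_tsv(df, path)
}

#' @rdname fork_tables
#' @export
read_forks <- function(path) read_tsv(path, colClasses = c(fiber_id = "character"))

#' @rdname fork_tables
#' @export
write_units <- function(units, path) {
  df <- as.data.frame(units)[c("fiber_id", "unit_id", "v_left", "v_right",
                               "percent_difference", "sym_class", "n_forks")]
  write_tsv(df, path)
}

#' @rdname fork_tables
#' @export
read_units <- function(path) read_tsv(path, colClasses = c(fiber_id = "character"))
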