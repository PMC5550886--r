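#' Simulation configuration for combed-fiber ground truth
#'
#' Parameterises the stochastic fiber model: fibers of given length carry
#' replication origins (Poisson along the fiber) which fire at a uniform time
#' within `firing_time_window_min` (relative to the start of pulse 1; negative
#' times mean the origin fired before labeling). Each origin launches two
#' divergent forks with independently drawn speeds. A fork is "dead before
#' labeling" with probability `p_dead` (it never produces any labeled track,
#' the source of unidirectional patterns); otherwise it may stall permanently
#' during labeling with exponential hazard `stall_rate_per_min` (the source of
#' asymmetric patterns).
#'
#' @param n_fibers number of fibers to simulate.
#' @param fiber_length_kb a [dist_spec] (or single number) for fiber length.
#' @param origin_rate_per_kb Poisson intensity of origins per kb.
#' @param firing_time_window_min length-2 numeric, uniform window of firing
#'   times in minutes relative to pulse-1 start (may be negative).
#' @param speed_kb_min a [dist_spec] for fork speed (kb/min, truncated > 0).
#' @param p_dead probability a fork is permanently stalled before labeling.
#' @param stall_rate_per_min hazard (1/min) of permanent stalling during
#'   labeling; 0 means forks never stall.
#' @param min_origin_sep_kb minimum distance between origins on one fiber;
#'   `NULL` (default) uses 2 x speed_max x total pulse time so that labeled
#'   tracks of neighbouring units cannot collide.
#' @param origin_edge_margin_kb keep origins at least this far from both fiber
#'   ends (a fiber-inclusion-style criterion; 0 places origins anywhere).
#' @param seed integer RNG seed making [sample_fibers()] deterministic.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_fibers,
                              fiber_length_kb,
                              origin_rate_per_kb,
                              firing_time_window_min = c(-20, 0),
                              speed_kb_min = dist_normal(1.5, 0.2),
                              p_dead = 0,
                              stall_rate_per_min = 0,
                              min_origin_sep_kb = NULL,
                              origin_edge_margin_kb = 0,
                              seed = NULL) {
  if (!is_count(n_fibers)) stop_config("n_fibers must be a non-negative integer")
  fiber_length_kb <- as_dist_spec(fiber_length_kb, "fiber_length_kb")
  speed_kb_min <- as_dist_spec(speed_kb_min, "speed_kb_min")
  if (!is_number(origin_rate_per_kb) || origin_rate_per_kb < 0)
    stop_config("origin_rate_per_kb must be a non-negative number")
  if (!is.numeric(firing_time_window_min) || length(firing_time_window_min) != 2L ||
      anyNA(firing_time_window_min) ||
      firing_time_window_min[1] > firing_time_window_min[2])
    stop_config("firing_time_window_min must be c(lo, hi) with lo <= hi")
  if (!is_number(p_dead) || p_dead < 0 || p_dead > 1)
    stop_config("p_dead must lie in [0, 1]")
  if (!is_number(stall_rate_per_min) || stall_rate_per_min < 0)
    stop_config("stall_rate_per_min must be a non-negative number")
  if (!is.null(min_origin_sep_kb) &&
      (!is_number(min_origin_sep_kb) || min_origin_sep_kb < 0))
    stop_config("min_origin_sep_kb must be NULL or a non-negative number")
  if (!is_number(origin_edge_margin_kb) || origin_edge_margin_kb < 0)
    stop_config("origin_edge_margin_kb must be a non-negative number")
  if (!is.null(seed) && !is_count(seed))
    stop_config("seed must be NULL or a non-negative integer")
  structure(list(n_fibers = as.integer(n_fibers),
                 fiber_length_kb = fiber_length_kb,
                 origin_rate_per_kb = origin_rate_per_kb,
                 firing_time_window_min = as.numeric(firing_time_window_min),
                 speed_kb_min = speed_kb_min,
                 p_dead = p_dead,
                 stall_rate_per_min = stall_rate_per_min,
                 min_origin_sep_kb = min_origin_sep_kb,
                 origin_edge_margin_kb = origin_edge_margin_kb,
                 seed = seed),
            class = "simulation_config")
}

new_fork_truth <- function(speed_kb_min, stall_time_min) {
  stopifnot(speed_kb_min > 0)
  list(speed_kb_min = speed_kb_min, stall_time_min = stall_time_min)
}

#' Construct a replication-unit ground truth
#'
#' One origin with its two divergent forks. `stall_time_min` of a fork is the
#' minute (from pulse-1 start) at which it permanently stops: `-Inf` encodes a
#' fork dead before labeling, `Inf` a fork that never stalls.
#'
#' @param origin_pos_kb origin coordinate on the fiber (kb).
#' @param t_fire_min firing time, minutes relative to pulse-1 start.
#' @param left_speed,right_speed fork speeds (kb/min, > 0).
#' @param left_stall,right_stall permanent stall times (min).
#' @return a `replication_unit_truth` list.
#' @export
replication_unit <- function(origin_pos_kb, t_fire_min,
                             left_speed, right_speed,
                             left_stall = Inf, right_stall = Inf) {
  if (left_speed <= 0 || right_speed <= 0)
    stop_config("fork speeds must be strictly positive")
  structure(list(origin_pos_kb = origin_pos_kb,
                 t_fire_min = t_fire_min,
                 left_fork = new_fork_truth(left_speed, left_stall),
                 right_fork = new_fork_truth(right_speed, right_stall)),
            class = "replication_unit_truth")
}

new_fiber_truth <- function(fiber_id, length_kb, units) {
  ord <- order(vapply(units, `[[`, numeric(1), "origin_pos_kb"))
  structure(list(fiber_id = fiber_id, length_kb = length_kb,
                 units = units[ord]),
            class = "fiber_truth")
}

# Place n origins uniformly on [lo, hi] with pairwise min separation.
# Redraws the whole set; if infeasible after max_try redraws, drops one
# origin and retries (keeps the count Poisson whenever feasible).
place_origins <- function(n, lo, hi, min_sep, max_try = 200L) {
  if (n <= 0L || hi < lo) return(numeric(0))
  while (n > 0L) {
    for (i in seq_len(max_try)) {
      pos <- sort(stats::runif(n, lo, hi))
      if (n == 1L || all(diff(pos) >= min_sep)) return(pos)
    }
    n <- n - 1L
  }
  numeric(0)
}

#' Simulate combed fibers with ground-truth replication units
#'
#' Draws `n_fibers` fibers per the configuration. Origin counts are Poisson
#' with mean `origin_rate_per_kb * length_kb`; origin positions are uniform
#' subject to the minimum-separation rule; firing times are uniform on the
#' firing window; fork speeds are independent draws; each fork is dead before
#' labeling with probability `p_dead`, otherwise its stall time is
#' exponential with rate `stall_rate_per_min` (`Inf` when the rate is 0).
#'
#' @param config a [simulation_config()].
#' @param protocol a [labeling_protocol()]; only the total pulse time enters
#'   (the default origin-separation rule).
#' @return list of `fiber_truth` objects (class `fiber_set`).
#' @export
sample_fibers <- function(config, protocol = labeling_protocol()) {
  if (!inherits(config, "simulation_config"))
    stop_config("'config' must be a simulation_config")
  total_min <- total_labeling_min(protocol)
  vmax <- dist_upper(config$speed_kb_min)
  min_sep <- config$min_origin_sep_kb %||% (2 * vmax * total_min)
  win <- config$firing_time_window_min
  margin <- config$origin_edge_margin_kb

  fibers <- with_seed(config$seed, {
    lapply(seq_len(config$n_fibers), function(i) {
      len <- sample_dist(config$fiber_length_kb, 1L)
      n_org <- stats::rpois(1L, config$origin_rate_per_kb * len)
      pos <- place_origins(n_org, margin, len - margin, min_sep)
      units <- lapply(pos, function(p) {
        t_fire <- stats::runif(1L, win[1], win[2])
        speeds <- sample_dist(config$speed_kb_min, 2L)
        stalls <- vapply(1:2, function(j) {
          if (stats::runif(1L) < config$p_dead) -Inf
          else if (config$stall_rate_per_min > 0)
            stats::rexp(1L, config$stall_rate_per_min)
          else Inf
        }, numeric(1))
        replication_unit(p, t_fire, speeds[1], speeds[2], stalls[1], stalls[2])
      })
      new_fiber_truth(sprintf("F%05d", i), len, units)
    })
  })
  structure(fibers, class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  n_units <- sum(vapply(x, function(f) length(f$units), integer(1)))
  cat(sprintf("fiber_set: %d fibers, %d replication units\n", length(x), n_units))
  invisible(x)
}

# Distance travelled by a fork by time t (minutes from pulse-1 start).
# Dead-before-labeling forks (stall = -Inf) travel 0 for all t >= 0.
fork_distance <- function(fork, t_fire, t) {
  fork$speed_kb_min * max(0, min(t, fork$stall_time_min) - t_fire)
}

#' Derive the labeled segments implied by the pulse scheme
#'
#' Computes, for one replication unit, the exact kb intervals marked by each
#' pulse: a fork active during pulse 1 sweeps its IdU interval, during pulse 2
#' its CldU interval. DNA replicated before pulse 1 is unlabeled; dead forks
#' contribute nothing; intervals are clipped to the fiber `[0, length)`.
#'
#' @param unit a [replication_unit()].
#' @param fiber_length_kb fiber length (kb).
#' @param protocol a [labeling_protocol()].
#' @param fiber_id fiber identifier stamped on the output rows.
#' @return a [segment_table] (possibly zero rows) with the unit's labeled
#'   intervals; no DNA counterstain row is included.
#' @export
apply_labeling <- function(unit, fiber_length_kb,
                           protocol = labeling_protocol(),
                           fiber_id = "fiber") {
  if (!inherits(unit, "replication_unit_truth"))
    stop_config("'unit' must be a replication_unit_truth")
  if (unit$origin_pos_kb < 0 || unit$origin_pos_kb > fiber_length_kb)
    stop_config("unit origin outside fiber [0, %g]", fiber_length_kb)
  t1 <- protocol$pulse1_duration_min
  t2 <- protocol$pulse2_duration_min
  rows <- list()
  for (side in c("left", "right")) {
    fork <- unit[[paste0(side, "_fork")]]
    d <- vapply(c(0, t1, t1 + t2), function(t)
      fork_distance(fork, unit$t_fire_min, t), numeric(1))
    for (k in 1:2) {
      lo <- d[k]; hi <- d[k + 1]
      if (hi <= lo) next
      iv <- if (side == "right") c(unit$origin_pos_kb + lo, unit$origin_pos_kb + hi)
            else c(unit$origin_pos_kb - hi, unit$origin_pos_kb - lo)
      iv[1] <- max(0, iv[1]); iv[2] <- min(fiber_length_kb, iv[2])
      if (iv[1] >= iv[2]) next
      chan <- if (k == 1L) protocol$pulse1_label else protocol$pulse2_label
      rows[[length(rows) + 1L]] <- data.frame(
        fiber_id = fiber_id, channel = chan,
        start_kb = iv[1], end_kb = iv[2], stringsAsFactors = FALSE)
    }
  }
  seg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiber_id = character(0), channel = character(0),
               start_kb = numeric(0), end_kb = numeric(0))
  as_segment_table(seg, merge = FALSE)
}

#' Observable segment table of a simulated fiber set
#'
#' Applies the labeling geometry to every unit of every fiber and returns the
#' observable per-fiber segment table: one DNA counterstain interval spanning
#' each whole fiber plus merged, per-channel label intervals (abutting
#' same-channel intervals, e.g. the two IdU arms of an origin fired during
#' pulse 1, coalesce into the single track a microscope would show).
#'
#' @param fibers a `fiber_set` from [sample_fibers()].
#' @param protocol a [labeling_protocol()].
#' @return a [segment_table].
#' @export
truth_segments <- function(fibers, protocol = labeling_protocol()) {
  tabs <- lapply(fibers, function(f) {
    segs <- lapply(f$units, apply_labeling, fiber_length_kb = f$length_kb,
                   protocol = protocol, fiber_id = f$fiber_id)
    dna <- data.frame(fiber_id = f$fiber_id, channel = "DNA",
                      start_kb = 0, end_kb = f$length_kb,
                      stringsAsFactors = FALSE)
    do.call(rbind, c(list(dna), segs))
  })
  as_segment_table(do.call(rbind, tabs), merge = TRUE)
}

#' Write / read ground-truth fiber tables
#'
#' Lossless TSV round-trip of a `fiber_set`: one row per fork (columns
#' fiber_id, length_kb, unit_id, origin_pos_kb, t_fire_min, side, speed_kb_min,
#' stall_time_min); fibers without units keep a single row with NA fields so
#' that empty fibers survive the round trip.
#'
#' @param fibers a `fiber_set`.
#' @param path output (for `export_truth`) or input (for `read_truth`) TSV.
#' @return `export_truth` returns `path` invisibly; `read_truth` a `fiber_set`.
#' @export
export_truth <- function(fibers, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_data("directory does not exist for path '%s'", path)
  rows <- lapply(fibers, function(f) {
    if (length(f$units) == 0L)
      return(data.frame(fiber_id = f$fiber_id, length_kb = f$length_kb,
                        unit_id = NA_character_, origin_pos_kb = NA_real_,
                        t_fire_min = NA_real_, side = NA_character_,
                        speed_kb_min = NA_real_, stall_time_min = NA_real_,
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(seq_along(f$units), function(i) {
      u <- f$units[[i]]
      data.frame(fiber_id = f$fiber_id, length_kb = f$length_kb,
                 unit_id = sprintf("%s.U%d", f$fiber_id, i),
                 origin_pos_kb = u$origin_pos_kb, t_fire_min = u$t_fire_min,
                 side = c("L", "R"),
                 speed_kb_min = c(u$left_fork$speed_kb_min,
                                  u$right_fork$speed_kb_min),
                 stall_time_min = c(u$left_fork$stall_time_min,
                                    u$right_fork$stall_time_min),
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(fiber_id = character(0), length_kb = numeric(0),
                     unit_id = character(0), origin_pos_kb = numeric(0),
                     t_fire_min = numeric(0), side = character(0),
                     speed_kb_min = numeric(0), stall_time_min = numeric(0))
  write_tsv(df, path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  df <- read_tsv(path, colClasses = c(fiber_id = "character"))
  need <- c("fiber_id", "length_kb", "unit_id", "origin_pos_kb", "t_fire_min",
            "side", "speed_kb_min", "stall_time_min")
  if (!all(need %in% names(df)))
    stop_data("truth table '%s' missing columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  fibers <- lapply(split(df, factor(df$fiber_id, unique(df$fiber_id))), function(fd) {
    ud <- fd[!is.na(fd$unit_id), , drop = FALSE]
    units <- lapply(split(ud, factor(ud$unit_id, unique(ud$unit_id))), function(u) {
      l <- u[u$side == "L", ]; r <- u[u$side == "R", ]
      replication_unit(l$origin_pos_kb[1], l$t_fire_min[1],
                       l$speed_kb_min, r$speed_kb_min,
                       l$stall_time_min, r$stall_time_min)
    })
    new_fiber_truth(fd$fiber_id[1], fd$length_kb[1], unname(units))
  })
  structure(unname(fibers), class = "fiber_set")
}
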