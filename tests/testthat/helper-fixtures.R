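# Shared fixtures and independent oracles.

proto <- labeling_protocol()  # IdU 30 min -> CldU 30 min

seg_tab <- function(...) {
  # seg_tab("F1", "IdU", 60, 90, "F1", "CldU", 30, 60)
  v <- list(...)
  stopifnot(length(v) %% 4 == 0)
  idx <- seq(1, length(v), by = 4)
  as_segment_table(data.frame(
    fiber_id = vapply(idx, function(i) as.character(v[[i]]), ""),
    channel = vapply(idx, function(i) as.character(v[[i + 1]]), ""),
    start_kb = vapply(idx, function(i) as.numeric(v[[i + 2]]), 0),
    end_kb = vapply(idx, function(i) as.numeric(v[[i + 3]]), 0),
    stringsAsFactors = FALSE))
}

# Add a DNA counterstain row spanning [0, len) to a label-only table.
with_dna <- function(tab, len, fiber_id = tab$fiber_id[1]) {
  as_segment_table(rbind(as.data.frame(tab),
                         data.frame(fiber_id = fiber_id, channel = "DNA",
                                    start_kb = 0, end_kb = len)))
}

# Analytic label lengths of one fork of a truth unit (independent of the
# segment machinery): distance travelled inside each pulse window.
fork_label_lengths <- function(fork, t_fire, protocol = proto) {
  t1 <- protocol$pulse1_duration_min
  t2 <- protocol$pulse2_duration_min
  s <- function(t) fork$speed_kb_min *
    max(0, min(t, fork$stall_time_min) - t_fire)
  c(idu = s(t1) - s(0), cldu = s(t1 + t2) - s(t1), pre = s(0))
}

# Brute-force classifier applied to ForkTruth pairs: reproduces the assay's
# scoring rules (flanked / IdU-only speeds, orientation observability) from
# the analytic lengths, assuming uncensored fibers (origins fired pre-pulse,
# tracks away from fiber ends). Returns NA when the unit yields no call,
# otherwise one of the class labels.
truth_class_oracle <- function(unit, protocol = proto,
                               thresholds = symmetry_thresholds()) {
  ll <- fork_label_lengths(unit$left_fork, unit$t_fire_min, protocol)
  rr <- fork_label_lengths(unit$right_fork, unit$t_fire_min, protocol)
  t1 <- protocol$pulse1_duration_min
  tot <- t1 + protocol$pulse2_duration_min
  spd <- function(l) if (l["cldu"] > 0) (l["idu"] + l["cldu"]) / tot
                     else l["idu"] / t1
  l_lab <- ll["idu"] > 0
  r_lab <- rr["idu"] > 0
  if (!l_lab && !r_lab) return(NA_character_)
  if (l_lab && r_lab) {
    if (ll["cldu"] == 0 && rr["cldu"] == 0) return("unclassifiable")
    vl <- spd(ll); vr <- spd(rr)
    d <- abs(vl - vr) / max(vl, vr) * 100
    return(if (d < thresholds$symmetric_below_pct) "symmetric" else "asymmetric")
  }
  lone <- if (l_lab) ll else rr
  if (lone["cldu"] > 0) "unidirectional" else "unclassifiable"
}

# Hand-coded two-sample statistics (pooled Student t, two-tailed p, Cohen's
# d); the reference the package implementation is tested against.
t_d_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2),
       d = (mean(a) - mean(b)) / sqrt(sp2))
}

chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  list(chi2 = chi2,
       p = stats::pchisq(chi2, (nrow(tab) - 1) * (ncol(tab) - 1),
                         lower.tail = FALSE))
}

# Stated-world simulation configs reused across tests: long fibers with
# origins kept one maximal track length away from both ends, so no label is
# clipped and every CldU track is counterstain-flanked.
uncensored_config <- function(n_fibers, seed, firing_window = c(-20, -5),
                              p_dead = 0, stall_rate = 0,
                              speed = dist_normal(1.5, 0.2)) {
  simulation_config(n_fibers, dist_fixed(700), 1 / 700,
                    firing_time_window_min = firing_window,
                    speed_kb_min = speed,
                    p_dead = p_dead, stall_rate_per_min = stall_rate,
                    origin_edge_margin_kb = 200, seed = seed)
}

# All ground-truth units of a fiber set, flattened.
all_units <- function(fibers) unlist(lapply(fibers, `[[`, "units"),
                                     recursive = FALSE)
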