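#' Summarize a fork population
#'
#' Counts and fractions of the symmetry classes over classifiable units
#' (symmetric + asymmetric + unidirectional; unclassifiable units are
#' reported separately, as the assay censors them) and moments of the fork
#' speed distribution over all forks with a valid speed.
#'
#' @param units a `unit_calls` data frame.
#' @param forks a `fork_calls` data frame.
#' @param label condition name.
#' @return a `condition_summary` list.
#' @export
summarize_condition <- function(units, forks, label = "condition") {
  classes <- c("symmetric", "asymmetric", "unidirectional")
  cls <- units$sym_class[units$sym_class %in% classes]
  counts <- vapply(classes, function(k) sum(cls == k), integer(1))
  fractions <- if (length(cls)) counts / length(cls) else
    stats::setNames(rep(NA_real_, 3), classes)
  speeds <- forks$speed_kb_min[!is.na(forks$speed_kb_min)]
  structure(list(label = label,
                 n_units = nrow(units),
                 n_classifiable = length(cls),
                 n_unclassifiable = sum(units$sym_class == "unclassifiable"),
                 n_forks = nrow(forks),
                 class_counts = counts,
                 class_fractions = fractions,
                 speed_mean = if (length(speeds)) mean(speeds) else NA_real_,
                 speed_sd = if (length(speeds) > 1) stats::sd(speeds) else NA_real_,
                 speed_n = length(speeds),
                 speeds = speeds),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition '%s': %d units (%d classifiable, %d censored), %d forks\n",
              x$label, x$n_units, x$n_classifiable, x$n_unclassifiable, x$n_forks))
  if (x$n_classifiable > 0) {
    fr <- sprintf("%s %.1f%%", names(x$class_counts),
                  100 * x$class_fractions)
    cat("  classes:", paste(fr, collapse = ", "), "\n")
  }
  cat(sprintf("  fork speed: mean %.3f kb/min, sd %.3f (n = %d)\n",
              x$speed_mean, x$speed_sd, x$speed_n))
  invisible(x)
}

#' Compare fork-speed populations of two conditions
#'
#' Equal-variance two-sample Student t-test (two-tailed p from the t
#' distribution with `nA + nB - 2` df; a Welch option is provided but off by
#' default) and Cohen's d in the pooled-SD form,
#' `d = (meanA - meanB) / sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA+nB-2))`,
#' so the sign of d follows the sign of `meanA - meanB`.
#'
#' @param speeds_a,speeds_b numeric vectors (each n >= 2, finite).
#' @param welch use the Welch (unequal-variance) t-test for t and p; d stays
#'   pooled.
#' @return a `speed_comparison` list with `t_stat`, `p_two_tailed`,
#'   `cohen_d`, `df`, group sizes and means.
#' @export
compare_speeds <- function(speeds_a, speeds_b, welch = FALSE) {
  if (length(speeds_a) < 2 || length(speeds_b) < 2)
    stop_data("each group needs at least 2 observations")
  if (!all(is.finite(speeds_a)) || !all(is.finite(speeds_b)))
    stop_data("speeds must be finite")
  na <- length(speeds_a); nb <- length(speeds_b)
  va <- stats::var(speeds_a); vb <- stats::var(speeds_b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  dm <- mean(speeds_a) - mean(speeds_b)
  if (sp2 == 0) {
    if (dm == 0) stop_data("undefined statistic: zero pooled variance and equal means")
    tt <- list(statistic = sign(dm) * Inf, p.value = 0,
               parameter = na + nb - 2)
  } else {
    tt <- stats::t.test(speeds_a, speeds_b, var.equal = !welch)
  }
  structure(list(t_stat = unname(tt$statistic),
                 p_two_tailed = tt$p.value,
                 cohen_d = if (sp2 > 0) dm / sqrt(sp2) else sign(dm) * Inf,
                 df = unname(tt$parameter),
                 welch = welch,
                 n_a = na, n_b = nb,
                 mean_a = mean(speeds_a), mean_b = mean(speeds_b)),
            class = "speed_comparison")
}

#' Compare symmetry-class proportions of two conditions
#'
#' Pearson chi-square (no continuity correction, 2 df) on the 2 x 3
#' contingency table of class counts.
#'
#' @param summary_a,summary_b [summarize_condition()] outputs (or bare
#'   3-vectors of class counts).
#' @return list with `chi2`, `p`, `df` and the table.
#' @export
compare_class_fractions <- function(summary_a, summary_b) {
  get_counts <- function(s)
    if (inherits(s, "condition_summary")) s$class_counts else as.numeric(s)
  tab <- rbind(a = get_counts(summary_a), b = get_counts(summary_b))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_data("degenerate contingency table: empty row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), table = tab)
}

#' Full two-condition comparison
#'
#' @param summary_a,summary_b [summarize_condition()] outputs; group A is
#'   conventionally the treatment so that a positive Cohen's d means faster
#'   forks in A.
#' @param welch passed to [compare_speeds()].
#' @return a `fork_comparison` list bundling the speed test and the
#'   class-proportion test.
#' @export
compare_conditions <- function(summary_a, summary_b, welch = FALSE) {
  sp <- compare_speeds(summary_a$speeds, summary_b$speeds, welch = welch)
  cl <- compare_class_fractions(summary_a, summary_b)
  structure(list(label_a = summary_a$label, label_b = summary_b$label,
                 speed = sp, classes = cl),
            class = "fork_comparison")
}

#' @export
print.fork_comparison <- function(x, ...) {
  cat(sprintf("Comparison: %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  speed: t = %.3f (df %.1f), two-tailed p = %.3g, Cohen's d = %.3f\n",
              x$speed$t_stat, x$speed$df, x$speed$p_two_tailed, x$speed$cohen_d))
  cat(sprintf("  classes: chi2 = %.3f (df %d), p = %.3g\n",
              x$classes$chi2, x$classes$df, x$classes$p))
  invisible(x)
}
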