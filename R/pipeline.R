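#' Load and validate a pipeline configuration
#'
#' YAML layout: a `seed`, a named `conditions:` map (each entry a
#' [simulation_config()] field list), optional `render:`, `detect:`,
#' `metrics:` (adjacency_tol_kb, origin_gap_max_kb, end_margin_kb,
#' symmetric_below_pct), `protocol:`, `compare:` (welch) and
#' `skip_imaging:`. Every section is validated through its module's
#' constructor before any computation.
#'
#' @param path YAML file, or a list with the same structure.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  raw <- if (is.list(path)) path
         else if (is.character(path) && file.exists(path)) yaml::read_yaml(path)
         else stop_config("config file not found: '%s'", path)
  if (is.null(raw$conditions) || length(raw$conditions) < 1L)
    stop_config("config must declare at least one entry under 'conditions'")
  nm <- names(raw$conditions)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop_config("condition names must be unique and non-empty")
  protocol <- do.call(labeling_protocol, raw$protocol %||% list())
  conditions <- lapply(raw$conditions, function(cc) {
    if (is.null(cc$simulate))
      stop_config("each condition needs a 'simulate' section")
    sim <- cc$simulate
    for (f in c("fiber_length_kb", "speed_kb_min"))
      if (!is.null(sim[[f]])) sim[[f]] <- as_dist_spec(sim[[f]], f)
    if (!is.null(sim$firing_time_window_min))
      sim$firing_time_window_min <- as.numeric(unlist(sim$firing_time_window_min))
    do.call(simulation_config, sim)
  })
  met <- raw$metrics %||% list()
  structure(list(
    seed = raw$seed %||% 1L,
    protocol = protocol,
    conditions = conditions,
    render = do.call(render_config, raw$render %||% list()),
    detect = do.call(detect_config, raw$detect %||% list()),
    metrics = list(
      adjacency_tol_kb = met$adjacency_tol_kb %||% 1,
      origin_gap_max_kb = met$origin_gap_max_kb %||% 200,
      end_margin_kb = met$end_margin_kb %||% 2,
      thresholds = symmetry_thresholds(met$symmetric_below_pct %||% 30)),
    compare = list(welch = isTRUE((raw$compare %||% list())$welch)),
    skip_imaging = isTRUE(raw$skip_imaging)),
    class = "pipeline_config")
}

summary_for_json <- function(s) {
  s <- unclass(s)
  s$speeds <- NULL
  s$class_counts <- as.list(s$class_counts)
  s$class_fractions <- as.list(s$class_fractions)
  s
}

#' Run the end-to-end combing analysis pipeline
#'
#' Per condition: simulate fibers, derive the observable segment table, and
#' either render + detect (imaging arm) or use the ground-truth segments
#' directly (`skip_imaging`); then call forks, group units and summarise.
#' With two or more conditions the second condition (treatment) is compared
#' against the first (reference): positive Cohen's d means faster forks in
#' the treatment. All tables, a JSON results file and a run log (seed,
#' config digest, package version) are written to `out_dir`; identical
#' config and seed give identical outputs.
#'
#' @param config a [pipeline_config()] (or a path/list accepted by it).
#' @param out_dir output directory (created if missing).
#' @param skip_imaging overrides the config flag when not `NULL`.
#' @param seed overrides the config seed when not `NULL`.
#' @return invisibly, a list with per-condition `summaries`, the
#'   `comparison` (or `NULL`), and output paths.
#' @export
run_pipeline <- function(config, out_dir, skip_imaging = NULL, seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(skip_imaging)) config$skip_imaging <- isTRUE(skip_imaging)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- digest::digest(config[c("protocol", "conditions", "render",
                                    "detect", "metrics", "compare",
                                    "skip_imaging")])
  seeds <- derive_seeds(config$seed, 2L * length(config$conditions))
  summaries <- list()
  paths <- list()
  for (i in seq_along(config$conditions)) {
    cname <- names(config$conditions)[i]
    sim <- config$conditions[[i]]
    sim$seed <- seeds[2L * i - 1L]
    fibers <- sample_fibers(sim, config$protocol)
    truth <- truth_segments(fibers, config$protocol)
    pre <- file.path(out_dir, cname)
    export_truth(fibers, paste0(pre, "_truth.tsv"))
    if (config$skip_imaging) {
      segments <- truth
    } else {
      rc <- config$render
      rc$seed <- seeds[2L * i]
      images <- render_fibers(truth, rc, config$protocol)
      write_fiber_images(images, paste0(pre, "_fibers.tif"))
      segments <- detect_all(images, config$detect)
    }
    write_segments(segments, paste0(pre, "_segments.tsv"))
    m <- measure_segments(segments, config$protocol,
                          adjacency_tol_kb = config$metrics$adjacency_tol_kb,
                          origin_gap_max_kb = config$metrics$origin_gap_max_kb,
                          end_margin_kb = config$metrics$end_margin_kb,
                          thresholds = config$metrics$thresholds)
    write_forks(m$forks, paste0(pre, "_forks.tsv"))
    write_units(m$units, paste0(pre, "_units.tsv"))
    summaries[[cname]] <- summarize_condition(m$units, m$forks, cname)
    paths[[cname]] <- paste0(pre, c("_truth.tsv", "_segments.tsv",
                                    "_forks.tsv", "_units.tsv"))
  }
  comparison <- NULL
  if (length(summaries) >= 2L)
    comparison <- compare_conditions(summaries[[2L]], summaries[[1L]],
                                     welch = config$compare$welch)
  results <- list(
    seed = config$seed,
    config_digest = digest,
    skip_imaging = config$skip_imaging,
    summaries = lapply(summaries, summary_for_json),
    comparison = if (!is.null(comparison))
      list(treatment = comparison$label_a, reference = comparison$label_b,
           t_stat = comparison$speed$t_stat,
           p_two_tailed = comparison$speed$p_two_tailed,
           cohen_d = comparison$speed$cohen_d,
           class_chi2 = comparison$classes$chi2,
           class_p = comparison$classes$p))
  results_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, results_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("combfork %s", as.character(utils::packageVersion("combfork"))),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", config$seed),
    sprintf("config_digest: %s", digest),
    sprintf("skip_imaging: %s", config$skip_imaging),
    sprintf("conditions: %s", paste(names(config$conditions), collapse = ", "))),
    log_path)
  invisible(list(summaries = summaries, comparison = comparison,
                 results_path = results_path, log_path = log_path,
                 paths = paths))
}
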