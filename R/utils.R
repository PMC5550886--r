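# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("combfork_config_error", "combfork_error")))
}

#' @keywords internal
stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("combfork_data_error", "combfork_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers do not perturb the surrounding random stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is_count(seed)) stop_config("seed must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive k child seeds (< 2^31) from one parent seed, reproducibly.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

# Fixed-point kb formatting used by every TSV writer (3 decimals).
fmt_kb <- function(x) {
  out <- sprintf("%.3f", x)
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_data("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop_data("file not found: '%s'", path)
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, colClasses = colClasses)
}
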