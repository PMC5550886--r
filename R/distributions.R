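# Small distribution-spec vocabulary used by SimulationConfig fields.
# A spec is a list(dist = "fixed"|"normal"|"lognormal", ...parameters...).
# Normal draws are truncated to (0, Inf) by resampling when truncate > 0 is
# requested (fork speeds must be positive); lognormal is parameterised on the
# natural scale (mean, sd in the units of the quantity).

#' Distribution specifications for simulation parameters
#'
#' `dist_fixed()` gives a degenerate (constant) value, `dist_normal()` a
#' normal optionally truncated to positive values, `dist_lognormal()` a
#' lognormal parameterised by its natural-scale mean and sd. These specs are
#' used for fiber lengths and fork speeds in [simulation_config()].
#'
#' @param value constant value.
#' @param mean,sd natural-scale mean and standard deviation.
#' @param truncate_positive resample draws until strictly positive.
#' @return a `dist_spec` list.
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  if (!is_number(value)) stop_config("dist_fixed: 'value' must be a number")
  structure(list(dist = "fixed", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncate_positive = TRUE) {
  if (!is_number(mean) || !is_number(sd) || sd < 0)
    stop_config("dist_normal: need numeric 'mean' and non-negative 'sd'")
  structure(list(dist = "normal", mean = mean, sd = sd,
                 truncate_positive = isTRUE(truncate_positive)),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd) {
  if (!is_number(mean) || mean <= 0 || !is_number(sd) || sd < 0)
    stop_config("dist_lognormal: need positive 'mean' and non-negative 'sd'")
  # convert natural-scale mean/sd to meanlog/sdlog
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  structure(list(dist = "lognormal", mean = mean, sd = sd,
                 meanlog = meanlog, sdlog = sdlog),
            class = "dist_spec")
}

as_dist_spec <- function(x, field) {
  if (inherits(x, "dist_spec")) return(x)
  if (is_number(x)) return(dist_fixed(x))
  if (is.list(x) && !is.null(x$dist)) {
    out <- switch(x$dist,
      fixed = dist_fixed(x$value %||% stop_config("field '%s': fixed spec needs 'value'", field)),
      normal = dist_normal(x$mean, x$sd,
                           truncate_positive = x$truncate_positive %||% TRUE),
      lognormal = dist_lognormal(x$mean, x$sd),
      stop_config("field '%s': unknown distribution '%s'", field, x$dist))
    return(out)
  }
  stop_config("field '%s': not a valid distribution spec", field)
}

sample_dist <- function(spec, n) {
  if (n == 0L) return(numeric(0))
  switch(spec$dist,
    fixed = rep(spec$value, n),
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      if (isTRUE(spec$truncate_positive)) {
        while (any(bad <- x <= 0))
          x[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
      }
      x
    },
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop_config("unknown distribution '%s'", spec$dist))
}

# Practical upper bound of a speed distribution, used for the origin
# separation rule (2 x speed_max x total pulse time).
dist_upper <- function(spec) {
  switch(spec$dist,
    fixed = spec$value,
    normal = spec$mean + 5 * spec$sd,
    lognormal = stats::qlnorm(1 - 1e-6, spec$meanlog, spec$sdlog),
    stop_config("unknown distribution '%s'", spec$dist))
}
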