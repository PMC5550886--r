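#' Dual-pulse labeling protocol
#'
#' Describes the sequential nucleotide-analog labeling scheme of a combing
#' experiment: a first pulse (default IdU, 30 min) immediately followed by a
#' second pulse (default CldU, 30 min). Time zero throughout the package is
#' the start of pulse 1; the two pulse durations define the denominators of
#' all fork-speed computations. Concentrations are metadata only.
#'
#' @param pulse1_label,pulse2_label channel names of the two analogs; must be
#'   distinct and distinct from `"DNA"` (the counterstain channel).
#' @param pulse1_duration_min,pulse2_duration_min pulse lengths in minutes,
#'   strictly positive.
#' @param pulse1_conc_uM,pulse2_conc_uM analog concentrations (µM), recorded
#'   but never used in computation.
#' @return an object of class `labeling_protocol`.
#' @examples
#' labeling_protocol()
#' @export
labeling_protocol <- function(pulse1_label = "IdU", pulse1_duration_min = 30,
                              pulse2_label = "CldU", pulse2_duration_min = 30,
                              pulse1_conc_uM = 25, pulse2_conc_uM = 200) {
  if (!is_number(pulse1_duration_min) || pulse1_duration_min <= 0)
    stop_config("pulse1_duration_min must be a positive number")
  if (!is_number(pulse2_duration_min) || pulse2_duration_min <= 0)
    stop_config("pulse2_duration_min must be a positive number")
  labs <- c(pulse1_label, pulse2_label)
  if (!is.character(labs) || anyNA(labs) || any(labs == "") ||
      pulse1_label == pulse2_label || any(labs == "DNA"))
    stop_config("pulse labels must be distinct non-empty names other than 'DNA'")
  structure(list(pulse1_label = pulse1_label,
                 pulse1_duration_min = pulse1_duration_min,
                 pulse2_label = pulse2_label,
                 pulse2_duration_min = pulse2_duration_min,
                 pulse1_conc_uM = pulse1_conc_uM,
                 pulse2_conc_uM = pulse2_conc_uM),
            class = "labeling_protocol")
}

total_labeling_min <- function(protocol) {
  protocol$pulse1_duration_min + protocol$pulse2_duration_min
}

#' @export
print.labeling_protocol <- function(x, ...) {
  cat(sprintf("Dual-pulse labeling: %s %g min (%g uM) -> %s %g min (%g uM)\n",
              x$pulse1_label, x$pulse1_duration_min, x$pulse1_conc_uM,
              x$pulse2_label, x$pulse2_duration_min, x$pulse2_conc_uM))
  invisible(x)
}
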