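#' Minimum oxygen saturation during sleep
#'
#' @param trace a [spo2_trace()] or numeric saturation vector (%).
#' @return SatMin in percent.
#' @export
sat_min <- function(trace) {
  s <- spo2_values(trace)
  min(s)
}

#' Percentage of sleep time with saturation below 90%
#'
#' Total sleep time is taken as the trace duration; the inequality is
#' strict, so samples at exactly 90% do not count.
#'
#' @param trace a [spo2_trace()] or numeric saturation vector (%).
#' @return T90 in percent of total samples.
#' @export
t90 <- function(trace) {
  s <- spo2_values(trace)
  100 * mean(s < 90)
}

spo2_values <- function(trace) {
  s <- if (inherits(trace, "spo2_trace")) trace$sat else as.numeric(trace)
  if (length(s) == 0) stop("empty SpO2 trace")
  s
}
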