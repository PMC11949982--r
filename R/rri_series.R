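#' Beat-to-beat RR-interval series
#'
#' Container for an ordered sequence of RR intervals (ms) together with its
#' offset from sleep onset and the audit trail of any spurious-beat
#' corrections applied to it.
#'
#' @param values numeric vector of RR intervals in milliseconds; all > 0.
#' @param t_start offset of the first beat from sleep onset, in seconds.
#' @param corrected_mask logical vector flagging beats replaced by the
#'   correction stage; defaults to all `FALSE`.
#' @return an object of class `rri_series` with fields `values`, `t_start`,
#'   `corrected_mask` and `n_corrected`.
#' @export
rri_series <- function(values, t_start = 0, corrected_mask = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty RRi series")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("RR intervals must be finite and positive")
  if (is.null(corrected_mask)) corrected_mask <- rep(FALSE, length(values))
  if (length(corrected_mask) != length(values))
    stop("corrected_mask length must match values")
  structure(
    list(values = values, t_start = t_start,
         corrected_mask = corrected_mask,
         n_corrected = sum(corrected_mask)),
    class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d beats, %.1f s, mean RR %.1f ms, %d corrected\n",
              length(x$values), sum(x$values) / 1000,
              mean(x$values), x$n_corrected))
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$values)

#' Total duration of an RRi series in seconds
#' @param x an `rri_series`.
#' @return duration in seconds (sum of intervals).
#' @export
rri_duration <- function(x) sum(x$values) / 1000

#' Oxygen-saturation trace
#'
#' A uniformly sampled SpO2 time series for one night.
#'
#' @param sat saturation values in percent, within \[0, 100\].
#' @param sample_hz sampling rate in Hz.
#' @param t0 time of the first sample (s from sleep onset).
#' @return an object of class `spo2_trace` with fields `t`, `sat`, `sample_hz`.
#' @export
spo2_trace <- function(sat, sample_hz = 1, t0 = 0) {
  sat <- as.numeric(sat)
  if (length(sat) == 0L) stop("empty SpO2 trace")
  if (any(!is.finite(sat)) || any(sat < 0) || any(sat > 100))
    stop("SpO2 values must lie in [0, 100]")
  if (!is.finite(sample_hz) || sample_hz <= 0) stop("sample_hz must be > 0")
  structure(
    list(t = t0 + (seq_along(sat) - 1L) / sample_hz,
         sat = sat, sample_hz = sample_hz),
    class = "spo2_trace")
}

#' @export
print.spo2_trace <- function(x, ...) {
  cat(sprintf("<spo2_trace> %d samples @ %g Hz, min %.1f%%, median %.1f%%\n",
              length(x$sat), x$sample_hz, min(x$sat), median(x$sat)))
  invisible(x)
}
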