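#' Parameters of the spurious-beat correction
#'
#' The correction estimates a baseline as a centred moving median of width
#' `window_W` beats and builds upper/lower tolerance lines by shifting the
#' baseline up and down by `tolerance_T` times the baseline average. Beats
#' outside the band are replaced by linear interpolation between the nearest
#' in-band neighbours. A series in which more than `max_corrected_frac` of
#' the beats had to be replaced is flagged ineligible for analysis.
#'
#' @param window_W odd number of beats in the moving-median window (>= 3).
#' @param tolerance_T band half-width as a fraction of the baseline average,
#'   in (0, 1).
#' @param max_corrected_frac maximum tolerated fraction of corrected beats.
#' @return object of class `correction_params`.
#' @export
correction_params <- function(window_W = 11, tolerance_T = 0.2,
                              max_corrected_frac = 0.025) {
  if (window_W < 3 || window_W %% 2 == 0)
    stop("window_W must be odd and >= 3")
  if (tolerance_T <= 0 || tolerance_T >= 1)
    stop("tolerance_T must lie in (0, 1)")
  if (max_corrected_frac <= 0 || max_corrected_frac > 1)
    stop("max_corrected_frac must lie in (0, 1]")
  structure(list(window_W = as.integer(window_W),
                 tolerance_T = tolerance_T,
                 max_corrected_frac = max_corrected_frac),
            class = "correction_params")
}

# centred moving-median baseline and out-of-band mask; endrule "median"
# shrinks the window symmetrically at the series edges
rri_band <- function(values, params) {
  baseline <- as.numeric(runmed(values, params$window_W, endrule = "median"))
  half <- params$tolerance_T * mean(baseline)
  list(baseline = baseline,
       lower = baseline - half, upper = baseline + half,
       out = values < baseline - half | values > baseline + half)
}

#' Correct spurious beats in an RRi series
#'
#' Replaces beats lying outside a moving-median tolerance band by linear
#' interpolation between the nearest in-band neighbours (a run of consecutive
#' out-of-band beats is replaced as a block; out-of-band beats at the series
#' edge take the value of the nearest in-band beat). Series length is
#' preserved and the correction is recorded in `corrected_mask` /
#' `n_corrected`.
#'
#' @param series an [rri_series()].
#' @param params a [correction_params()].
#' @return the corrected [rri_series()], with attribute `eligible` set to
#'   `FALSE` when more than `max_corrected_frac` of the beats were replaced.
#' @export
correct_rri <- function(series, params = correction_params()) {
  stopifnot(inherits(series, "rri_series"), inherits(params, "correction_params"))
  x <- series$values
  n <- length(x)
  if (n < params$window_W)
    stop("series shorter than the correction window")
  band <- rri_band(x, params)
  out <- band$out
  y <- x
  if (any(out)) {
    if (all(out)) stop("no in-band beats to interpolate from")
    idx <- which(!out)
    y[out] <- approx(idx, x[idx], xout = which(out), rule = 2)$y
  }
  res <- rri_series(y, t_start = series$t_start,
                    corrected_mask = series$corrected_mask | out)
  attr(res, "eligible") <- res$n_corrected / n <= params$max_corrected_frac
  res
}

#' Is a corrected series eligible for analysis?
#'
#' @param series a series returned by [correct_rri()].
#' @return logical; `FALSE` when the corrected fraction exceeded the bound.
#' @export
rri_eligible <- function(series) isTRUE(attr(series, "eligible"))

# beats of `series` whose cumulative-time midpoint falls in [t0, t0+dur)
rri_window <- function(series, t0, dur) {
  t_end <- cumsum(series$values) / 1000      # beat end times, s from start
  keep <- t_end > t0 & t_end <= t0 + dur
  keep
}

#' Select the cleanest 15-minute window from each recording hour
#'
#' For each hourly RRi series, candidate windows of `duration` seconds slide
#' in `step`-second increments (never crossing the hour boundary); each
#' window is scored by its fraction of out-of-band beats before correction,
#' and the window with the lowest score is returned (ties broken by the
#' earliest offset). This automates the visual quality screening of hourly
#' ECG segments.
#'
#' @param series_per_hour list of hourly [rri_series()] objects.
#' @param duration window length in seconds (default 900 = 15 min).
#' @param n_hours number of hours required (default 6); fewer available
#'   hours, or an hour spanning less than `duration` seconds, excludes the
#'   subject.
#' @param step slide increment in seconds.
#' @param params [correction_params()] defining the quality band.
#' @return list of `n_hours` uncorrected [rri_series()] windows, with
#'   attribute `offsets` giving each window's start (s within its hour).
#' @export
select_segments <- function(series_per_hour, duration = 900, n_hours = 6,
                            step = 60, params = correction_params()) {
  if (length(series_per_hour) < n_hours)
    stop("subject excluded: insufficient collected time (",
         length(series_per_hour), " h available, ", n_hours, " required)")
  segments <- vector("list", n_hours)
  offsets <- numeric(n_hours)
  for (h in seq_len(n_hours)) {
    hour <- series_per_hour[[h]]
    total <- rri_duration(hour)
    if (total < duration)
      stop("subject excluded: hour ", h, " spans only ",
           round(total), " s (< ", duration, " s)")
    out <- rri_band(hour$values, params)$out
    t_end <- cumsum(hour$values) / 1000
    cand <- seq(0, total - duration, by = step)
    score <- vapply(cand, function(t0) {
      keep <- t_end > t0 & t_end <= t0 + duration
      if (!any(keep)) return(Inf)
      mean(out[keep])
    }, 0)
    best <- cand[which.min(score)]           # which.min takes earliest tie
    keep <- t_end > best & t_end <= best + duration
    segments[[h]] <- rri_series(hour$values[keep],
                                t_start = hour$t_start + best)
    offsets[h] <- best
  }
  attr(segments, "offsets") <- offsets
  segments
}
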