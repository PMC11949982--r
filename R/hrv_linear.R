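#' Time-domain HRV indices
#'
#' @param series an [rri_series()] or numeric vector of RR intervals (ms).
#' @return named numeric vector: `MeanRR` (ms, arithmetic mean), `SDNN` (ms,
#'   sample standard deviation), `RMSSD` (ms, root mean square of successive
#'   differences).
#' @examples
#' hrv_time_domain(c(800, 810, 800))  # RMSSD = 10
#' @export
hrv_time_domain <- function(series) {
  x <- rri_values(series)
  if (length(x) < 2) stop("need at least 2 beats")
  c(MeanRR = mean(x), SDNN = sd(x),
    RMSSD = sqrt(mean(diff(x)^2)))
}

rri_values <- function(series) {
  if (inherits(series, "rri_series")) series$values else as.numeric(series)
}

#' Spectral-analysis configuration
#'
#' The RRi tachogram is cubic-spline resampled on its cumulative-time axis,
#' split into `segment_len`-sample windows with `overlap` fractional overlap,
#' mean-removed and Hanning-windowed per segment (with power compensation so
#' that total integrated power matches signal variance), and the averaged
#' periodogram is integrated over the standard bands.
#'
#' @param resample_hz resampling rate, Hz.
#' @param segment_len samples per FFT segment.
#' @param overlap fractional overlap between consecutive segments, in \[0, 1).
#' @param vlf_lo lower bound of the VLF band, Hz (the band is reported as
#'   "below 0.04 Hz"; power below `vlf_lo` is treated as trend).
#' @param vlf_hi,lf_hi,hf_hi upper band edges: VLF < 0.04 Hz,
#'   LF 0.04-0.15 Hz, HF 0.15-0.4 Hz.
#' @return object of class `spectral_config`.
#' @export
spectral_config <- function(resample_hz = 3, segment_len = 512, overlap = 0.5,
                            vlf_lo = 0.003, vlf_hi = 0.04, lf_hi = 0.15,
                            hf_hi = 0.4) {
  edges <- c(vlf_lo, vlf_hi, lf_hi, hf_hi)
  if (any(diff(edges) <= 0)) stop("band edges must be strictly increasing")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  structure(list(resample_hz = resample_hz,
                 segment_len = as.integer(segment_len), overlap = overlap,
                 vlf_lo = vlf_lo, vlf_hi = vlf_hi, lf_hi = lf_hi,
                 hf_hi = hf_hi),
            class = "spectral_config")
}

# Welch-averaged one-sided periodogram of an evenly sampled signal.
# Hanning window with power compensation (divide by mean squared window) so
# that sum(psd) * df equals the signal variance for a stationary signal.
welch_psd <- function(x, fs, segment_len, overlap) {
  n <- length(x)
  if (n < segment_len) stop("signal shorter than one FFT segment")
  step <- max(1L, as.integer(round(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(segment_len - 1)) / (segment_len - 1)))
  wnorm <- mean(w^2)
  nf <- segment_len %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[2:(nf + 1L)])^2
    acc <- acc + sp
  }
  acc <- acc / length(starts)
  df <- fs / segment_len
  # one-sided PSD; doubling all bins but Nyquist
  psd <- 2 * acc / (segment_len^2 * wnorm * df)
  psd[nf] <- psd[nf] / 2
  list(freq = (1:nf) * df, psd = psd, df = df)
}

band_power <- function(sp, lo, hi) {
  sel <- sp$freq >= lo & sp$freq < hi
  sum(sp$psd[sel]) * sp$df
}

#' Frequency-domain HRV indices
#'
#' Resamples the tachogram at `cfg$resample_hz` by cubic-spline interpolation
#' of RR value against cumulative beat time, computes a Welch-averaged
#' periodogram (mean removal and power-compensated Hanning window per
#' segment), and integrates the band powers. Normalised units use LF + HF as
#' the denominator, so `LFnu + HFnu = 100` by construction.
#'
#' @param series an [rri_series()] or numeric RR vector (ms).
#' @param cfg a [spectral_config()].
#' @return named numeric vector: `VLFabs`, `LFabs`, `HFabs` (ms^2), `LFnu`,
#'   `HFnu` (percent of LF + HF), `LF/HF` (ratio; `NA` when HF power is 0).
#' @export
hrv_spectral <- function(series, cfg = spectral_config()) {
  x <- rri_values(series)
  t_beat <- cumsum(x) / 1000
  dur <- t_beat[length(t_beat)] - t_beat[1]
  if (dur < cfg$segment_len / cfg$resample_hz)
    stop("segment too short for one ", cfg$segment_len, "-sample window")
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / cfg$resample_hz)
  xi <- spline(t_beat, x, xout = grid, method = "fmm")$y
  sp <- welch_psd(xi, cfg$resample_hz, cfg$segment_len, cfg$overlap)
  vlf <- band_power(sp, cfg$vlf_lo, cfg$vlf_hi)
  lf <- band_power(sp, cfg$vlf_hi, cfg$lf_hi)
  hf <- band_power(sp, cfg$lf_hi, cfg$hf_hi)
  tot <- lf + hf
  lfnu <- if (tot > 0) 100 * lf / tot else NA_real_
  hfnu <- if (tot > 0) 100 * hf / tot else NA_real_
  c(VLFabs = vlf, LFabs = lf, HFabs = hf, LFnu = lfnu, HFnu = hfnu,
    `LF/HF` = if (hf > 0) lf / hf else NA_real_)
}
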