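#' Parameters of the nonlinear HRV estimators
#'
#' Defaults follow the standard published parameterisations for short RRi
#' segments: SampEn(m = 2, r = 0.15 SD), FuzzyEn(m = 2, r = 0.15 SD, fuzzy
#' exponent 2), DispEn(m = 3, 6 classes), PermEn(m = 3, with tiny tie-break
#' noise), PhaseEn(16 sectors), DistEn(m = 3, 512 bins), DFA short-range
#' window sizes 6-14 beats, PRSA half-window L = 8 with a 5% anchor filter.
#'
#' @param sampen_m,sampen_r_frac sample-entropy template length and tolerance
#'   as a fraction of the series SD.
#' @param fuzzy_m,fuzzy_r_frac,fuzzy_n fuzzy-entropy template length,
#'   tolerance fraction, and membership exponent.
#' @param disp_m,disp_nc dispersion-entropy template length and classes.
#' @param perm_m,perm_noise_frac permutation-entropy order and tie-break
#'   noise amplitude as a fraction of the series SD.
#' @param phase_k number of angular sectors for phase entropy.
#' @param dist_m,dist_bins distribution-entropy template length and
#'   histogram bins.
#' @param dfa_scales integer window sizes for the short-range DFA exponent.
#' @param prsa_L,prsa_filter PRSA half-window (beats) and anchor exclusion
#'   threshold (fractional change from the previous beat).
#' @return object of class `nonlinear_params`.
#' @export
nonlinear_params <- function(sampen_m = 2, sampen_r_frac = 0.15,
                             fuzzy_m = 2, fuzzy_r_frac = 0.15, fuzzy_n = 2,
                             disp_m = 3, disp_nc = 6,
                             perm_m = 3, perm_noise_frac = 1e-6,
                             phase_k = 16,
                             dist_m = 3, dist_bins = 512,
                             dfa_scales = 6:14,
                             prsa_L = 8, prsa_filter = 0.05) {
  structure(list(sampen_m = sampen_m, sampen_r_frac = sampen_r_frac,
                 fuzzy_m = fuzzy_m, fuzzy_r_frac = fuzzy_r_frac,
                 fuzzy_n = fuzzy_n, disp_m = disp_m, disp_nc = disp_nc,
                 perm_m = perm_m, perm_noise_frac = perm_noise_frac,
                 phase_k = phase_k, dist_m = dist_m, dist_bins = dist_bins,
                 dfa_scales = as.integer(dfa_scales),
                 prsa_L = as.integer(prsa_L), prsa_filter = prsa_filter),
            class = "nonlinear_params")
}

shannon <- function(p, base = exp(1)) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B and A count template matches of length
#' `m` and `m + 1` at Chebyshev tolerance `r`, over template pairs i != j
#' (self-matches excluded; both counts use the first N - m templates).
#'
#' @param series [rri_series()] or numeric vector.
#' @param m template length.
#' @param r tolerance; defaults to `r_frac` times the series SD.
#' @param r_frac tolerance as a fraction of the SD, used when `r` is `NULL`.
#' @return SampEn (dimensionless); 0 for a constant series; `NA` when no
#'   template pairs match at tolerance.
#' @export
sample_entropy <- function(series, m = 2, r = NULL, r_frac = 0.15) {
  x <- rri_values(series)
  n <- length(x)
  if (n < m + 2) stop("series too short for SampEn")
  if (sd(x) == 0) return(0)
  if (is.null(r)) r <- r_frac * sd(x)
  ab <- .sampen_counts(x, as.integer(m), r)
  if (ab[2] == 0 || ab[1] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Fuzzy entropy
#'
#' Like SampEn but templates are baseline-removed (their own mean
#' subtracted) and matching is graded by the exponential membership
#' exp(-(d/r)^n) instead of a hard threshold.
#'
#' @inheritParams sample_entropy
#' @param n_fuzzy fuzzy membership exponent.
#' @return FuzzyEn (dimensionless); 0 for a constant series.
#' @export
fuzzy_entropy <- function(series, m = 2, r = NULL, r_frac = 0.15,
                          n_fuzzy = 2) {
  x <- rri_values(series)
  n <- length(x)
  if (n < m + 2) stop("series too short for FuzzyEn")
  if (sd(x) == 0) return(0)
  if (is.null(r)) r <- r_frac * sd(x)
  n_t <- n - m
  log(.fuzzyen_phi(x, as.integer(m), r, n_fuzzy, n_t)) -
    log(.fuzzyen_phi(x, as.integer(m + 1), r, n_fuzzy, n_t))
}

#' Dispersion entropy
#'
#' Values are mapped through the normal CDF (using the series mean and SD)
#' to `nc` discrete classes; the Shannon entropy of the frequencies of the
#' `nc^m` dispersion patterns is normalised by its maximum `ln(nc^m)`.
#'
#' @inheritParams sample_entropy
#' @param nc number of classes.
#' @return normalised DispEn in \[0, 1\]; 0 for a constant series.
#' @export
dispersion_entropy <- function(series, m = 3, nc = 6) {
  x <- rri_values(series)
  n <- length(x)
  if (n < m + 1) stop("series too short for DispEn")
  if (sd(x) == 0) return(0)
  y <- pnorm(x, mean(x), sd(x))
  z <- pmin(pmax(as.integer(round(y * nc + 0.5)), 1L), nc)
  code <- integer(n - m + 1)
  for (j in 0:(m - 1))
    code <- code + (z[seq_len(n - m + 1) + j] - 1L) * nc^j
  p <- tabulate(code + 1L, nbins = nc^m)
  p <- p / sum(p)
  shannon(p) / log(nc^m)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern frequencies of order `m`
#' (normalised by `ln(m!)`), with uniform noise of amplitude
#' `noise_frac * SD` added under a fixed internal seed to break ties. A
#' constant series receives no noise and collapses to a single pattern
#' (entropy 0).
#'
#' @inheritParams sample_entropy
#' @param noise_frac tie-break noise amplitude as a fraction of the SD.
#' @return normalised PermEn in \[0, 1\].
#' @export
permutation_entropy <- function(series, m = 3, noise_frac = 1e-6) {
  x <- rri_values(series)
  n <- length(x)
  if (n < m + 1) stop("series too short for PermEn")
  amp <- noise_frac * sd(x)
  if (amp > 0) {
    x <- x + with_fixed_seed(20230415L, runif(n, -amp, amp))
  }
  n_w <- n - m + 1L
  codes <- vapply(seq_len(n_w), function(i)
    paste(order(x[i:(i + m - 1L)]), collapse = ""), "")
  p <- table(codes)
  shannon(as.numeric(p) / n_w) / log(factorial(m))
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phase entropy
#'
#' Shannon entropy (normalised by `ln(k)`) of the angular-sector occupancy
#' of points in the second-order difference plot
#' (\eqn{\Delta RR_{i+1}} against \eqn{\Delta RR_i}), with `k` equal sectors
#' over \[0, 2\pi). Points at the origin carry no angle and are dropped.
#'
#' @inheritParams sample_entropy
#' @param k number of angular sectors.
#' @return normalised PhaseEn in \[0, 1\]; `NA` for a constant series.
#' @export
phase_entropy <- function(series, k = 16) {
  x <- rri_values(series)
  if (length(x) < 4) stop("series too short for PhaseEn")
  d <- diff(x)
  u <- d[-length(d)]
  v <- d[-1]
  ok <- !(u == 0 & v == 0)
  if (!any(ok)) return(NA_real_)
  theta <- atan2(v[ok], u[ok]) %% (2 * pi)
  sector <- pmin(floor(theta / (2 * pi / k)), k - 1)
  p <- tabulate(sector + 1L, nbins = k)
  shannon(p / sum(p)) / log(k)
}

#' Distribution entropy
#'
#' Shannon entropy (base 2, normalised by `log2(M)`) of the `M`-bin
#' histogram of all pairwise Chebyshev distances between length-`m`
#' templates.
#'
#' @inheritParams sample_entropy
#' @param n_bins number of histogram bins M.
#' @return normalised DistEn in \[0, 1\]; `NA` for a constant series.
#' @export
distribution_entropy <- function(series, m = 3, n_bins = 512) {
  x <- rri_values(series)
  n <- length(x)
  if (n < m + 2) stop("series too short for DistEn")
  if (sd(x) == 0) return(NA_real_)
  p <- .disten_counts(x, as.integer(m), as.integer(n_bins))
  if (length(p) == 0) return(0)      # all inter-template distances equal
  shannon(p / sum(p), base = 2) / log2(n_bins)
}

#' Attention entropy
#'
#' Parameter-free entropy of the intervals between local-extrema key
#' patterns: local maxima and minima are located, the four interval
#' sequences (max-to-max, min-to-min, max-to-min, min-to-max) are extracted,
#' and AttEn is the mean of the four Shannon entropies (base 2) of the
#' interval-length frequencies. An interval type with fewer than one
#' interval contributes 0.
#'
#' @inheritParams sample_entropy
#' @return AttEn (bits); `NA` when the series has no local extrema.
#' @export
attention_entropy <- function(series) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 5) stop("series too short for AttEn")
  i <- 2:(n - 1)
  imax <- i[x[i] > x[i - 1] & x[i] > x[i + 1]]
  imin <- i[x[i] < x[i - 1] & x[i] < x[i + 1]]
  if (length(imax) + length(imin) < 2) return(NA_real_)
  ent <- function(iv) {
    if (length(iv) < 1) return(0)
    shannon(as.numeric(table(iv)) / length(iv), base = 2)
  }
  # cross intervals from the merged, time-ordered extrema sequence
  key <- rbind(data.frame(i = imax, type = "max"),
               data.frame(i = imin, type = "min"))
  key <- key[order(key$i), ]
  gap <- diff(key$i)
  from <- key$type[-nrow(key)]
  to <- key$type[-1]
  mean(c(ent(diff(imax)), ent(diff(imin)),
         ent(gap[from == "max" & to == "min"]),
         ent(gap[from == "min" & to == "max"])))
}

#' Short-range detrended fluctuation exponent (DFA alpha-1)
#'
#' The mean-centred series is integrated; for each window size `n` in
#' `scales` the profile is split into non-overlapping windows (tail beats
#' beyond the last full window discarded), linearly detrended per window,
#' and the fluctuation F(n) is the RMS residual. Alpha-1 is the slope of
#' log F(n) against log n.
#'
#' @inheritParams sample_entropy
#' @param scales integer window sizes (beats).
#' @return the scaling exponent; `NA` for a zero-variance series.
#' @export
dfa_alpha1 <- function(series, scales = 6:14) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 100) stop("DFA needs at least 100 beats")
  if (sd(x) == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(w) {
    n_w <- n %/% w
    Y <- matrix(y[seq_len(n_w * w)], nrow = w)
    t <- seq_len(w)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    slope <- colSums(Y * tc) / stt
    inter <- colMeans(Y)
    res <- Y - outer(tc, slope) - rep(inter, each = w)
    sqrt(mean(res^2))
  }, 0)
  unname(coef(lm(log(Fn) ~ log(scales)))[2])
}

#' Max-Min symbolic dynamics
#'
#' The RRi range is split into 6 equal-width bins; each beat receives the
#' symbol (0-5) of its bin; overlapping words of 3 consecutive symbols are
#' classified as 0V (no variation), 1V (one variation), 2LV (two like, i.e.
#' same-sign, variations) or 2UV (two unlike variations).
#'
#' @inheritParams sample_entropy
#' @return named vector of percentages `Symb-0V`, `Symb-1V`, `Symb-2LV`,
#'   `Symb-2UV` summing to 100; all `NA` for a constant series.
#' @export
symbolic_maxmin <- function(series) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 3) stop("need at least 3 beats")
  out <- c(`Symb-0V` = NA_real_, `Symb-1V` = NA_real_,
           `Symb-2LV` = NA_real_, `Symb-2UV` = NA_real_)
  rng <- max(x) - min(x)
  if (rng == 0) return(out)
  s <- pmin(floor((x - min(x)) / rng * 6), 5)
  s1 <- s[1:(n - 2)]; s2 <- s[2:(n - 1)]; s3 <- s[3:n]
  v1 <- s1 != s2; v2 <- s2 != s3
  like <- sign(s2 - s1) == sign(s3 - s2)
  n_w <- n - 2
  out["Symb-0V"] <- 100 * sum(!v1 & !v2) / n_w
  out["Symb-1V"] <- 100 * sum(xor(v1, v2)) / n_w
  out["Symb-2LV"] <- 100 * sum(v1 & v2 & like) / n_w
  out["Symb-2UV"] <- 100 * sum(v1 & v2 & !like) / n_w
  out
}

#' Binary symbolic dynamics
#'
#' Each successive difference is assigned symbol 1 when positive and 0
#' otherwise (a zero difference counts as a non-increase); words of 3
#' symbols are classified by their number of symbol changes (0, 1 or 2).
#'
#' @inheritParams sample_entropy
#' @return named vector of percentages `Bin-0V`, `Bin-1V`, `Bin-2V`
#'   summing to 100.
#' @export
symbolic_binary <- function(series) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 5) stop("need at least 5 beats")
  s <- as.integer(diff(x) > 0)
  m <- length(s)
  ch <- (s[1:(m - 2)] != s[2:(m - 1)]) + (s[2:(m - 1)] != s[3:m])
  n_w <- m - 2
  c(`Bin-0V` = 100 * sum(ch == 0) / n_w,
    `Bin-1V` = 100 * sum(ch == 1) / n_w,
    `Bin-2V` = 100 * sum(ch == 2) / n_w)
}

#' Heart rate fragmentation
#'
#' Each successive difference receives a ternary symbol (1 decreasing RRi,
#' -1 increasing, 0 no change). Every transition between two different
#' consecutive symbols is an inflection point. PIP is the percentage of
#' inflection points among all transitions; words of 4 consecutive symbols
#' are classified by their internal inflection count (0-3).
#'
#' @inheritParams sample_entropy
#' @return named vector `HRF-PIP`, `HRF-W0`, `HRF-W1`, `HRF-W2`, `HRF-W3`
#'   (percent); the W family sums to 100.
#' @export
fragmentation <- function(series) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 6) stop("need at least 6 beats")
  s <- -sign(diff(x))                      # 1 = decreasing, -1 = increasing
  m <- length(s)
  infl <- s[-1] != s[-m]
  pip <- 100 * sum(infl) / (m - 1)
  cnt <- infl[1:(m - 3)] + infl[2:(m - 2)] + infl[3:(m - 1)]
  n_w <- m - 3
  c(`HRF-PIP` = pip,
    `HRF-W0` = 100 * sum(cnt == 0) / n_w,
    `HRF-W1` = 100 * sum(cnt == 1) / n_w,
    `HRF-W2` = 100 * sum(cnt == 2) / n_w,
    `HRF-W3` = 100 * sum(cnt == 3) / n_w)
}

#' Heart rate asymmetry indices
#'
#' With \eqn{\Delta RR_i = RR_{i+1} - RR_i} restricted to nonzero
#' differences: Porta's index is the percentage of negative differences,
#' Guzik's index the percentage of the squared-difference mass carried by
#' positive differences, and Ehlers' index the skewness-like ratio
#' \eqn{\sum \Delta^3 / (\sum \Delta^2)^{3/2}}. Porta and Guzik are 50 and
#' Ehlers 0 for a time-reversible series.
#'
#' @inheritParams sample_entropy
#' @return named vector `Porta`, `Guzik` (percent), `Ehlers`
#'   (dimensionless); all `NA` when every difference is zero.
#' @export
asymmetry_indices <- function(series) {
  x <- rri_values(series)
  if (length(x) < 3) stop("need at least 3 beats")
  d <- diff(x)
  dz <- d[d != 0]
  if (length(dz) == 0)
    return(c(Porta = NA_real_, Guzik = NA_real_, Ehlers = NA_real_))
  c(Porta = 100 * sum(dz < 0) / length(dz),
    Guzik = 100 * sum(dz[dz > 0]^2) / sum(dz^2),
    Ehlers = sum(dz^3) / sum(dz^2)^1.5)
}

#' Acceleration and deceleration capacity (PRSA)
#'
#' Phase-rectified signal averaging: anchors are beats longer (deceleration)
#' or shorter (acceleration) than their predecessor, excluding changes above
#' `filter` times the previous interval; windows of `L` beats on either side
#' of each anchor are averaged aligned on the anchor, and the capacity is
#' the 4-point Bauer estimate (X(0) + X(1) - X(-1) - X(-2)) / 4 on the
#' anchor-averaged signal.
#'
#' @inheritParams sample_entropy
#' @param L half-window in beats.
#' @param filter anchor exclusion threshold (fraction of the previous RR).
#' @return named vector `AC`, `DC` in ms (DC >= 0 and AC <= 0 on typical
#'   input; signs reported as computed); `NA` where no valid anchors exist.
#' @export
prsa_acdc <- function(series, L = 8, filter = 0.05) {
  x <- rri_values(series)
  n <- length(x)
  if (n < 2 * L + 2) stop("need at least 2L + 2 beats")
  capacity <- function(anchor_ok) {
    i <- (L + 1):(n - L + 1)               # full window i-L .. i+L-1
    i <- i[i >= 2]
    i <- i[anchor_ok(i)]
    i <- i[abs(x[i] - x[i - 1]) <= filter * x[i - 1]]
    if (length(i) == 0) return(NA_real_)
    X <- vapply(-L:(L - 1), function(k) mean(x[i + k]), 0)
    names(X) <- -L:(L - 1)
    (X["0"] + X["1"] - X["-1"] - X["-2"]) / 4
  }
  c(AC = unname(capacity(function(i) x[i] < x[i - 1])),
    DC = unname(capacity(function(i) x[i] > x[i - 1])))
}
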