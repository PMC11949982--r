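#' Per-class generative parameters for the synthetic cohort
#'
#' One row per severity class. The defaults emulate the cohort structure of a
#' clinical sleep-laboratory population: AHI ranges respect the class
#' boundaries of [classify_severity()]; an apnea-linked slow cyclic RR
#' oscillation (period 30-60 s, i.e. VLF-band power) whose amplitude grows
#' with severity; short-term RR irregularity that shrinks with severity;
#' oxygen-desaturation events whose hourly rate is proportional to the AHI
#' and whose depth grows with severity; and anthropometric distributions
#' (age, weight, male fraction) centred on values typical of each class.
#'
#' @return data.frame with one row per severity class and columns
#'   `class`, `ahi_lo`, `ahi_hi`, `cyc_amp_ms`, `rsa_amp_ms`, `white_sd_ms`,
#'   `desat_rate_per_ahi`, `desat_depth_pct`, `male_frac`, `age_med`,
#'   `age_sd`, `height_med`, `height_sd`, `weight_med`, `weight_sd`.
#' @export
default_severity_effects <- function() {
  data.frame(
    class            = severity_levels,
    ahi_lo           = c(0.5,  5,    15,   30),
    ahi_hi           = c(4.5,  14.5, 29.5, 80),
    cyc_amp_ms       = c(8,    20,   35,   55),
    rsa_amp_ms       = c(12,   10,   8,    6),
    white_sd_ms      = c(30,   26,   22,   18),
    desat_rate_per_ahi = c(0.6, 0.6, 0.6, 0.6),
    desat_depth_pct  = c(4,    7,    12,   20),
    male_frac        = c(0.255, 0.429, 0.429, 0.441),
    age_med          = c(41,   52,   56.5, 56),
    age_sd           = c(13,   13,   13,   11),
    height_med       = c(1.62, 1.66, 1.65, 1.63),
    height_sd        = c(0.08, 0.08, 0.09, 0.09),
    weight_med       = c(71.5, 82,   85.5, 98),
    weight_sd        = c(14,   14,   16,   22),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' @param n_per_class subjects per severity class (>= 1).
#' @param hours recording hours per subject (>= 1; the clinical protocol
#'   analyses the first 6 h of sleep).
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @param artifact_rate fraction of beats replaced by ectopic-like spurious
#'   values (0 to 0.1).
#' @param severity_effects per-class parameter table, see
#'   [default_severity_effects()]. Pass the table with all class rows equal
#'   to generate a null cohort in which the label carries no signal.
#' @param spo2_hz SpO2 sampling rate in Hz (>= 0.5).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 60, hours = 6, seed = 1,
                        artifact_rate = 0.01,
                        severity_effects = default_severity_effects(),
                        spo2_hz = 1) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (hours < 1) stop("hours must be >= 1")
  if (artifact_rate < 0 || artifact_rate > 0.1)
    stop("artifact_rate must lie in [0, 0.1]")
  if (spo2_hz < 0.5) stop("spo2_hz must be >= 0.5")
  se <- severity_effects
  need <- c("class", "ahi_lo", "ahi_hi", "cyc_amp_ms", "rsa_amp_ms",
            "white_sd_ms", "desat_rate_per_ahi", "desat_depth_pct",
            "male_frac", "age_med", "age_sd", "height_med", "height_sd",
            "weight_med", "weight_sd")
  if (!all(need %in% names(se)) || !setequal(se$class, severity_levels))
    stop("severity_effects must have one row per severity class ",
         "with the documented columns")
  se <- se[match(severity_levels, se$class), ]
  # AHI ranges must stay inside the class boundaries they are labelled with
  bounds <- list(normal = c(0, 5), mild = c(5, 15),
                 moderate = c(15, 30), severe = c(30, Inf))
  for (i in seq_len(nrow(se))) {
    b <- bounds[[se$class[i]]]
    if (se$ahi_lo[i] < b[1] || se$ahi_hi[i] >= b[2] + 1e-9 ||
        se$ahi_lo[i] > se$ahi_hi[i])
      stop("AHI range for class '", se$class[i],
           "' violates the severity boundaries")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 hours = as.integer(hours), seed = as.integer(seed),
                 artifact_rate = artifact_rate, severity_effects = se,
                 spo2_hz = spo2_hz),
            class = "cohort_spec")
}

#' Null-cohort parameter table
#'
#' Every class receives the physiological parameters of the normal class, so
#' class labels are assigned (by AHI range) but carry no signal in the RRi,
#' SpO2 or anthropometric distributions. Used to calibrate chance-level
#' classifier performance.
#'
#' @return a severity-effects table, see [default_severity_effects()].
#' @export
null_severity_effects <- function() {
  se <- default_severity_effects()
  flat <- se[se$class == "normal", setdiff(names(se), c("class", "ahi_lo", "ahi_hi"))]
  for (col in names(flat)) se[[col]] <- flat[[col]]
  se
}

# one hour of beats: baseline + AM slow cyclic component + RSA tone + white
# noise, with isolated ectopic-like artifacts injected at artifact_rate
simulate_rri_hour <- function(base_rr, eff, cyc_period, artifact_rate,
                              hour_s = 3600) {
  n <- ceiling(hour_s * 1000 / base_rr) + 50L
  t <- base_rr * (seq_len(n) - 1L) / 1000          # approximate beat times, s
  envelope <- 0.5 + 0.5 * sin(2 * pi * t / 600 + runif(1, 0, 2 * pi))
  cyc <- eff$cyc_amp_ms * envelope * sin(2 * pi * t / cyc_period +
                                           runif(1, 0, 2 * pi))
  rsa <- eff$rsa_amp_ms * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
  rr <- base_rr + cyc + rsa + rnorm(n, 0, eff$white_sd_ms)
  rr <- pmax(rr, 250)
  # trim to the hour
  keep <- cumsum(rr) <= hour_s * 1000
  rr <- rr[keep]
  # isolated artifacts: 0.5x or 1.5x the local value, never two adjacent
  n_art <- rbinom(1L, length(rr), artifact_rate)
  if (n_art > 0) {
    idx <- sort(sample.int(length(rr), n_art))
    idx <- idx[c(TRUE, diff(idx) > 1)]
    fac <- sample(c(0.5, 1.5), length(idx), replace = TRUE)
    rr[idx] <- rr[idx] * fac
  } else {
    idx <- integer(0)
  }
  list(rr = rr, artifact_idx = idx)
}

# one night of SpO2: baseline with square desaturation dips plus sensor noise
simulate_spo2 <- function(ahi, eff, hours, hz) {
  n <- as.integer(hours * 3600 * hz)
  base <- runif(1, 95, 98)
  sat <- rep(base, n)
  n_ev <- rpois(1, eff$desat_rate_per_ahi * ahi * hours)
  if (n_ev > 0) {
    onset <- runif(n_ev, 0, hours * 3600)
    dur <- runif(n_ev, 10, 30)
    depth <- pmax(eff$desat_depth_pct + rnorm(n_ev, 0, 1.5), 1)
    for (k in seq_len(n_ev)) {
      i0 <- max(1L, floor(onset[k] * hz) + 1L)
      i1 <- min(n, ceiling((onset[k] + dur[k]) * hz))
      if (i0 <= i1) sat[i0:i1] <- pmin(sat[i0:i1], base - depth[k])
    }
  }
  sat <- sat + rnorm(n, 0, 0.4)
  spo2_trace(pmin(pmax(sat, 40), 100), sample_hz = hz)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate a synthetic OSA cohort
#'
#' Draws `n_per_class` subjects per severity class. Each subject carries one
#' RRi series per recording hour (baseline mean RR drawn in 700-1000 ms,
#' white short-term variability, an amplitude-modulated apnea-linked slow
#' oscillation with period 30-60 s whose amplitude scales with severity, a
#' respiratory sinus-arrhythmia tone, and isolated ectopic-like artifacts at
#' `artifact_rate`), an SpO2 trace (baseline 95-98% with square desaturation
#' dips at a rate proportional to the AHI, clipped to \[40, 100\]), and
#' anthropometrics drawn from truncated normals centred per class.
#'
#' The cohort is deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return list of subject records (class `osa_cohort`); each subject is a
#'   list with fields `id`, `gender`, `age`, `height`, `weight`, `bmi`,
#'   `ahi`, `severity`, `binary`, `rri_hours` (list of [rri_series()]),
#'   `spo2` ([spo2_trace()]) and `artifact_idx` (per-hour injected artifact
#'   positions, for validation).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  se <- spec$severity_effects
  subjects <- vector("list", 4L * spec$n_per_class)
  k <- 0L
  # per-subject substreams keyed off the spec seed keep the draw order
  # independent of class ordering
  for (ci in seq_len(nrow(se))) {
    eff <- se[ci, ]
    for (j in seq_len(spec$n_per_class)) {
      k <- k + 1L
      set.seed((as.numeric(spec$seed) * 10007 + k) %% 2147483647)
      ahi <- runif(1, eff$ahi_lo, eff$ahi_hi)
      gender <- if (runif(1) < eff$male_frac) "male" else "female"
      age <- truncnorm1(eff$age_med, eff$age_sd, 18, 90)
      height <- truncnorm1(eff$height_med, eff$height_sd, 1.40, 2.05)
      weight <- truncnorm1(eff$weight_med, eff$weight_sd, 40, 180)
      base_rr <- runif(1, 700, 1000)
      cyc_period <- runif(1, 30, 60)
      rri_hours <- vector("list", spec$hours)
      artifact_idx <- vector("list", spec$hours)
      for (h in seq_len(spec$hours)) {
        sim <- simulate_rri_hour(base_rr, eff, cyc_period,
                                 spec$artifact_rate)
        rri_hours[[h]] <- rri_series(sim$rr, t_start = (h - 1L) * 3600)
        artifact_idx[[h]] <- sim$artifact_idx
      }
      spo2 <- simulate_spo2(ahi, eff, spec$hours, spec$spo2_hz)
      subjects[[k]] <- list(
        id = sprintf("S%03d", k), gender = gender,
        age = age, height = height, weight = weight,
        bmi = weight / height^2, ahi = ahi,
        severity = as.character(classify_severity(ahi)),
        binary = as.character(classify_binary(ahi)),
        rri_hours = rri_hours, spo2 = spo2,
        artifact_idx = artifact_idx)
    }
  }
  structure(subjects, class = "osa_cohort")
}

#' @export
print.osa_cohort <- function(x, ...) {
  sev <- table(factor(vapply(x, `[[`, "", "severity"),
                      levels = severity_levels))
  cat(sprintf("<osa_cohort> %d subjects (%s)\n", length(x),
              paste(names(sev), sev, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort an `osa_cohort`.
#' @return data.frame with one row per subject: id, gender, age, height,
#'   weight, bmi, ahi, severity, binary label.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    id = vapply(cohort, `[[`, "", "id"),
    gender = vapply(cohort, `[[`, "", "gender"),
    age = vapply(cohort, `[[`, 0, "age"),
    height = vapply(cohort, `[[`, 0, "height"),
    weight = vapply(cohort, `[[`, 0, "weight"),
    bmi = vapply(cohort, `[[`, 0, "bmi"),
    ahi = vapply(cohort, `[[`, 0, "ahi"),
    severity = vapply(cohort, `[[`, "", "severity"),
    binary = vapply(cohort, `[[`, "", "binary"),
    stringsAsFactors = FALSE)
}

#' Write a cohort to disk as plain CSV files
#'
#' Writes `manifest.csv` plus, per subject, one single-column RRi CSV per
#' hour (`<id>_rri_h<hour>.csv`, ms) and one SpO2 CSV (`<id>_spo2.csv`,
#' columns `t` seconds and `sat` percent).
#'
#' @param cohort an `osa_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort_manifest(cohort), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  for (s in cohort) {
    for (h in seq_along(s$rri_hours))
      write.csv(data.frame(rri_ms = s$rri_hours[[h]]$values),
                file.path(dir, sprintf("%s_rri_h%d.csv", s$id, h)),
                row.names = FALSE)
    write.csv(data.frame(t = s$spo2$t, sat = s$spo2$sat),
              file.path(dir, sprintf("%s_spo2.csv", s$id)),
              row.names = FALSE)
  }
  invisible(dir)
}
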