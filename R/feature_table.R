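#' Names of the anthropometric feature columns
#' @export
anthropometric_names <- c("Gender", "Age", "Height", "Weight", "BMI")

#' Names of the oximetry feature columns
#' @export
spo2_index_names <- c("SatMin", "T90")

#' Assemble the per-subject feature table
#'
#' For every subject: selects the cleanest 15-minute window of each of the
#' first `n_hours` recording hours ([select_segments()]), applies
#' spurious-beat correction ([correct_rri()]), computes the 34-index HRV
#' profile of each segment ([hrv_indices()]) and averages it across hours;
#' adds SatMin and T90 from the SpO2 trace and the anthropometric
#' attributes (gender encoded male = 1, female = 0). Subjects with fewer
#' than `n_hours` hours, an hour shorter than 15 minutes, or any segment
#' exceeding the corrected-beat bound are dropped and logged.
#'
#' @param cohort an `osa_cohort` (or any list of subject records with the
#'   same fields, e.g. from [ingest_subject()]).
#' @param n_hours hourly segments required per subject.
#' @param correction a [correction_params()].
#' @param spectral a [spectral_config()].
#' @param nonlinear a [nonlinear_params()].
#' @return data.frame (one row per retained subject) with columns `id`, the
#'   34 HRV indices, `SatMin`, `T90`, `Gender`, `Age`, `Height`, `Weight`,
#'   `BMI`, `severity`, `binary`. The attribute `exclusions` is a data.frame
#'   (id, reason) for dropped subjects.
#' @export
build_feature_table <- function(cohort, n_hours = 6,
                                correction = correction_params(),
                                spectral = spectral_config(),
                                nonlinear = nonlinear_params()) {
  rows <- vector("list", length(cohort))
  excl <- list()
  for (si in seq_along(cohort)) {
    s <- cohort[[si]]
    res <- tryCatch({
      segs <- select_segments(s$rri_hours, n_hours = n_hours,
                              params = correction)
      mat <- matrix(NA_real_, n_hours, length(hrv_index_names),
                    dimnames = list(NULL, hrv_index_names))
      for (h in seq_len(n_hours)) {
        seg <- correct_rri(segs[[h]], correction)
        if (!rri_eligible(seg))
          stop("poor quality: segment hour ", h, " exceeds ",
               100 * correction$max_corrected_frac, "% corrected beats")
        mat[h, ] <- hrv_indices(seg, spectral, nonlinear)
      }
      hrv_mean <- colMeans(mat)
      df <- data.frame(id = s$id, stringsAsFactors = FALSE)
      df[hrv_index_names] <- as.list(unname(hrv_mean))
      df$SatMin <- sat_min(s$spo2)
      df$T90 <- t90(s$spo2)
      df$Gender <- as.numeric(s$gender == "male")
      df$Age <- s$age
      df$Height <- s$height
      df$Weight <- s$weight
      df$BMI <- s$bmi
      df$severity <- s$severity
      df$binary <- s$binary
      df
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <- data.frame(id = s$id, reason = res,
                                              stringsAsFactors = FALSE)
    } else {
      rows[[si]] <- res
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (!is.null(tab)) rownames(tab) <- NULL
  attr(tab, "exclusions") <- if (length(excl)) do.call(rbind, excl)
    else data.frame(id = character(0), reason = character(0))
  tab
}

#' Feature columns of the three published input sets
#'
#' @param set one of `"hrv"` (HRV + anthropometrics), `"spo2"` (SpO2 +
#'   anthropometrics) or `"all"` (HRV + SpO2 + anthropometrics).
#' @return character vector of feature-table column names.
#' @export
feature_set_columns <- function(set = c("all", "hrv", "spo2")) {
  set <- match.arg(set)
  switch(set,
         hrv = c(hrv_index_names, anthropometric_names),
         spo2 = c(spo2_index_names, anthropometric_names),
         all = c(hrv_index_names, spo2_index_names, anthropometric_names))
}
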