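#' OSA severity classes
#'
#' Ordered severity levels used throughout the pipeline.
#' @export
severity_levels <- c("normal", "mild", "moderate", "severe")

#' Binary screening labels (AHI cutoff of 15 events/h)
#' @export
binary_levels <- c("normal-to-mild", "moderate-to-severe")

#' Classify OSA severity from the apnea-hypopnea index
#'
#' Maps AHI (events per hour of sleep) to the four standard severity classes.
#' Boundaries are half-open on the left: an AHI of exactly 5, 15 or 30 falls
#' in the higher class, so that the clinical cutoff of 15 places a patient in
#' the moderate-to-severe group.
#'
#' @param ahi numeric vector of AHI values (events/h), all >= 0.
#' @return factor with levels `normal < mild < moderate < severe`.
#' @examples
#' classify_severity(c(2.6, 10, 15, 57.7))
#' @export
classify_severity <- function(ahi) {
  ahi <- as.numeric(ahi)
  if (any(!is.finite(ahi)) || any(ahi < 0))
    stop("AHI must be finite and non-negative")
  cls <- cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
             labels = severity_levels)
  factor(cls, levels = severity_levels, ordered = TRUE)
}

#' Binary relabeling of OSA severity (AHI cutoff 15)
#'
#' @param ahi numeric vector of AHI values (events/h).
#' @return factor with levels `normal-to-mild`, `moderate-to-severe`;
#'   AHI >= 15 maps to `moderate-to-severe`.
#' @export
classify_binary <- function(ahi) {
  ahi <- as.numeric(ahi)
  if (any(!is.finite(ahi)) || any(ahi < 0))
    stop("AHI must be finite and non-negative")
  factor(ifelse(ahi >= 15, binary_levels[2], binary_levels[1]),
         levels = binary_levels)
}
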