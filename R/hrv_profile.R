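#' Names of the 34 HRV indices, in report order
#' @export
hrv_index_names <- c(
  "MeanRR", "SDNN", "RMSSD", "VLFabs", "LFabs", "HFabs", "LFnu", "HFnu",
  "LF/HF", "DFA-a1", "SampEn", "FuzzyEn", "DispEn", "PhaseEn", "DistEn",
  "PermEn", "AttEn", "Symb-0V", "Symb-1V", "Symb-2LV", "Symb-2UV",
  "Bin-0V", "Bin-1V", "Bin-2V", "HRF-PIP", "HRF-W0", "HRF-W1", "HRF-W2",
  "HRF-W3", "Porta", "Guzik", "Ehlers", "AC", "DC")

#' Compute the full 34-index HRV profile of one RRi segment
#'
#' Evaluates the three time-domain statistics, the six spectral indices, and
#' the 25 nonlinear indices on a single analysis-ready segment (typically a
#' corrected 15-minute window).
#'
#' @param series an [rri_series()] or numeric RR vector (ms).
#' @param spectral a [spectral_config()].
#' @param nonlinear a [nonlinear_params()].
#' @return named numeric vector of length 34 (see [hrv_index_names]).
#' @export
hrv_indices <- function(series, spectral = spectral_config(),
                        nonlinear = nonlinear_params()) {
  np <- nonlinear
  out <- c(
    hrv_time_domain(series),
    hrv_spectral(series, spectral),
    `DFA-a1` = dfa_alpha1(series, np$dfa_scales),
    SampEn = sample_entropy(series, np$sampen_m, r_frac = np$sampen_r_frac),
    FuzzyEn = fuzzy_entropy(series, np$fuzzy_m, r_frac = np$fuzzy_r_frac,
                            n_fuzzy = np$fuzzy_n),
    DispEn = dispersion_entropy(series, np$disp_m, np$disp_nc),
    PhaseEn = phase_entropy(series, np$phase_k),
    DistEn = distribution_entropy(series, np$dist_m, np$dist_bins),
    PermEn = permutation_entropy(series, np$perm_m, np$perm_noise_frac),
    AttEn = attention_entropy(series),
    symbolic_maxmin(series),
    symbolic_binary(series),
    fragmentation(series),
    asymmetry_indices(series),
    prsa_acdc(series, np$prsa_L, np$prsa_filter))
  stopifnot(identical(names(out), hrv_index_names))
  out
}
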