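#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one nested list.
#' Parameters that appear in the standard parameterisation of each method
#' (resampling rate, FFT segment length and overlap, band edges, entropy
#' parameters, forest size, SMOTE k, fold and bootstrap counts, AHI
#' cutoffs) carry their published defaults; parameters the methods leave
#' open (correction window and tolerance, VLF lower bound, PRSA window,
#' tie-break noise) are marked `assumed = TRUE` in the `assumed` block.
#'
#' @param seed global RNG seed.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @param correction a [correction_params()].
#' @param spectral a [spectral_config()].
#' @param nonlinear a [nonlinear_params()].
#' @param cohort a [cohort_spec()] (used with `simulate = TRUE`).
#' @param n_hours hourly segments per subject.
#' @param ml named list of machine-learning settings (n_trees, cv_folds,
#'   smote_k, bootstrap_reps).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("osahrv_"),
                            correction = correction_params(),
                            spectral = spectral_config(),
                            nonlinear = nonlinear_params(),
                            cohort = cohort_spec(seed = seed),
                            n_hours = 6,
                            ml = list(n_trees = 100, cv_folds = 10,
                                      smote_k = 5, bootstrap_reps = 2000)) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, correction = correction,
    spectral = spectral, nonlinear = nonlinear, cohort = cohort,
    n_hours = n_hours, ml = ml,
    assumed = list(correction.W = TRUE, correction.T = TRUE,
                   spectral.vlf_lo = TRUE, nonlinear.perm_noise_frac = TRUE,
                   nonlinear.prsa_L = TRUE, nonlinear.prsa_filter = TRUE,
                   segments.step = TRUE)),
    class = "pipeline_config")
}

#' Ingest one subject from plain CSV files
#'
#' Reads per-hour single-column RRi CSVs (ms) and a two-column SpO2 CSV
#' (`t` seconds, `sat` percent) together with one manifest row, validating
#' units and completeness. Error messages are prefixed with the exclusion
#' category they correspond to (`corrupted`, `insufficient time`,
#' `missing data`).
#'
#' @param rri_csv_paths character vector of per-hour RRi CSV paths, in
#'   hour order.
#' @param spo2_csv_path SpO2 CSV path.
#' @param manifest_row one-row data.frame with columns id, gender, age,
#'   height, weight, bmi, ahi.
#' @param n_hours required number of recording hours.
#' @return a subject record (same shape as the elements of an
#'   `osa_cohort`).
#' @export
ingest_subject <- function(rri_csv_paths, spo2_csv_path, manifest_row,
                           n_hours = 6) {
  need <- c("id", "gender", "age", "height", "weight", "bmi", "ahi")
  miss <- setdiff(need, names(manifest_row))
  if (length(miss) || anyNA(manifest_row[need]))
    stop("missing data: manifest fields ", paste(miss, collapse = ", "))
  if (length(rri_csv_paths) < n_hours)
    stop("insufficient time: ", length(rri_csv_paths),
         " h of RRi files (", n_hours, " required)")
  rri_hours <- lapply(seq_along(rri_csv_paths), function(h) {
    p <- rri_csv_paths[h]
    if (!file.exists(p)) stop("corrupted: missing file ", p)
    v <- tryCatch(read.csv(p)[[1]],
                  error = function(e) stop("corrupted: unreadable ", p))
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("corrupted: non-positive or non-numeric RR intervals in ", p)
    if (any(v < 200) || any(v > 4000))
      stop("corrupted: RR intervals outside 200-4000 ms in ", p)
    rri_series(v, t_start = (h - 1) * 3600)
  })
  if (!file.exists(spo2_csv_path))
    stop("corrupted: missing file ", spo2_csv_path)
  sp <- read.csv(spo2_csv_path)
  if (!all(c("t", "sat") %in% names(sp)))
    stop("corrupted: SpO2 CSV needs columns t, sat")
  dt <- diff(sp$t)
  hz <- 1 / median(dt)
  spo2 <- spo2_trace(sp$sat, sample_hz = hz, t0 = sp$t[1])
  ahi <- manifest_row$ahi
  list(id = as.character(manifest_row$id),
       gender = as.character(manifest_row$gender),
       age = manifest_row$age, height = manifest_row$height,
       weight = manifest_row$weight, bmi = manifest_row$bmi, ahi = ahi,
       severity = as.character(classify_severity(ahi)),
       binary = as.character(classify_binary(ahi)),
       rri_hours = rri_hours, spo2 = spo2,
       artifact_idx = NULL)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and per-subject CSVs.
#' @param n_hours hours per subject to ingest.
#' @return an `osa_cohort`.
#' @export
read_cohort <- function(dir, n_hours = 6) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("empty cohort manifest")
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    paths <- file.path(dir, sprintf("%s_rri_h%d.csv", id, seq_len(n_hours)))
    paths <- paths[file.exists(paths)]
    ingest_subject(paths, file.path(dir, sprintf("%s_spo2.csv", id)),
                   manifest[i, ], n_hours = n_hours)
  })
  structure(subjects, class = "osa_cohort")
}

#' Run the full pipeline on a cohort
#'
#' Executes cohort generation (or ingestion), segment selection and
#' correction, feature extraction, and the classification experiment,
#' writing the feature table, exclusion log and model report under
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param cohort an `osa_cohort`; when `NULL` the synthetic cohort defined
#'   by `config$cohort` is generated.
#' @param task,feature_set forwarded to [experiment_spec()].
#' @return the `osa_model_report`, invisibly; artifacts on disk:
#'   `feature_table.csv`, `exclusions.csv`, `model_report.json`,
#'   `config.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         task = "binary", feature_set = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  if (length(cohort) == 0) stop("empty cohort")
  tab <- build_feature_table(cohort, n_hours = config$n_hours,
                             correction = config$correction,
                             spectral = config$spectral,
                             nonlinear = config$nonlinear)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no eligible subjects after exclusions")
  spec <- experiment_spec(feature_set = feature_set, task = task,
                          n_trees = config$ml$n_trees,
                          cv_folds = config$ml$cv_folds,
                          smote_k = config$ml$smote_k,
                          seed = config$seed,
                          bootstrap_reps = config$ml$bootstrap_reps)
  report <- run_experiment(tab, spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, file.path(config$out_dir, "feature_table.csv"),
            row.names = FALSE)
  write.csv(attr(tab, "exclusions"),
            file.path(config$out_dir, "exclusions.csv"), row.names = FALSE)
  write_model_report(report, file.path(config$out_dir, "model_report.json"))
  jsonlite::write_json(
    list(seed = config$seed, n_hours = config$n_hours, ml = config$ml,
         correction = unclass(config$correction),
         spectral = unclass(config$spectral),
         nonlinear = unclass(config$nonlinear),
         assumed = config$assumed),
    file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Serialise a model report to JSON
#'
#' @param report an `osa_model_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(
    list(task = report$spec$task, feature_set = report$spec$feature_set,
         auroc = report$auroc, importance = report$importance,
         fold_info = report$fold_info),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
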