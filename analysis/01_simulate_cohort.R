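#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates the default synthetic cohort (60 subjects per OSA severity
# class, 6 recording hours each, 1% ectopic-like artifact contamination)
# and writes the subject manifest plus a per-class summary in the layout of
# a clinical cohort-description table: median (1st-3rd quartile) for the
# continuous variables, count (%) of men.

suppressPackageStartupMessages(library(osahrv))
dir.create("results", showWarnings = FALSE)

SEED <- 2024
cohort <- generate_cohort(cohort_spec(n_per_class = 60, hours = 6,
                                      seed = SEED))
man <- cohort_manifest(cohort)
write.csv(man, "results/cohort_manifest.csv", row.names = FALSE)

fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", median(v),
                           quantile(v, 0.25), quantile(v, 0.75))
sev <- factor(man$severity, levels = severity_levels)
summary_tab <- data.frame(
  variable = c("Sex (men)", "Age (years)", "Height (m)", "Weight (kg)",
               "BMI", "AHI", "T90 (%)", "SatMin (%)"))
t90s <- vapply(cohort, function(s) t90(s$spo2), 0)
smin <- vapply(cohort, function(s) sat_min(s$spo2), 0)
for (cl in severity_levels) {
  i <- sev == cl
  summary_tab[[cl]] <- c(
    sprintf("%d (%.1f%%)", sum(man$gender[i] == "male"),
            100 * mean(man$gender[i] == "male")),
    fmt(man$age[i]), fmt(man$height[i]), fmt(man$weight[i]),
    fmt(man$bmi[i]), fmt(man$ahi[i]), fmt(t90s[i]), fmt(smin[i]))
}
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)

cat("Simulated", length(cohort), "subjects (seed", SEED, ").\n")
cat("Cohort structure by severity class:\n")
print(summary_tab, row.names = FALSE)
cat("\nAs designed, T90 rises and SatMin falls with severity, BMI/weight\n")
cat("shift upward, and the AHI ranges sit inside their class boundaries.\n")
cat("Wrote results/cohort_manifest.csv and results/cohort_summary.csv\n")
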