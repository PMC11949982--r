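# generation is the slow part of these tests, so one small cohort is shared
small_spec <- cohort_spec(n_per_class = 3, hours = 2, seed = 11)
small_cohort <- generate_cohort(small_spec)

test_that("a cohort is a pure function of its spec", {
  again <- generate_cohort(cohort_spec(n_per_class = 3, hours = 2, seed = 11))
  expect_identical(small_cohort, again)
  other <- generate_cohort(cohort_spec(n_per_class = 3, hours = 2, seed = 12))
  expect_false(identical(small_cohort, other))
})

test_that("subject records satisfy their structural invariants", {
  for (s in small_cohort) {
    expect_equal(s$bmi, s$weight / s$height^2, tolerance = 0.1)
    expect_equal(s$severity, as.character(classify_severity(s$ahi)))
    expect_length(s$rri_hours, small_spec$hours)
    for (h in s$rri_hours) {
      expect_true(all(h$values > 0))
      expect_gte(rri_duration(h), 3500)
    }
    expect_true(all(s$spo2$sat >= 40 & s$spo2$sat <= 100))
  }
  sev <- vapply(small_cohort, `[[`, "", "severity")
  expect_equal(unname(table(factor(sev, levels = severity_levels))),
               rep(3L, 4), ignore_attr = TRUE)
})

test_that("cohort spec validation rejects out-of-range parameters", {
  expect_error(cohort_spec(n_per_class = 0), "n_per_class")
  expect_error(cohort_spec(artifact_rate = 0.5), "artifact_rate")
  se <- default_severity_effects()
  se$ahi_hi[se$class == "normal"] <- 9   # normal AHI range crossing 5
  expect_error(cohort_spec(severity_effects = se), "severity boundaries")
})

test_that("severity gradients point the right way: T90, SatMin, cyclic power, BMI", {
  co <- generate_cohort(cohort_spec(n_per_class = 20, hours = 1, seed = 3))
  man <- cohort_manifest(co)
  t90s <- vapply(co, function(s) t90(s$spo2), 0)
  smin <- vapply(co, function(s) sat_min(s$spo2), 0)
  sdnn <- vapply(co, function(s) sd(s$rri_hours[[1]]$values), 0)
  by_class <- function(v) tapply(v, factor(man$severity, severity_levels), mean)
  expect_gt(by_class(t90s)["severe"], by_class(t90s)["normal"])
  expect_true(all(diff(by_class(t90s)) > 0))          # monotone in severity
  expect_true(all(diff(by_class(smin)) < 0))
  # weight/BMI: the generating medians increase with class; observed group
  # means at this n separate cleanly only at the extremes (the mild and
  # moderate classes are nearly equal by design)
  expect_true(all(diff(default_severity_effects()$weight_med) > 0))
  expect_gt(by_class(man$bmi)["severe"], by_class(man$bmi)["normal"])
  # the slow cyclic component dominates total variability in severe subjects
  expect_gt(by_class(sdnn)["severe"], by_class(sdnn)["normal"])
})

test_that("with artifact_rate = 0 the correction stage finds nothing to fix", {
  co <- generate_cohort(cohort_spec(n_per_class = 1, hours = 1, seed = 5,
                                    artifact_rate = 0))
  for (s in co) {
    fixed <- correct_rri(s$rri_hours[[1]])
    expect_equal(fixed$n_corrected, 0)
    expect_equal(fixed$values, s$rri_hours[[1]]$values)
  }
})

test_that("null severity effects equalise physiology but keep labels", {
  se <- null_severity_effects()
  phys <- setdiff(names(se), c("class", "ahi_lo", "ahi_hi"))
  for (col in phys) expect_equal(length(unique(se[[col]])), 1L)
  expect_equal(se$ahi_lo, default_severity_effects()$ahi_lo)
})

test_that("a cohort written to CSV reads back with identical signals", {
  dir <- tempfile("cohort_")
  write_cohort(small_cohort, dir)
  back <- read_cohort(dir, n_hours = small_spec$hours)
  expect_length(back, length(small_cohort))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$rri_hours[[1]]$values,
                 small_cohort[[i]]$rri_hours[[1]]$values)
    expect_equal(back[[i]]$spo2$sat, small_cohort[[i]]$spo2$sat)
    expect_equal(back[[i]]$ahi, small_cohort[[i]]$ahi, tolerance = 1e-6)
    expect_equal(back[[i]]$severity, small_cohort[[i]]$severity)
  }
  unlink(dir, recursive = TRUE)
})
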