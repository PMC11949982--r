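series_battery <- random_test_series(20)

test_that("SampEn matches the brute-force template count on random series", {
  for (x in series_battery) {
    r <- 0.15 * sd(x)
    expect_equal(sample_entropy(x, m = 2, r = r),
                 oracle_sampen(x, 2, r), tolerance = 1e-12)
  }
  # the fixed-fixture case: 30 points, r = 0.2 SD
  set.seed(77)
  x30 <- 800 + 40 * rnorm(30)
  expect_equal(sample_entropy(x30, m = 2, r = 0.2 * sd(x30)),
               oracle_sampen(x30, 2, 0.2 * sd(x30)), tolerance = 1e-10)
})

test_that("FuzzyEn matches the brute-force membership sum", {
  for (x in series_battery[1:10]) {
    r <- 0.15 * sd(x)
    expect_equal(fuzzy_entropy(x, m = 2, r = r, n_fuzzy = 2),
                 oracle_fuzzyen(x, 2, r, 2), tolerance = 1e-9)
  }
})

test_that("DispEn matches the brute-force dispersion-pattern tabulation", {
  for (x in series_battery)
    expect_equal(dispersion_entropy(x, m = 3, nc = 6),
                 oracle_dispen(x, 3, 6), tolerance = 1e-12)
})

test_that("PermEn matches the brute-force ordinal-pattern tabulation", {
  for (x in series_battery)   # continuous draws: tie-free, noise disabled
    expect_equal(permutation_entropy(x, m = 3, noise_frac = 0),
                 oracle_permen(x, 3), tolerance = 1e-12)
})

test_that("both symbolic schemes match brute-force word classification", {
  for (x in series_battery) {
    expect_equal(symbolic_maxmin(x), oracle_maxmin(x), tolerance = 1e-12)
    expect_equal(symbolic_binary(x), oracle_binary_symb(x), tolerance = 1e-12)
  }
})

test_that("fragmentation matches brute-force inflection counting", {
  for (x in series_battery)
    expect_equal(fragmentation(x), oracle_hrf(x), tolerance = 1e-12)
  # zero-difference symbols participate: a repeated value breaks a run
  x <- c(800, 810, 810, 820, 815, 815, 800, 805, 810)
  expect_equal(fragmentation(x), oracle_hrf(x), tolerance = 1e-12)
})

test_that("asymmetry indices match their definitions", {
  for (x in series_battery)
    expect_equal(asymmetry_indices(x), oracle_asymmetry(x), tolerance = 1e-12)
  d <- c(30, -10, -10, -10)                 # worked example
  x <- 800 + cumsum(c(0, d))
  a <- asymmetry_indices(x)
  expect_equal(unname(a["Porta"]), 75)
  expect_equal(unname(a["Guzik"]), 100 * 900 / 1200)
})

test_that("PRSA matches the brute-force aligned average", {
  for (x in series_battery) {
    v <- prsa_acdc(x, L = 8, filter = 0.05)
    expect_equal(unname(v["AC"]), oracle_prsa(x, 8, 0.05, "ac"),
                 tolerance = 1e-12)
    expect_equal(unname(v["DC"]), oracle_prsa(x, 8, 0.05, "dc"),
                 tolerance = 1e-12)
  }
})

test_that("negating a series around its mean swaps AC and DC exactly", {
  set.seed(51)
  x <- 800 + 25 * rnorm(300)
  y <- 2 * mean(x) - x
  big <- 1e9                                # disable the anchor filter
  vx <- prsa_acdc(x, filter = big)
  vy <- prsa_acdc(y, filter = big)
  expect_equal(unname(vx["DC"]), -unname(vy["AC"]), tolerance = 1e-9)
  expect_equal(unname(vx["AC"]), -unname(vy["DC"]), tolerance = 1e-9)
})

test_that("a constant series has no PRSA anchors", {
  v <- prsa_acdc(rep(800, 100))
  expect_true(all(is.na(v)))
})

test_that("DFA alpha-1 recovers the known exponents of white and Brownian noise", {
  whites <- browns <- numeric(20)
  for (s in 1:20) {
    set.seed(60 + s)
    w <- rnorm(1000)
    whites[s] <- dfa_alpha1(w + 800)
    browns[s] <- dfa_alpha1(cumsum(w) + 800)
  }
  expect_gte(mean(whites), 0.4); expect_lte(mean(whites), 0.6)
  expect_gte(mean(browns), 1.35); expect_lte(mean(browns), 1.65)
})

test_that("shuffling destroys the correlations DFA and Symb-0V measure", {
  dfa_drop <- symb_drop <- logical(50)
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 400
    x <- 800 + 40 * sin(2 * pi * (1:n) / 50) + 8 * rnorm(n)
    xs <- sample(x)
    dfa_drop[s] <- dfa_alpha1(x) > dfa_alpha1(xs)
    symb_drop[s] <- symbolic_maxmin(x)["Symb-0V"] >=
      symbolic_maxmin(xs)["Symb-0V"]
  }
  expect_gte(mean(dfa_drop), 0.9)
  expect_gte(mean(symb_drop), 0.9)
})

test_that("SampEn and DistEn of an i.i.d. series are shuffle-invariant in distribution", {
  set.seed(71)
  base <- 800 + 30 * rnorm(250)
  se0 <- sample_entropy(base)
  de0 <- distribution_entropy(base)
  ses <- des <- numeric(30)
  for (s in 1:30) {
    set.seed(200 + s)
    xs <- sample(base)
    ses[s] <- sample_entropy(xs)
    des[s] <- distribution_entropy(xs)
  }
  # the unshuffled value sits inside the shuffled distribution
  expect_gte(se0, min(ses) - 2 * sd(ses))
  expect_lte(se0, max(ses) + 2 * sd(ses))
  expect_gte(de0, min(des) - 2 * sd(des))
  expect_lte(de0, max(des) + 2 * sd(des))
})

test_that("SampEn with SD-scaled tolerance is scale-invariant", {
  set.seed(72)
  x <- 800 + 35 * rnorm(200)
  expect_equal(sample_entropy(x), sample_entropy(3.7 * x), tolerance = 1e-9)
})

test_that("degenerate and limiting inputs take their documented conventions", {
  const <- rep(800, 120)
  expect_equal(sample_entropy(const), 0)
  expect_equal(fuzzy_entropy(const), 0)
  expect_equal(dispersion_entropy(const), 0)
  expect_equal(permutation_entropy(const), 0)
  expect_true(is.na(distribution_entropy(const)))
  expect_true(is.na(phase_entropy(const)))
  expect_true(is.na(attention_entropy(const)))
  expect_true(is.na(dfa_alpha1(const)))
  expect_true(all(is.na(symbolic_maxmin(const))))
  expect_true(all(is.na(asymmetry_indices(const))))
  # monotone ramp: a single ordinal pattern
  expect_equal(permutation_entropy(800 + 1:100), 0)
  # strictly increasing: one binary symbol, no inflection points
  ramp <- 800 + (1:100) * 2
  expect_equal(unname(symbolic_binary(ramp)["Bin-0V"]), 100)
  hrf <- fragmentation(ramp)
  expect_equal(unname(hrf[c("HRF-PIP", "HRF-W0")]), c(0, 100))
})

test_that("constructed patterns land in the expected symbolic families", {
  staircase <- seq(0.5, 5.5, by = 1) * 100          # one new bin per beat
  expect_equal(unname(symbolic_maxmin(staircase)["Symb-2LV"]), 100)
  alt <- c(rep(c(700, 900), 10), 700)   # two-bin alternation, balanced diffs
  expect_equal(unname(symbolic_maxmin(alt)["Symb-2UV"]), 100)
  expect_equal(unname(symbolic_binary(alt)["Bin-2V"]), 100)
  hrf <- fragmentation(alt)
  expect_equal(unname(hrf[c("HRF-PIP", "HRF-W3")]), c(100, 100))
  a <- asymmetry_indices(alt)
  expect_equal(unname(a), c(50, 50, 0))
})

test_that("Porta's index is unbiased at 50 for symmetric differences", {
  porta <- numeric(50)
  for (s in 1:50) {
    set.seed(300 + s)
    porta[s] <- asymmetry_indices(800 + cumsum(rnorm(200)))["Porta"]
  }
  expect_gte(mean(porta), 48)
  expect_lte(mean(porta), 52)
})

test_that("all percentage families partition to 100", {
  for (x in series_battery[1:5]) {
    expect_equal(unname(sum(symbolic_maxmin(x))), 100, tolerance = 1e-12)
    expect_equal(unname(sum(symbolic_binary(x))), 100, tolerance = 1e-12)
    hrf <- fragmentation(x)
    expect_equal(unname(sum(hrf[c("HRF-W0", "HRF-W1", "HRF-W2", "HRF-W3")])),
                 100, tolerance = 1e-12)
  }
})

test_that("the full profile returns all 34 indices, finite on realistic input", {
  set.seed(81)
  x <- 820 + 30 * rnorm(1000) + 25 * sin(2 * pi * (1:1000) * 0.8 / 45)
  v <- hrv_indices(x)
  expect_named(v, hrv_index_names)
  expect_true(all(is.finite(v)))
  expect_lte(unname(v["AC"]), 0)
  expect_gte(unname(v["DC"]), 0)
})
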