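---
title: "HRV and oximetry profiling for OSA screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV and oximetry profiling for OSA screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osahrv)
```

This vignette documents the models and estimators behind `osahrv`, the
parameter choices that matter, what the synthetic cohort does and does not
emulate, and the numerical conventions adopted where the published methods
leave details open.

## 1. The screening model

Obstructive sleep apnea is graded by the apnea–hypopnea index (AHI):
normal < 5, mild 5–15, moderate 15–30, severe > 30 events/h, with the
clinical screening cutoff AHI ≥ 15 separating normal-to-mild from
moderate-to-severe. We treat all class boundaries as half-open `[lo, hi)`,
so an AHI of exactly 15 is moderate (and moderate-to-severe): this is the
only convention consistent with a cutoff that assigns 15 to the positive
screening class.

The pipeline predicts these labels from three feature modalities computed
per subject: 34 HRV indices (mean over six hourly 15-minute RRi segments),
two oximetry indices (SatMin, T90), and five anthropometric attributes
(gender coded male = 1, age, height, weight, BMI) — 41 features in the
combined set, 39 in HRV + anthropometrics, 7 in SpO₂ + anthropometrics.

## 2. RRi cleaning and segment selection

Spurious beats are detected against a baseline estimated by a centred
moving median of `W` beats; tolerance lines sit at ±`T`·mean(baseline).
Out-of-band beats are replaced by linear interpolation between the nearest
in-band neighbours (runs are replaced as blocks; edge runs take the
nearest in-band value). The published description of this procedure leaves
`W` and `T` unstated; we default to `W = 11` beats and `T = 0.2`, typical
moving-median HRV cleaning settings, and expose both
(`correction_params()`). The correction-recovery tests pass for
`W ∈ {7, 11, 21}`, so the default is not load-bearing. A segment needing
more than 2.5% replacements is ineligible; we apply this bound
**per segment** (the published account does not resolve per-segment vs
per-recording; per-segment is the stricter reading and matches the audit
trail we keep per series).

Where the original protocol chose each hour's best 15 minutes by visual
inspection, we automate it: candidate windows slide in 60-s steps within
the hour, each scored by its fraction of out-of-band beats before
correction, lowest score wins, ties go to the earliest offset. A subject
needs six hours each spanning ≥ 15 min, mirroring the minimum-recording
inclusion rule.

## 3. The 34-index HRV profile

**Time domain.** MeanRR, sample-SD SDNN, RMSSD.

**Spectral.** The tachogram (RR value against cumulative beat time) is
cubic-spline resampled at 3 Hz, split into 512-sample windows with 50%
overlap, mean-removed and Hanning-windowed per window, and the
window-averaged periodogram is integrated over VLF (< 0.04 Hz), LF
(0.04–0.15 Hz) and HF (0.15–0.4 Hz). Two conventions are ours: the window
is power-compensated (PSD divided by the mean squared window) so that
total integrated power equals signal variance — this makes Parseval
testable at the 5% level — and the VLF integration starts at 0.003 Hz
(the band is only stated as "< 0.04 Hz"; a 15-min segment cannot resolve
much below 0.003 Hz anyway). Normalised units divide by LF + HF, which
guarantees LFnu + HFnu = 100. Mean removal per window is the only
detrending applied.

**DFA-α₁.** Integrated mean-centred profile, non-overlapping windows of
n ∈ {6, …, 14} beats (the published scaling range "5 < n < 15" read as
integers), per-window linear detrend, tail beats beyond the last full
window discarded. The suite checks the known limits: α₁ ≈ 0.5 on white
and ≈ 1.5 on Brownian noise.

**Entropies.** SampEn(m = 2, r = 0.15·SD) and FuzzyEn(m = 2, r = 0.15·SD,
exponent 2; r SD-scaled like SampEn) use the first N − m templates for
both template lengths (Richman–Moorman convention). DispEn (m = 3, 6
classes, normal-CDF mapping) and PermEn (order 3) are reported
normalised to [0, 1] by their maxima, following their source definitions.
PermEn breaks ties with uniform noise of amplitude 1e-6·SD under a fixed
internal seed — deterministic, negligible against any real signal, and
exactly zero for a constant series, which therefore keeps a single
ordinal pattern and zero entropy. PhaseEn is the normalised Shannon
entropy of 16-sector angle occupancy in the second-order difference plot
(origin points dropped). DistEn is the normalised base-2 entropy of the
512-bin histogram of pairwise Chebyshev template distances (m = 3).
AttEn averages the base-2 entropies of the four interval distributions
between local-extrema key patterns (max–max, min–min, max–min, min–max).
Degenerate (constant) input conventions: SampEn = FuzzyEn = DispEn =
PermEn = 0 (their limiting values); PhaseEn, DistEn, AttEn, DFA-α₁ and
the Max-Min symbols are undefined and reported missing.

**Symbolic dynamics.** Max-Min: six equal-width bins over [min, max],
3-symbol words classified 0V/1V/2LV/2UV. Binary: symbol 1 for a positive
successive difference, 0 otherwise — a zero difference maps to 0
(non-increase), the only two-symbol-consistent choice, and the oracle
tests pin it. Words of three symbols are classified by their number of
symbol changes.

**Fragmentation.** Ternary difference symbols (1 decreasing, −1
increasing, 0 unchanged); *every* transition between different symbols is
an inflection point, including transitions through 0 — we follow the
stated rule ("all except 1–1, −1–−1, 0–0") even though the original
fragmentation papers treat zeros differently. PIP is the inflection
fraction of all transitions; 4-symbol words are classified by internal
inflection count (W0–W3).

**Asymmetry.** Over nonzero ΔRR: Porta = % negative, Guzik = % of squared
mass from positive differences, Ehlers = ΣΔ³/(ΣΔ²)^{3/2}.

**PRSA.** Anchors are increases (DC) or decreases (AC) bounded by a 5%
change filter; half-window L = 8 beats (both unstated in the source and
exposed in `nonlinear_params()`); capacity is the Bauer 4-point estimate
(X(0) + X(1) − X(−1) − X(−2))/4 on the anchor-aligned average.

The three O(N²) template computations (SampEn, FuzzyEn, DistEn) are
implemented in C++; every combinatorial index is verified against an
independent brute-force R enumeration to 1e-9 on batteries of random
100–300-beat series.

## 4. Oximetry

SatMin is the trace minimum; T90 the strict below-90% fraction of
samples. Total sleep time equals trace duration: no hypnogram exists in
this pipeline, so wake periods inside the recording are not excluded.

## 5. The synthetic cohort

The generator is the package's substitute for a clinical dataset and is a
pure function of its spec (seed included). Per subject: baseline mean RR
~ U(700, 1000) ms; white short-term variability; a respiratory
sinus-arrhythmia tone at 0.25 Hz; an amplitude-modulated sinusoid of
period 30–60 s placing apnea-cycle power in the VLF band, with class
amplitudes 8/20/35/55 ms (normal→severe) and white-noise SDs 30/26/22/18
ms (short-term irregularity falls as severity rises); isolated ectopic
artifacts at 0.5× or 1.5× the local RR with probability
`artifact_rate` (default 1%). SpO₂: baseline U(95, 98)%, square
desaturation dips at 0.6·AHI events/h, 10–30 s long, class depths
4/7/12/20%, sensor noise, clipped to [40, 100]. Anthropometrics are
truncated normals centred per class on values typical of clinical OSA
cohorts (weight medians 71.5/82/85.5/98 kg; male fraction rising from
~26% to ~44%); BMI is computed from the drawn height and weight. AHI is
drawn uniformly inside each class's range, so labels are exact.

These choices are engineering defaults, not physiological claims: the
generator reproduces the *direction and rough magnitude* of the group
differences seen in clinical cohorts (T90 rising from ~0 to ~18%, SatMin
falling from ~90 to ~71% — see `analysis/01_simulate_cohort.R` output),
but its classes are cleaner than clinical reality. There are no sleep
stages, no arousals, no arrhythmia, no drift in sensor calibration, and
the class-conditional distributions barely overlap. Consequently the
classification experiments saturate (AUROC ≈ 1.0 on the default cohort),
which validates the pipeline's mechanics — signal in, signal recovered;
permuted labels collapse to AUROC ≈ 0.5 — but says nothing about
achievable clinical accuracy, and published clinical AUROCs cannot be
reproduced without the original patient data. `null_severity_effects()`
generates the matched null cohort in which labels carry no signal.

## 6. Classification and inference

Stratified 10-fold CV; SMOTE (k = 5, Euclidean neighbours on standardised
features, synthetic points uniform on the segment to a sampled neighbour)
is fit on training folds only — oversampling before splitting leaks
synthetic copies of validation subjects into training and inflates AUROC,
and a structural test asserts the score matrix contains original subjects
only, each scored exactly once. Forests use 100 trees, no depth limit.
Multiclass AUROC is one-vs-rest per class on pooled out-of-fold
probabilities; CIs are percentile bootstrap over subjects (2,000 reps).
Feature importance comes from a single forest on the full SMOTE-balanced
table (as the source protocol describes), normalised to percent of total
impurity decrease — a known reproducibility caveat, since it is not the
CV forest. DeLong's structural-components test compares correlated
AUROCs; the comparison family (three feature-set models per task) is
Benjamini–Hochberg corrected. The null calibration permutes labels and
reruns the full CV+SMOTE pipeline, which is also how the chance-level
acceptance check is implemented.

## 7. Problem sizes and numerical conventions

The study-scale runs use 60 subjects per class × 6 hours, the default
spec of `cohort_spec()`; feature extraction for the 240-subject cohort
takes a few minutes on one core, dominated by the template entropies.
Oracle batteries use 20 series of 100–300 beats; DFA limit checks use 20
seeded 1,000-beat realisations; null calibration uses 20 permutations.
Other conventions: `runmed(endrule = "median")` shrinks the correction
window symmetrically at series edges; `which.min` resolves segment-score
ties to the earliest window; bootstrap resamples that lose a class are
dropped from the CI; SMOTE reduces k with a warning for classes smaller
than k + 1 and duplicates singletons.

## 8. Known limitations

- The pipeline starts at RRi series: no R-peak detection from raw ECG,
  and EDF waveform ingestion is out of scope (CSV is the interchange
  format).
- T90/SatMin use trace duration as total sleep time (no hypnogram).
- The synthetic cohort's separability ceiling means model-comparison
  machinery (DeLong, BH) is exercised mostly in its degenerate regime on
  default data; its correctness is instead certified on constructed score
  sets against brute-force oracles.
- Importances from the full-data forest are not cross-validated.
- AttEn, PhaseEn and DistEn follow our pinned readings of their source
  definitions (Section 3); other implementations differ in normalisation
  and base, so absolute values are comparable only within this package.
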