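# Toy feature tables for classifier tests: all 41 feature columns present,
# with an optional additive signal on T90/SatMin separating the binary
# classes, built without running the signal pipeline.
make_toy_table <- function(n = 120, seed = 1, signal = 3) {
  set.seed(seed)
  tab <- data.frame(id = sprintf("T%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (nm in feature_set_columns("all")) tab[[nm]] <- rnorm(n)
  ahi <- runif(n, 0, 60)
  tab$severity <- as.character(classify_severity(ahi))
  tab$binary <- as.character(classify_binary(ahi))
  sev <- as.integer(factor(tab$severity, levels = severity_levels))
  tab$T90 <- tab$T90 + signal * sev
  tab$SatMin <- tab$SatMin - signal * sev
  tab
}
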