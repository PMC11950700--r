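# Small in-code fixtures shared across test files.

# A tiny mixed-type cohort with one strongly predictive continuous
# feature, one predictive binary feature, and pure-noise columns.
toy_cohort <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    data.frame(
      id = sprintf("r%02d", seq_len(n)),
      signal = y * 2 + rnorm(n, sd = 0.5),
      noise1 = rnorm(n),
      noise2 = runif(n),
      flag = as.numeric(runif(n) < ifelse(y == 1, 0.85, 0.15)),
      outcome = y)
  })
}

toy_schema <- function() {
  feature_schema(c(id = "identifier", signal = "continuous",
                   noise1 = "continuous", noise2 = "continuous",
                   flag = "binary", outcome = "outcome"))
}

# A preprocessed-style table (numeric, no missing) built from a score
# pattern: each feature drawn so its correlation with y is controlled.
make_scored_table <- function(n_features, n = 100, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    cols <- lapply(seq_len(n_features), function(j) rnorm(n))
    names(cols) <- sprintf("f%02d", seq_len(n_features))
    cbind(as.data.frame(cols), outcome = y)
  })
}

schema_for <- function(table, outcome = "outcome") {
  kinds <- vapply(names(table), function(nm) {
    if (nm == outcome) "outcome"
    else if (all(table[[nm]] %in% c(0, 1, NA))) "binary"
    else "continuous"
  }, character(1))
  feature_schema(kinds)
}
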