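# Independent oracles and small fixtures used across the test suite.

# Closed-form OLS of log(rate) on age via raw sums — written independently of
# fit_exponential() as a cross-check of the log-linear estimator.
ols_loglinear_oracle <- function(age, rate) {
  y <- log(rate)
  n <- length(age)
  sx <- sum(age); sy <- sum(y)
  sxx <- sum(age^2); sxy <- sum(age * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  ybar <- sy / n
  ss_res <- sum((y - a - b * age)^2)
  ss_tot <- sum((y - ybar)^2)
  list(r0 = exp(a), b = b, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

# Through-origin OLS of (log(rate) - log(r0)) on age.
ols_fixed_oracle <- function(age, rate, r0) {
  y <- log(rate) - log(r0)
  sum(age * y) / sum(age^2)
}

# A tiny annotated tree: ((A,B),C) with hand-checkable ages 0/1/3.
toy_annotated_tree <- function() {
  parse_annotated_nexus(paste0(
    "((A:1[&rate_median=0.02],B:1[&rate_median=0.04])",
    "[&posterior=1.0,rate_median=0.03]:2,C:3);"))
}

table2_fixture_path <- function() {
  system.file("extdata", "table2_calibrations.tsv", package = "cicadaclock",
              mustWork = TRUE)
}
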