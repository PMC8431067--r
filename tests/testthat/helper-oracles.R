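# Independent oracles and small fixture builders used across test files.

# Brute-force demeaned-sum form of the concentration index for equal weights:
# 2 / (n^2 * ybar) * sum_i y_i * (r_i - rbar), with every sum written as an
# explicit loop so it shares no code with the covariance implementation.
ci_bruteforce <- function(y, r) {
  n <- length(y)
  ybar <- 0
  rbar <- 0
  for (i in seq_len(n)) {
    ybar <- ybar + y[i] / n
    rbar <- rbar + r[i] / n
  }
  acc <- 0
  for (i in seq_len(n)) acc <- acc + y[i] * (r[i] - rbar)
  2 * acc / (n * ybar)
}

# double-loop weighted covariance oracle
cov_bruteforce <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  acc <- 0
  for (i in seq_along(x)) acc <- acc + w[i] * (x[i] - mx) * (y[i] - my)
  acc / sw
}

# small deterministic schema dataset for structural tests
tiny_dataset <- function(n = 400, groups = "A", seed = 100) {
  generate_dataset(preset_scenario("share_like",
    n = n, groups = groups,
    seed = seed
  ))
}

equal_rank <- function(n) (2 * seq_len(n) - 1) / (2 * n)
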