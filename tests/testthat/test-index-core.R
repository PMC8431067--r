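test_that("concentration indices reproduce hand-derived extreme cases", {
  r <- equal_rank(4)
  expect_equal(concentration_index(c(1, 1, 0, 0), r, se = FALSE)$value, -0.5)
  expect_equal(concentration_index(c(0, 0, 1, 1), r, se = FALSE)$value, 0.5)
  expect_equal(erreygers_index(c(1, 1, 0, 0), r, se = FALSE)$value, -1)
  expect_equal(erreygers_index(c(0, 0, 1, 1), r, se = FALSE)$value, 1)
  # constant outcome: no inequality, whatever the ranks
  expect_equal(concentration_index(rep(3, 4), runif(4), se = FALSE)$value, 0)
  expect_equal(generalized_ci(c(-1, -1, 1, 1), r)$value, 0.5)
})

test_that("degenerate and invalid inputs raise typed errors", {
  r <- equal_rank(4)
  expect_error(concentration_index(rep(0, 4), r), class = "hinequity_undefined_index")
  expect_error(erreygers_index(rep(1, 4), r), class = "hinequity_degenerate_outcome")
  expect_error(erreygers_index(rep(0, 4), r), class = "hinequity_degenerate_outcome")
  expect_error(erreygers_index(c(0, 2, 1, 1), r), class = "hinequity_invalid_input")
  expect_error(concentration_index(c(1, 0), c(0.25)), class = "hinequity_invalid_input")
  expect_error(index_standard_error(c(1, 0, 1), rep(0.5, 3)), class = "hinequity_undefined_se")
})

test_that("covariance form matches the brute-force demeaned-sum oracle", {
  set.seed(13)
  for (trial in 1:40) {
    n <- sample(3:50, 1)
    y <- rexp(n) + 0.05
    r <- weighted_frac_rank(rnorm(n))
    ci <- concentration_index(y, r, se = FALSE)$value
    expect_equal(ci, ci_bruteforce(y, r), tolerance = 1e-12)
  }
})

test_that("weighted covariance matches a double-loop oracle", {
  set.seed(29)
  for (trial in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    w <- rgamma(n, 2) + 0.1
    r <- weighted_frac_rank(x, w)
    expect_equal(
      generalized_ci(y, r, w)$value,
      2 * cov_bruteforce(y, r, w),
      tolerance = 1e-12
    )
  }
})

test_that("index algebra: CCI = 4 mean CI, GCI = mean CI, bounds, scale behaviour", {
  set.seed(37)
  for (trial in 1:25) {
    n <- sample(10:200, 1)
    w <- rgamma(n, 2) + 0.1
    r <- weighted_frac_rank(rlnorm(n), w)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    ci <- concentration_index(y, r, w, se = FALSE)
    cci <- erreygers_index(y, r, w, se = FALSE)
    my <- weighted.mean(y, w)
    expect_equal(cci$value, 4 * my * ci$value, tolerance = 1e-12)
    expect_gte(ci$value, my - 1 - 1e-12)
    expect_lte(ci$value, 1 - my + 1e-12)
    expect_true(abs(cci$value) <= 1 + 1e-12)
    # standard CI is scale invariant; the Erreygers index deliberately is not
    v <- rnorm(n)
    if (abs(weighted.mean(v, w)) > 1e-8) {
      expect_equal(
        concentration_index(3.7 * (v - min(v) + 1), r, w, se = FALSE)$value,
        concentration_index(v - min(v) + 1, r, w, se = FALSE)$value,
        tolerance = 1e-10
      )
      expect_equal(
        generalized_ci(v, r, w)$value,
        weighted.mean(v, w) * concentration_index(v, r, w, se = FALSE)$value,
        tolerance = 1e-12
      )
    }
  }
})

test_that("transferring outcome mass from poorest to richest raises the index", {
  set.seed(41)
  n <- 30
  w <- rep(1, n)
  inc <- sort(rlnorm(n))
  r <- weighted_frac_rank(inc, w)
  y <- runif(n, 1, 2)
  ci0 <- concentration_index(y, r, w, se = FALSE)$value
  y2 <- y
  y2[1] <- y2[1] - 0.5
  y2[n] <- y2[n] + 0.5
  expect_gt(concentration_index(y2, r, w, se = FALSE)$value, ci0)
})

test_that("convenient-regression slope equals the covariance-formula index", {
  set.seed(53)
  for (trial in 1:100) {
    n <- 20
    y <- rbinom(n, 1, 0.5)
    if (sum(y) %in% c(0, n)) next
    w <- runif(n, 0.2, 3)
    r <- weighted_frac_rank(rnorm(n), w)
    wn <- w / sum(w) * n
    vr <- sum(wn * (r - weighted.mean(r, wn))^2) / n
    # slope of WLS of the scaled transform on the rank
    slope_of <- function(z) {
      X <- cbind(1, r)
      unname(solve(crossprod(X, wn * X), crossprod(X, wn * z))[2, 1])
    }
    expect_equal(
      slope_of(2 * vr * y / weighted.mean(y, wn)),
      concentration_index(y, r, w, se = FALSE)$value,
      tolerance = 1e-10
    )
    expect_equal(
      slope_of(8 * vr * y),
      erreygers_index(y, r, w, se = FALSE)$value,
      tolerance = 1e-10
    )
  }
})

test_that("robust SE matches the HC1 sandwich oracle and ignores weight scale", {
  set.seed(59)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  w <- runif(n, 0.5, 2)
  r <- weighted_frac_rank(rlnorm(n), w)
  wn <- w / sum(w) * n
  vr <- sum(wn * (r - weighted.mean(r, wn))^2) / n
  fit <- stats::lm(I(8 * vr * y) ~ r, weights = wn)
  expect_equal(
    index_standard_error(y, r, w, kind = "erreygers_CCI"),
    sqrt(sandwich::vcovHC(fit, type = "HC1")[2, 2]),
    tolerance = 1e-10
  )
  # doubling all weights changes nothing
  a <- erreygers_index(y, r, w)
  b <- erreygers_index(y, r, 2 * w)
  expect_equal(a$value, b$value, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  # constant outcome: zero slope but finite SE
  expect_true(is.finite(index_standard_error(rep(1, n), r, w, kind = "generalized_GCI")))
})

test_that("tidy() of an index estimate carries inference columns", {
  d <- tiny_dataset(n = 500)
  est <- erreygers_index(d$y_postponed, d$frac_rank, d$weight)
  td <- tidy(est)
  expect_named(td, c(
    "kind", "estimate", "std.error", "statistic", "p.value",
    "conf.low", "conf.high", "n", "mean_y"
  ))
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_lt(td$conf.low, td$conf.high)
})
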