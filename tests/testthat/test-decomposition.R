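test_that("OLS decomposition of a perfectly explained outcome has zero residual", {
  set.seed(3)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  d <- tibble::tibble(
    ybin = x, xbin = x, weight = runif(n, 0.5, 2),
    eq_income = rlnorm(n), frac_rank = NA_real_
  )
  d$frac_rank <- weighted_frac_rank(d$eq_income, d$weight)
  dec <- decompose_cci(d, "ybin", need = "xbin", nonneed = character(0), model = "ols")
  expect_equal(dec$residual_term, 0, tolerance = 1e-12)
  expect_equal(sum(dec$contributions$contribution), dec$cci_total, tolerance = 1e-12)
  expect_equal(dec$contributions$contribution, dec$cci_total, tolerance = 1e-12)
})

test_that("OLS adding-up identity holds on random schema instances", {
  for (trial in 1:100) {
    d <- tiny_dataset(n = 200, seed = 1000 + trial)
    if (weighted.mean(d$y_postponed, d$weight) %in% c(0, 1)) next
    dec <- decompose_cci(d, "y_postponed", model = "ols")
    gap <- dec$cci_total - sum(dec$contributions$contribution) - dec$residual_term
    expect_lt(abs(gap), 1e-10)
    expect_equal(dec$hi, dec$cci_total - dec$need_sum, tolerance = 1e-12)
  }
})

test_that("probit decomposition reports the residual and the definitional HI", {
  d <- tiny_dataset(n = 2000, seed = 77)
  dec <- decompose_cci(d, "y_postponed", model = "probit")
  expect_equal(dec$hi, dec$cci_total - dec$need_sum, tolerance = 1e-12)
  # all pieces reported and consistent: CCI = need + nonneed + residual
  expect_equal(
    dec$cci_total,
    dec$need_sum + dec$nonneed_sum + dec$residual_term,
    tolerance = 1e-10
  )
  expect_equal(horizontal_inequity(dec), dec$hi)
  g <- glance(dec)
  expect_equal(g$hi, dec$hi)
  td <- tidy(dec)
  expect_setequal(unique(td$class), c("need", "nonneed"))
  roll <- tidy(dec, roll_up = TRUE)
  expect_equal(sum(roll$contribution), sum(td$contribution), tolerance = 1e-12)
  expect_equal(nrow(roll), length(c(need_vars(), nonneed_vars())))
})

test_that("a regressor uncorrelated with the income rank contributes nothing", {
  n <- 8
  r <- equal_rank(n)
  # mirror-symmetric regressor: exactly zero covariance with the rank
  x_sym <- c(1, 0, 0, 1, 1, 0, 0, 1)
  set.seed(10)
  d <- tibble::tibble(
    y = rbinom(n, 1, 0.5), x = x_sym, z = rnorm(n),
    weight = rep(1, n), frac_rank = r, eq_income = exp(r)
  )
  d$y[1] <- 0
  d$y[8] <- 1
  dec <- decompose_cci(d, "y", need = "x", nonneed = "z", model = "ols")
  expect_equal(dec$contributions$contribution[dec$contributions$term == "x"], 0,
    tolerance = 1e-12
  )
})

test_that("with no need variables HI equals the corrected index exactly", {
  d <- tiny_dataset(n = 1500, seed = 12)
  dec <- decompose_cci(d, "y_postponed",
    need = character(0),
    nonneed = c("living_alone", "log_eq_income", "urban"), model = "probit"
  )
  expect_equal(dec$need_sum, 0)
  expect_identical(dec$hi, dec$cci_total)
})

test_that("HI centers on zero when income affects nothing beyond need", {
  # need-only DGP: all systematic concentration flows through need variables
  his <- vapply(1:200, function(i) {
    d <- generate_dataset(preset_scenario("null_need_only", n = 20000, seed = 5000 + i))
    decompose_cci(d, "y_postponed", model = "probit")$hi
  }, numeric(1))
  expect_lt(abs(mean(his)), 0.01)
})

test_that("a direct income effect on denial drives HI negative", {
  his <- vapply(1:200, function(i) {
    d <- generate_dataset(preset_scenario("pro_rich_denial", n = 20000, seed = 7000 + i))
    decompose_cci(d, "y_denied", model = "probit")$hi
  }, numeric(1))
  expect_gte(mean(his < 0), 0.95)
})

test_that("indirect standardization gives a same-sign inequity cross-check", {
  d <- generate_dataset(preset_scenario("pro_rich_denial", n = 20000, seed = 901))
  dec <- decompose_cci(d, "y_denied", model = "probit")
  alt <- hi_indirect(d, "y_denied")
  expect_lt(alt, 0)
  expect_equal(sign(alt), sign(dec$hi))
})

test_that("degenerate outcomes and disjointness violations are typed errors", {
  d <- tiny_dataset(n = 120, seed = 2)
  d$y_denied <- 0L
  expect_error(decompose_cci(d, "y_denied"), class = "hinequity_degenerate_outcome")
  expect_error(
    decompose_cci(d, "y_postponed", need = "female", nonneed = c("female", "urban")),
    "disjoint"
  )
})
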