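test_that("intercept-only probit has the closed-form solution", {
  set.seed(7)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  w <- runif(n, 0.5, 2)
  fit <- fit_probit(y, matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), w)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), qnorm(weighted.mean(y, w)), tolerance = 1e-8)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(11)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, pnorm(0.3 - 0.5 * X[, 2] + X[, 3]))
  w <- runif(n, 0.5, 2)
  for (trial in 1:5) {
    beta <- rnorm(3, sd = 0.5)
    g <- probit_loglik(beta, y, X, w)$gradient
    h <- 1e-5
    g_fd <- vapply(1:3, function(j) {
      e <- numeric(3)
      e[j] <- h
      (probit_loglik(beta + e, y, X, w)$loglik -
        probit_loglik(beta - e, y, X, w)$loglik) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_fd, tolerance = 1e-6)
  }
})

test_that("weighted fit agrees with glm's probit on the full schema", {
  d <- tiny_dataset(n = 2000, seed = 5)
  X <- build_design(d, c(need_vars(), nonneed_vars()))
  fit <- fit_probit(d$y_postponed, X, d$weight)
  df <- as.data.frame(X[, -1])
  names(df) <- make.names(names(df))
  df$y <- d$y_postponed
  wn <- d$weight / sum(d$weight) * nrow(d)
  gfit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial("probit"), weights = wn)
  )
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(stats::coef(gfit)), tolerance = 1e-5)
})

test_that("duplicating rows is identical to doubling their weights", {
  d <- tiny_dataset(n = 300, seed = 21)
  X <- build_design(d, c("female", "chronic", "sah"))
  y <- d$y_postponed
  i <- 1:50
  X_dup <- rbind(X, X[i, ])
  y_dup <- c(y, y[i])
  w_dup <- c(d$weight, d$weight[i])
  w_dbl <- d$weight
  w_dbl[i] <- 2 * w_dbl[i]
  f1 <- fit_probit(y_dup, X_dup, w_dup)
  f2 <- fit_probit(y, X, w_dbl)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("estimates recover a known data-generating process", {
  set.seed(31)
  n <- 50000
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5), x3 = runif(n))
  beta <- c(-0.8, 0.4, -0.3, 0.6)
  y <- as.integer(X %*% beta + rnorm(n) > 0)
  w <- runif(n, 0.5, 1.5)
  fit <- fit_probit(y, X, w)
  se <- sqrt(diag(fit$vcov))
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - beta) / se < 4))
})

test_that("no spurious effects under the null", {
  set.seed(33)
  n <- 10000
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, 0.25)
  fit <- fit_probit(y, X)
  z <- fit$coefficients[-1] / sqrt(diag(fit$vcov))[-1]
  expect_true(all(abs(z) < 4))
})

test_that("partial effects at means scale coefficients by the density", {
  d <- tiny_dataset(n = 600, seed = 8)
  X <- build_design(d, c("female", "chronic"))
  fit <- fit_probit(d$y_postponed, X, d$weight)
  pe <- partial_effects_at_means(fit)
  expect_equal(
    unname(pe),
    unname(dnorm(fit$linear_index_at_means) * fit$coefficients)
  )
  # sign of a partial effect always equals the sign of its coefficient
  expect_equal(sign(pe), sign(fit$coefficients))
  # zero linear index at means: the density factor is phi(0)
  pe0 <- partial_effects_at_means(fit, xbar = c(1, 0, 0) * 0)
  expect_equal(unname(pe0), unname(0.3989422804014327 * fit$coefficients))
  # finite-difference check of d P(y=1)/d chronic at xbar
  h <- 1e-6
  xb <- fit$xbar
  up <- xb
  up["chronic"] <- up["chronic"] + h
  dn <- xb
  dn["chronic"] <- dn["chronic"] - h
  fd <- (pnorm(sum(up * fit$coefficients)) - pnorm(sum(dn * fit$coefficients))) / (2 * h)
  expect_equal(unname(pe["chronic"]), fd, tolerance = 1e-6)
  # a non-converged fit refuses to linearize
  broken <- fit
  broken$converged <- FALSE
  expect_error(partial_effects_at_means(broken), class = "hinequity_not_converged")
})

test_that("separation and collinearity are reported as typed errors", {
  set.seed(44)
  n <- 200
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, sep_var = x)
  y <- as.integer(x > 0)
  expect_error(fit_probit(y, X), class = "hinequity_separation")
  X2 <- cbind(`(Intercept)` = 1, a = x, b = 2 * x)
  y2 <- rbinom(n, 1, 0.4)
  err <- tryCatch(fit_probit(y2, X2), error = function(e) e)
  expect_s3_class(err, "hinequity_collinearity")
  expect_match(conditionMessage(err), "b")
})
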