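# Inference: bias-corrected bootstrap for the horizontal inequity index,
# normal-approximation inference for analytic (robust) standard errors, and
# significance flagging.

bc_interval <- function(t_boot, t_hat, level) {
  B <- length(t_boot)
  # midpoint convention for replicates tied with the estimate, so an estimate
  # at the bootstrap median gives z0 = 0 exactly
  frac <- (sum(t_boot < t_hat) + 0.5 * sum(t_boot == t_hat)) / B
  # clamp so qnorm stays finite when the point estimate falls outside the
  # bootstrap range
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(frac)
  a <- (1 - level) / 2
  lo_p <- pnorm(2 * z0 + qnorm(a))
  hi_p <- pnorm(2 * z0 + qnorm(1 - a))
  stats::quantile(t_boot, probs = c(lo_p, hi_p), names = FALSE, type = 7)
}

#' Bootstrap inference for the horizontal inequity index
#'
#' Resamples individuals with replacement within one group, recomputing the
#' entire estimator per replicate — fractional income ranks, the weighted
#' probit (or OLS) fit, the decomposition and the inequity index — so that
#' rank variability propagates into the interval. Reports the bootstrap
#' standard deviation and bias-corrected (BC) percentile intervals: with
#' `z0 = qnorm(fraction of replicates below the point estimate)`, the
#' endpoints sit at percentiles `pnorm(2 z0 +/- qnorm(1 - (1-level)/2))`.
#' Replicates that fail (separation, degenerate resample) are dropped and
#' counted; if more than 5% fail the result is flagged unreliable.
#'
#' @inheritParams decompose_cci
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param levels Confidence levels, all computed from the same replicate set.
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `hi_inference`: point estimate, `se_boot`,
#'   per-level BC intervals, star code from the normal approximation
#'   `estimate / se_boot`, failure count and reliability flag. `tidy()`
#'   returns one row per confidence level.
#' @examples
#' d <- generate_dataset(preset_scenario("pro_rich_denial", n = 2000, seed = 3))
#' bootstrap_hi(add_income_ranks(d), "y_denied", n_reps = 50, seed = 9)
#' @export
bootstrap_hi <- function(data, outcome, need = need_vars(),
                         nonneed = nonneed_vars(),
                         model = c("probit", "ols"), n_reps = 1000,
                         levels = 0.95, seed = 1, theta = 0.5) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), n_reps >= 2)
  if (!"eq_income" %in% names(data)) {
    data <- add_income_ranks(data, theta = theta, group = NULL)
  }
  y <- data[[outcome]]
  n <- length(y)
  w <- check_weights(data[["weight"]], n)
  inc <- data$eq_income

  terms <- c(need, nonneed)
  X <- build_design(data, terms)
  assign <- attr(X, "assign")
  src <- c("(Intercept)", terms)[assign + 1]
  class_vec <- dplyr::case_when(
    src == "(Intercept)" ~ "intercept",
    src %in% need ~ "need",
    TRUE ~ "nonneed"
  )

  rank0 <- weighted_frac_rank(inc, w)
  core0 <- hi_core(y, X, class_vec, w, rank0, model = model)
  t_hat <- core0$hi
  start <- if (model == "probit") core0$fit$coefficients else NULL

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  t_boot <- rep(NA_real_, n_reps)
  for (b in seq_len(n_reps)) {
    # aggregate the multiplicities of the resample into the weights: a row
    # drawn m times with weight w is identical to one row with weight m*w
    # for every weighted statistic in the chain (incl. midpoint tie ranks)
    m <- tabulate(sample.int(n, n, replace = TRUE), n)
    keep <- m > 0L
    t_boot[b] <- tryCatch(
      {
        wb <- w[keep] * m[keep]
        rb <- weighted_frac_rank(inc[keep], wb)
        hi_core(y[keep], X[keep, , drop = FALSE], class_vec, wb, rb,
          model = model, start = start
        )$hi
      },
      error = function(e) NA_real_
    )
  }
  ok <- t_boot[!is.na(t_boot)]
  n_failed <- n_reps - length(ok)
  if (length(ok) == 0) {
    abort("All bootstrap replicates failed; inference impossible.",
      class = "hinequity_inference_impossible"
    )
  }
  se_boot <- stats::sd(ok)
  ints <- purrr::map(levels, function(lv) bc_interval(ok, t_hat, lv))
  z <- t_hat / se_boot
  p <- 2 * pnorm(-abs(z))

  structure(
    list(
      outcome = outcome, estimate = t_hat, se_boot = se_boot,
      intervals = tibble::tibble(
        level = levels,
        ci_low = vapply(ints, `[`, numeric(1), 1),
        ci_high = vapply(ints, `[`, numeric(1), 2)
      ),
      statistic = z, p.value = p, stars = significance_stars(p),
      n = n, n_reps = n_reps, n_failed = n_failed,
      unreliable = n_failed > 0.05 * n_reps,
      method = "bias_corrected_percentile", seed = seed, model = model
    ),
    class = "hi_inference"
  )
}

#' @export
print.hi_inference <- function(x, digits = 4, ...) {
  fmt <- function(v) format(round(v, digits), nsmall = digits)
  cat("<hi_inference> HI for ", x$outcome, " (", x$model, ", n = ", x$n,
    ")\n",
    sep = ""
  )
  cat("  estimate: ", fmt(x$estimate), x$stars, "  (bootstrap SE ",
    fmt(x$se_boot), ", ", x$n_reps, " reps, ", x$n_failed, " failed)\n",
    sep = ""
  )
  for (i in seq_len(nrow(x$intervals))) {
    cat("  ", format(100 * x$intervals$level[i]), "% BC interval: [",
      fmt(x$intervals$ci_low[i]), ", ", fmt(x$intervals$ci_high[i]), "]\n",
      sep = ""
    )
  }
  if (x$unreliable) cat("  WARNING: > 5% of replicates failed; flagged unreliable\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hi_inference <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, estimate = x$estimate, std.error = x$se_boot,
    statistic = x$statistic, p.value = x$p.value, stars = x$stars,
    level = x$intervals$level, conf.low = x$intervals$ci_low,
    conf.high = x$intervals$ci_high, n = x$n, n_reps = x$n_reps,
    n_failed = x$n_failed, method = x$method, seed = x$seed
  )
}

#' Normal-approximation inference from an estimate and standard error
#'
#' Two-sided z-test and confidence interval for index estimates with
#' analytic (robust or bootstrapped) standard errors, with the conventional
#' star codes (`*` p < 0.1, `**` p < 0.05, `***` p < 0.01). Vectorized, so a
#' whole results table can be flagged in one call.
#'
#' @param estimate,se Numeric vectors of estimates and standard errors.
#' @param level Confidence level for the interval.
#' @return A tibble with `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`, `stars`.
#' @examples
#' analytic_inference(c(0.0445, -0.1085), c(0.0220, 0.0258))
#' @export
analytic_inference <- function(estimate, se, level = 0.95) {
  if (length(se) != length(estimate)) {
    abort("`estimate` and `se` must have equal length.")
  }
  if (anyNA(se) || any(se <= 0)) {
    abort("Standard errors must be positive and non-missing.",
      class = "hinequity_invalid_input"
    )
  }
  z <- estimate / se
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    estimate = estimate, std.error = se, statistic = z, p.value = p,
    conf.low = estimate - q * se, conf.high = estimate + q * se,
    stars = significance_stars(p)
  )
}
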