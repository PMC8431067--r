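# Concentration-type indices with analytic robust standard errors.
#
# All three indices are weighted-covariance forms against the fractional
# income rank r (weighted mean 1/2):
#   standard CI  = 2 cov_w(y, r) / mean_w(y)   (scale invariant, bounded by
#                  [mean-1, 1-mean] for binary y)
#   Erreygers    = 8 cov_w(y, r) = 4 mean_w(y) CI   (bounded in [-1, 1] for
#                  binary y, comparable across prevalences)
#   generalized  = 2 cov_w(v, r)   (defined for mean-zero v, e.g. residuals)
# Positive values mean the outcome concentrates among the better-off.

new_index_estimate <- function(kind, value, se, n, mean_y,
                               method = "covariance") {
  structure(
    list(
      kind = kind, value = value, se = se, n = n, mean_y = mean_y,
      method = method
    ),
    class = "index_estimate"
  )
}

#' @export
print.index_estimate <- function(x, digits = 4, ...) {
  cat("<index_estimate> ", x$kind, "\n", sep = "")
  cat("  value: ", format(round(x$value, digits), nsmall = digits), sep = "")
  if (!is.null(x$se) && !is.na(x$se)) {
    cat("  (robust SE ", format(round(x$se, digits), nsmall = digits), ")",
      sep = ""
    )
  }
  cat("\n  n = ", x$n, ", weighted mean outcome = ",
    format(round(x$mean_y, digits), nsmall = digits), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.index_estimate <- function(x, conf.level = 0.95, ...) {
  se <- x$se %||% NA_real_
  z <- if (is.na(se) || se == 0) NA_real_ else x$value / se
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    kind = x$kind, estimate = x$value, std.error = se,
    statistic = z, p.value = p,
    conf.low = if (is.na(se)) NA_real_ else x$value - q * se,
    conf.high = if (is.na(se)) NA_real_ else x$value + q * se,
    n = x$n, mean_y = x$mean_y
  )
}

validate_index_inputs <- function(y, rank, weight, call = rlang::caller_env()) {
  n <- length(y)
  if (n == 0L || length(rank) != n) {
    abort("`y` and `rank` must be non-empty vectors of equal length.",
      class = "hinequity_invalid_input", call = call
    )
  }
  if (anyNA(y) || anyNA(rank)) {
    abort("`y` and `rank` must not contain missing values.",
      class = "hinequity_invalid_input", call = call
    )
  }
  check_weights(weight, n, call = call)
}

#' Standard concentration index
#'
#' Twice the weighted covariance between an outcome and the fractional income
#' rank, divided by the weighted outcome mean: a measure of income-related
#' inequality equal to twice the area between the concentration curve and the
#' line of equality. Positive values indicate concentration among the
#' better-off.
#'
#' @param y Numeric outcome vector.
#' @param rank Fractional income ranks in \[0, 1\], see
#'   [weighted_frac_rank()].
#' @param weight Strictly positive sampling weights; `NULL` for equal.
#' @param se Compute the heteroskedasticity-robust (HC1) standard error via
#'   the convenient regression? See [index_standard_error()].
#' @return An `index_estimate` object; use [tidy()] for a tibble.
#' @examples
#' r <- weighted_frac_rank(1:4)
#' concentration_index(c(1, 1, 0, 0), r) # -0.5: concentrated among the poor
#' @export
concentration_index <- function(y, rank, weight = NULL, se = TRUE) {
  weight <- validate_index_inputs(y, rank, weight)
  my <- w_mean(y, weight)
  if (my == 0) {
    abort(
      "Concentration index undefined: weighted mean of `y` is zero (division by a zero mean).",
      class = "hinequity_undefined_index"
    )
  }
  value <- 2 * w_cov(y, rank, weight) / my
  se_val <- if (se) {
    index_standard_error(y, rank, weight, kind = "standard_CI")
  } else {
    NA_real_
  }
  new_index_estimate("standard_CI", value, se_val, length(y), my)
}

#' Erreygers-corrected concentration index
#'
#' The concentration index of a binary outcome is bounded by
#' \[mean - 1, 1 - mean\], so indices are not comparable across populations
#' with different prevalences. The Erreygers correction rescales it to
#' `CCI = 4 * mean * CI = 8 * cov_w(y, rank)`, bounded in \[-1, 1\].
#'
#' @inheritParams concentration_index
#' @param y Binary (0/1) outcome vector.
#' @return An `index_estimate` object.
#' @examples
#' r <- weighted_frac_rank(1:4)
#' erreygers_index(c(0, 0, 1, 1), r) # +1: extreme pro-rich concentration
#' @export
erreygers_index <- function(y, rank, weight = NULL, se = TRUE) {
  weight <- validate_index_inputs(y, rank, weight)
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary (0/1) for the Erreygers-corrected index.",
      class = "hinequity_invalid_input"
    )
  }
  my <- w_mean(y, weight)
  if (my == 0 || my == 1) {
    abort(paste0(
      "Erreygers index undefined: outcome is degenerate (weighted prevalence ",
      my, ")."
    ), class = "hinequity_degenerate_outcome")
  }
  value <- 8 * w_cov(y, rank, weight)
  se_val <- if (se) {
    index_standard_error(y, rank, weight, kind = "erreygers_CCI")
  } else {
    NA_real_
  }
  new_index_estimate("erreygers_CCI", value, se_val, length(y), my)
}

#' Generalized concentration index
#'
#' Twice the weighted covariance between a variable and the fractional rank,
#' without dividing by the mean. Defined for mean-zero variables, and used
#' for the residual term of the decomposition.
#'
#' @inheritParams concentration_index
#' @param v Numeric vector (may have zero mean).
#' @return An `index_estimate` object.
#' @export
generalized_ci <- function(v, rank, weight = NULL, se = FALSE) {
  weight <- validate_index_inputs(v, rank, weight)
  value <- 2 * w_cov(v, rank, weight)
  se_val <- if (se) {
    index_standard_error(v, rank, weight, kind = "generalized_GCI")
  } else {
    NA_real_
  }
  new_index_estimate("generalized_GCI", value, se_val, length(v),
    w_mean(v, weight),
    method = "covariance"
  )
}

#' Robust standard error of a concentration-type index
#'
#' Uses the convenient-regression device: the index equals the slope of a
#' weighted least-squares regression of a suitably scaled transform of the
#' outcome on the fractional rank — `2 var_w(rank) y / mean_w(y)` for the
#' standard CI, `8 var_w(rank) y` for the Erreygers index,
#' `2 var_w(rank) v` for the generalized index — and the standard error is
#' the heteroskedasticity-robust (HC1) sandwich SE of that slope, with
#' weights treated as sampling weights normalized to sum to n (so value and
#' SE are invariant to weight rescaling).
#'
#' @inheritParams concentration_index
#' @param kind One of `"standard_CI"`, `"erreygers_CCI"`,
#'   `"generalized_GCI"`.
#' @return The robust standard error (a single number).
#' @export
index_standard_error <- function(y, rank, weight = NULL,
                                 kind = c(
                                   "standard_CI", "erreygers_CCI",
                                   "generalized_GCI"
                                 )) {
  kind <- match.arg(kind)
  weight <- validate_index_inputs(y, rank, weight)
  n <- length(y)
  if (n < 3) {
    abort("At least 3 observations are required for a standard error.",
      class = "hinequity_invalid_input"
    )
  }
  w <- weight / sum(weight) * n
  vr <- w_var(rank, w)
  if (vr <= 0) {
    abort("Rank variance is zero: standard error undefined.",
      class = "hinequity_undefined_se"
    )
  }
  z <- switch(kind,
    standard_CI = {
      my <- w_mean(y, w)
      if (my == 0) {
        abort("Weighted mean of `y` is zero: standard CI undefined.",
          class = "hinequity_undefined_index"
        )
      }
      2 * vr * y / my
    },
    erreygers_CCI = 8 * vr * y,
    generalized_GCI = 2 * vr * y
  )
  convenient_regression(z, rank, w)$se
}

# Weighted least squares of z on rank with pweight-style HC1 sandwich SE:
#   slope = cov_w(z, r) / var_w(r)
#   vcov  = (X'WX)^-1 (sum w_i^2 e_i^2 x_i x_i') (X'WX)^-1 * n/(n-2)
# Returns slope and its robust SE. Weights assumed pre-normalized to sum n.
convenient_regression <- function(z, rank, w) {
  n <- length(z)
  X <- cbind(1, rank)
  XtWX <- crossprod(X, w * X)
  bread <- solve(XtWX)
  beta <- bread %*% crossprod(X, w * z)
  e <- z - X %*% beta
  we <- w * as.numeric(e)
  meat <- crossprod(X * we)
  vc <- bread %*% meat %*% bread * n / (n - 2)
  list(slope = beta[2, 1], se = sqrt(vc[2, 2]))
}
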