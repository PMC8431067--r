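# Need/non-need decomposition of the Erreygers-corrected concentration
# index and the horizontal inequity index.
#
# With a linear(ized) model y = a + sum_j b_j x_j + u, the corrected index
# obeys  CCI(y) = sum_j 4 b_j GCI(x_j) + 4 GCI(u),  where GCI is the
# generalized concentration index 2 cov_w(., rank). Each regressor's term is
# its elasticity-weighted partial index: 4 b_j GCI(x_j) = 4 b_j xbar_j
# CI(x_j). For a probit the slopes are the partial effects at weighted
# sample means; the approximation error is carried in u and reported as the
# residual term, never absorbed. The horizontal inequity index is the total
# corrected index minus the summed need contributions.

# Fast computation core shared by decompose_cci() and the bootstrap: no
# tibbles, no validation. X is the full design (intercept first), class_vec
# tags each column "intercept"/"need"/"nonneed".
hi_core <- function(y, X, class_vec, w, rank, model = "probit", start = NULL,
                    vcov = FALSE) {
  cci_total <- 8 * w_cov(y, rank, w)
  slope_idx <- which(class_vec != "intercept")
  if (model == "probit") {
    fit <- fit_probit(y, X, w, start = start, vcov = vcov)
    if (!fit$converged) {
      abort("Probit fit did not converge.", class = "hinequity_not_converged")
    }
    m <- fit$partial_effects_at_means
    # intercept of the linearization chosen so u has weighted mean zero;
    # a constant has zero GCI, so this cannot move any reported term
    alpha_m <- w_mean(y, w) - sum(m[slope_idx] * fit$xbar[slope_idx])
    yhat <- alpha_m + as.numeric(X[, slope_idx, drop = FALSE] %*% m[slope_idx])
  } else {
    wn <- w / sum(w) * length(y)
    XtWX <- crossprod(X, wn * X)
    b <- solve(XtWX, crossprod(X, wn * y))
    m <- as.numeric(b)
    names(m) <- colnames(X)
    yhat <- as.numeric(X %*% b)
    fit <- NULL
  }
  u <- y - yhat
  # cov_w(x_j, r) = sum w x_j (r - rbar) / sum w since r - rbar has weighted
  # mean zero; one gemv for all regressors
  sw <- sum(w)
  rc <- w * (rank - sum(w * rank) / sw)
  gci_x <- 2 * as.numeric(crossprod(X[, slope_idx, drop = FALSE], rc)) / sw
  contrib <- 4 * m[slope_idx] * gci_x
  need_sum <- sum(contrib[class_vec[slope_idx] == "need"])
  nonneed_sum <- sum(contrib[class_vec[slope_idx] == "nonneed"])
  residual_term <- 4 * (2 * w_cov(u, rank, w))
  list(
    cci_total = cci_total, contributions = contrib, gci_x = gci_x,
    slopes = m[slope_idx], need_sum = need_sum, nonneed_sum = nonneed_sum,
    residual_term = residual_term, hi = cci_total - need_sum, fit = fit
  )
}

#' Decompose the corrected concentration index into need and non-need parts
#'
#' Fits a model of the binary outcome on the need and non-need regressors
#' (weighted probit linearized via partial effects at weighted sample means,
#' or weighted least squares for which the decomposition identity is exact),
#' and splits the Erreygers-corrected concentration index into
#' elasticity-weighted contributions of each regressor plus a residual term
#' `4 * GCI(u)`. The horizontal inequity index is the total minus the need
#' contributions: the income-related inequality not justified by need.
#'
#' @param data Data frame for a single group, with the outcome, regressors,
#'   `weight`, and either `frac_rank` or the income columns needed to compute
#'   it.
#' @param outcome Name of the binary outcome column.
#' @param need,nonneed Character vectors of need and non-need regressor
#'   names (defaults: the package schema).
#' @param model `"probit"` (linearized, the default) or `"ols"`.
#' @param theta Buhmann elasticity used if ranks must be computed.
#' @return An object of class `hi_decomposition`. `tidy()` returns the
#'   per-regressor contributions (with a per-factor roll-up available via
#'   `tidy(x, roll_up = TRUE)`); `glance()` the one-row summary with
#'   `cci_total`, `need_sum`, `nonneed_sum`, `residual_term` and `hi`;
#'   [horizontal_inequity()] extracts the inequity index.
#' @examples
#' d <- generate_dataset(preset_scenario("pro_rich_denial", n = 4000, seed = 7))
#' dec <- decompose_cci(add_income_ranks(d), "y_denied")
#' glance(dec)
#' @export
decompose_cci <- function(data, outcome, need = need_vars(),
                          nonneed = nonneed_vars(),
                          model = c("probit", "ols"), theta = 0.5) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column `", outcome, "` not found."))
  }
  if (length(intersect(need, nonneed)) > 0) {
    abort("`need` and `nonneed` sets must be disjoint.")
  }
  if (!"frac_rank" %in% names(data)) {
    data <- add_income_ranks(data, theta = theta, group = NULL)
  }
  y <- data[[outcome]]
  w <- check_weights(data[["weight"]], length(y))
  rank <- data$frac_rank
  if (!all(y %in% c(0, 1))) {
    abort("Outcome must be binary (0/1).", class = "hinequity_invalid_input")
  }
  my <- w_mean(y, w)
  if (my == 0 || my == 1) {
    abort(paste0(
      "Outcome `", outcome, "` is degenerate (weighted prevalence ", my, ")."
    ), class = "hinequity_degenerate_outcome")
  }

  terms <- c(need, nonneed)
  X <- build_design(data, terms)
  assign <- attr(X, "assign")
  src <- c("(Intercept)", terms)[assign + 1]
  class_vec <- dplyr::case_when(
    src == "(Intercept)" ~ "intercept",
    src %in% need ~ "need",
    TRUE ~ "nonneed"
  )

  core <- hi_core(y, X, class_vec, w, rank, model = model, vcov = TRUE)

  slope_idx <- which(class_vec != "intercept")
  xbar <- colSums((w / sum(w)) * X)[slope_idx]
  contributions <- tibble::tibble(
    term = colnames(X)[slope_idx],
    regressor = src[slope_idx],
    class = class_vec[slope_idx],
    slope = unname(core$slopes),
    wmean = unname(xbar),
    partial_ci = ifelse(xbar != 0, core$gci_x / xbar, NA_real_),
    contribution = unname(core$contributions)
  )

  structure(
    list(
      outcome = outcome, model = model, n = length(y), mean_y = my,
      cci_total = core$cci_total, contributions = contributions,
      need_sum = core$need_sum, nonneed_sum = core$nonneed_sum,
      residual_term = core$residual_term, hi = core$hi, fit = core$fit
    ),
    class = "hi_decomposition"
  )
}

#' Horizontal inequity index of a decomposition
#'
#' The corrected concentration index minus the summed need contributions.
#' For an unmet-need outcome, a negative value means unmet need concentrates
#' among the poor beyond what need justifies (pro-rich inequity in access);
#' a positive value the converse.
#'
#' @param x An `hi_decomposition` object.
#' @return A single number.
#' @export
horizontal_inequity <- function(x) {
  stopifnot(inherits(x, "hi_decomposition"))
  x$hi
}

#' Horizontal inequity via indirect standardization (cross-check)
#'
#' Alternative inequity measure: the corrected index of the observed outcome
#' minus the corrected-scale index of need-predicted outcome probabilities,
#' with non-need regressors held at their weighted means. Provided as a
#' cross-check on the contribution-subtraction form, which remains the
#' default.
#'
#' @inheritParams decompose_cci
#' @return A single number.
#' @export
hi_indirect <- function(data, outcome, need = need_vars(),
                        nonneed = nonneed_vars(), theta = 0.5) {
  if (!"frac_rank" %in% names(data)) {
    data <- add_income_ranks(data, theta = theta, group = NULL)
  }
  y <- data[[outcome]]
  w <- check_weights(data[["weight"]], length(y))
  rank <- data$frac_rank
  terms <- c(need, nonneed)
  X <- build_design(data, terms)
  assign <- attr(X, "assign")
  src <- c("(Intercept)", terms)[assign + 1]
  fit <- fit_probit(y, X, w, vcov = FALSE)
  Xstd <- X
  zbar <- colSums((w / sum(w)) * X)
  for (j in which(src %in% nonneed)) Xstd[, j] <- zbar[j]
  yhat_need <- pnorm(as.numeric(Xstd %*% fit$coefficients))
  (8 * w_cov(y, rank, w)) - (8 * w_cov(yhat_need, rank, w))
}

#' @export
print.hi_decomposition <- function(x, digits = 4, ...) {
  cat("<hi_decomposition> outcome: ", x$outcome, " (", x$model, " model, n = ",
    x$n, ")\n",
    sep = ""
  )
  fmt <- function(v) format(round(v, digits), nsmall = digits)
  cat("  corrected CI:  ", fmt(x$cci_total), "\n", sep = "")
  cat("  need sum:      ", fmt(x$need_sum), "\n", sep = "")
  cat("  non-need sum:  ", fmt(x$nonneed_sum), "\n", sep = "")
  cat("  residual term: ", fmt(x$residual_term), "\n", sep = "")
  cat("  HI:            ", fmt(x$hi), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname decompose_cci
#' @param x An `hi_decomposition` object.
#' @param roll_up Sum dummy contributions within each source regressor?
#' @param ... Unused.
tidy.hi_decomposition <- function(x, roll_up = FALSE, ...) {
  if (!roll_up) {
    return(x$contributions)
  }
  x$contributions |>
    dplyr::group_by(.data$regressor, .data$class) |>
    dplyr::summarise(contribution = sum(.data$contribution), .groups = "drop")
}

#' @exportS3Method generics::glance
glance.hi_decomposition <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, model = x$model, n = x$n, mean_y = x$mean_y,
    cci_total = x$cci_total, need_sum = x$need_sum,
    nonneed_sum = x$nonneed_sum, residual_term = x$residual_term, hi = x$hi
  )
}
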