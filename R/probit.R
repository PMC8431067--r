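# Weighted probit fitting and partial effects at sample means.
#
# The decomposition of a corrected concentration index needs a linear
# approximation of the binary-outcome model; the probit is linearized with
# partial effects evaluated at the weighted sample means of the regressors.
# The fitter is a Newton-type iteration on the weighted log-likelihood using
# the expected information (Fisher scoring), with step-halving when a step
# decreases the likelihood and a small ridge on the information matrix when
# it is near-singular.

#' Build a probit design matrix from schema columns
#'
#' Expands the named regressors into an intercept-first design matrix,
#' turning factor columns into treatment-coded dummies against the schema's
#' reference categories (age 50-64, self-assessed health excellent/very good,
#' primary education, inactive).
#'
#' @param data Data frame containing the regressor columns.
#' @param terms Character vector of regressor column names.
#' @return Numeric matrix with an `(Intercept)` column and one column per
#'   numeric regressor or non-reference factor level.
#' @export
build_design <- function(data, terms) {
  stopifnot(is.data.frame(data))
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms) > 0) {
    abort(paste0(
      "Regressors not found in data: ",
      paste(missing_terms, collapse = ", ")
    ), class = "hinequity_invalid_input")
  }
  lv <- schema_levels()
  df <- data[terms]
  for (v in intersect(names(lv), terms)) {
    df[[v]] <- factor(as.character(df[[v]]), levels = lv[[v]])
  }
  for (v in terms) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  old <- options(na.action = "na.fail")
  on.exit(options(old))
  stats::model.matrix(~., data = df)
}

#' Fit a weighted probit model
#'
#' Maximizes the weighted probit log-likelihood
#' `sum w_i [y_i log pnorm(eta_i) + (1 - y_i) log pnorm(-eta_i)]` by a
#' Newton-type iteration (Fisher scoring with step-halving and a ridge
#' fallback for near-singular information). Convergence is declared when the
#' gradient max-norm falls below `grad_tol` or the relative log-likelihood
#' change below `ll_tol`. The variance matrix is the sampling-weight
#' sandwich.
#'
#' @param y Binary (0/1) outcome vector.
#' @param X Design matrix including an intercept column (see
#'   [build_design()]).
#' @param weight Strictly positive sampling weights; `NULL` for equal.
#' @param start Optional starting coefficient vector (warm starts).
#' @param grad_tol,ll_tol Convergence tolerances (defaults 1e-8 and 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @param vcov Compute the sandwich variance matrix? Skipping it speeds up
#'   bootstrap replicates, which only need the point fit.
#' @param check_rank Verify the design matrix has full column rank before
#'   fitting (default: only for cold starts; warm-started bootstrap
#'   replicates reuse the full-sample design already checked).
#' @return A `probit_fit` object: coefficients, vcov, loglik, convergence
#'   info, weighted regressor means `xbar`, partial effects at means and the
#'   linear index at means. Methods: [tidy()], [glance()], `print()`.
#' @examples
#' d <- generate_dataset(preset_scenario("share_like", n = 2000, seed = 1))
#' X <- build_design(d, c(need_vars(), nonneed_vars()))
#' fit <- fit_probit(d$y_postponed, X, d$weight)
#' glance(fit)
#' @export
fit_probit <- function(y, X, weight = NULL, start = NULL,
                       grad_tol = 1e-8, ll_tol = 1e-10, max_iter = 100,
                       vcov = TRUE, check_rank = is.null(start)) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary (0/1).", class = "hinequity_invalid_input")
  }
  if (nrow(X) != n) abort("`X` and `y` dimensions disagree.")
  if (n <= p) {
    abort("More coefficients than observations.",
      class = "hinequity_invalid_input"
    )
  }
  w <- check_weights(weight, n)
  w <- w / sum(w) * n

  qrX <- if (check_rank) qr(X) else NULL
  if (check_rank && qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(
      paste0(
        "Design matrix is rank deficient; aliased columns: ",
        paste(aliased, collapse = ", ")
      ),
      class = "hinequity_collinearity"
    )
  }

  beta <- start %||% c(qnorm(min(max(w_mean(y, w), 1e-6), 1 - 1e-6)), rep(0, p - 1))
  sgn <- 2 * y - 1
  ll_fun <- function(eta) sum(w * pnorm(sgn * eta, log.p = TRUE))
  eta <- as.numeric(X %*% beta)
  ll <- ll_fun(eta)
  converged <- FALSE
  iter <- 0L
  g <- NULL
  repeat {
    iter <- iter + 1L
    phi <- dnorm(eta)
    Phi <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
    resid <- (y - Phi) * phi / (Phi * (1 - Phi)) # generalized residual
    g <- crossprod(X, w * resid)
    if (max(abs(g)) < grad_tol) {
      converged <- TRUE
      break
    }
    info_w <- w * phi^2 / (Phi * (1 - Phi))
    H <- crossprod(X, info_w * X)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), p), g)
    })
    # step-halving if the likelihood does not improve
    ok <- FALSE
    for (h in 0:20) {
      beta_new <- beta + step / 2^h
      eta_new <- as.numeric(X %*% beta_new)
      ll_new <- ll_fun(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    if (max(abs(eta)) > 30 || max(abs(beta)) > 1e4) {
      worst <- colnames(X)[which.max(abs(beta))]
      abort(
        paste0(
          "Perfect separation suspected while fitting the probit ",
          "(diverging linear index); offending regressor: ", worst
        ),
        class = "hinequity_separation"
      )
    }
    if (rel_change < ll_tol) {
      phi <- dnorm(eta)
      Phi <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
      g <- crossprod(X, w * (y - Phi) * phi / (Phi * (1 - Phi)))
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  vc <- NULL
  if (vcov) {
    phi <- dnorm(eta)
    Phi <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
    info_w <- w * phi^2 / (Phi * (1 - Phi))
    A <- crossprod(X, info_w * X)
    resid <- (y - Phi) * phi / (Phi * (1 - Phi))
    U <- X * (w * resid)
    B <- crossprod(U)
    Ainv <- solve(A)
    vc <- Ainv %*% B %*% Ainv
    dimnames(vc) <- list(colnames(X), colnames(X))
  }

  xbar <- colSums(w * X) / sum(w)
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  idx_at_means <- sum(xbar * beta)
  pe <- dnorm(idx_at_means) * beta

  structure(
    list(
      coefficients = beta, vcov = vc, loglik = ll, converged = converged,
      n_iter = iter, gradient = as.numeric(g), n = n,
      xbar = xbar, linear_index_at_means = idx_at_means,
      partial_effects_at_means = pe
    ),
    class = "probit_fit"
  )
}

#' Partial effects of a probit at weighted sample means
#'
#' The derivative of the fitted probability with respect to each regressor,
#' evaluated at the weighted means of all regressors:
#' `dnorm(xbar'beta) * beta`. Categorical dummies enter through their
#' weighted proportions. This linearization carries the probit into the
#' decomposition of the corrected concentration index.
#'
#' @param fit A converged `probit_fit`.
#' @param xbar Optional vector of weighted regressor means (defaults to the
#'   means stored in the fit; must include the intercept entry).
#' @return Named vector of partial effects (intercept entry included; it is
#'   not a marginal effect but the scaled intercept).
#' @export
partial_effects_at_means <- function(fit, xbar = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) {
    abort("Probit fit did not converge; partial effects refused.",
      class = "hinequity_not_converged"
    )
  }
  xbar <- xbar %||% fit$xbar
  if (length(xbar) != length(fit$coefficients)) {
    abort("`xbar` must match the coefficient vector.")
  }
  idx <- sum(xbar * fit$coefficients)
  dnorm(idx) * fit$coefficients
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("<probit_fit> weighted probit, n = ", x$n, "\n", sep = "")
  cat(
    "  converged: ", x$converged, " (", x$n_iter, " iterations, logLik ",
    format(round(x$loglik, 2), nsmall = 2), ")\n",
    sep = ""
  )
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.probit_fit <- function(x, ...) {
  se <- if (is.null(x$vcov)) rep(NA_real_, length(x$coefficients)) else sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    partial_effect = unname(x$partial_effects_at_means)
  )
}

#' @exportS3Method generics::glance
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, converged = x$converged, n_iter = x$n_iter,
    n = x$n, df = length(x$coefficients),
    linear_index_at_means = x$linear_index_at_means
  )
}

# Log-likelihood and analytic gradient at an arbitrary beta (exposed for
# verification against finite differences).
probit_loglik <- function(beta, y, X, weight = NULL) {
  X <- as.matrix(X)
  w <- check_weights(weight, length(y))
  w <- w / sum(w) * length(y)
  eta <- as.numeric(X %*% beta)
  ll <- sum(w * ifelse(y == 1, pnorm(eta, log.p = TRUE), pnorm(-eta, log.p = TRUE)))
  phi <- dnorm(eta)
  Phi <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  grad <- as.numeric(crossprod(X, w * (y - Phi) * phi / (Phi * (1 - Phi))))
  list(loglik = ll, gradient = grad)
}
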