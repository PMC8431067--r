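# Weighted moment helpers. Weights are sampling weights; all moments use the
# normalized-weight (population) convention: sums divided by sum(w), never n-1.

check_weights <- function(weight, n, call = rlang::caller_env()) {
  if (is.null(weight)) weight <- rep(1, n)
  if (length(weight) != n) {
    abort("`weight` must have the same length as the data.", call = call)
  }
  if (anyNA(weight) || any(weight <= 0)) {
    abort("All weights must be strictly positive and non-missing.",
      class = "hinequity_invalid_input", call = call
    )
  }
  weight
}

w_mean <- function(x, w) sum(w * x) / sum(w)

w_cov <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sum(w * (x - mx) * (y - my)) / sw
}

w_var <- function(x, w) w_cov(x, x, w)

#' Significance stars from a two-sided p-value
#'
#' Maps p-values to the conventional star codes used in inequality tables:
#' `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.1, `""` otherwise.
#'
#' @param p Numeric vector of two-sided p-values.
#' @return Character vector of star codes.
#' @examples
#' significance_stars(c(0.2, 0.07, 0.03, 0.004))
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.1 ~ "*",
    TRUE ~ ""
  )
}

# Stable per-group seed derived from the master seed and the group label, so
# that adding or removing a group never perturbs another group's random
# stream. Kept below 2^31 - 1.
group_seed <- function(seed, group) {
  (as.double(seed) + 131 * sum(utf8ToInt(as.character(group)))) %% 2147483647
}
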