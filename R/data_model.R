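# Dataset schema, income equivalization, weighted fractional ranks, and
# input validation.

#' Default variable sets of the unmet-need analysis schema
#'
#' The analysis dataset carries one row per individual with a group (country)
#' label, household income and size, a calibrated cross-sectional sampling
#' weight, two binary unmet-need outcomes, and the regressors used to
#' standardize for need. `need_vars()` returns the need regressors (legitimate
#' drivers of healthcare use: age, gender, morbidity and functional status);
#' `nonneed_vars()` the non-need regressors (socio-economic circumstances);
#' `outcome_vars()` the binary outcomes.
#'
#' @return Character vector of column names.
#' @examples
#' need_vars()
#' nonneed_vars()
#' @export
need_vars <- function() {
  c(
    "age_group", "female", "sah", "worsened_health", "chronic",
    "cancer", "adl", "iadl"
  )
}

#' @rdname need_vars
#' @export
nonneed_vars <- function() {
  c("living_alone", "log_eq_income", "education", "job", "urban")
}

#' @rdname need_vars
#' @export
outcome_vars <- function() c("y_postponed", "y_denied")

# Factor levels; the first level is the reference category of every model.
schema_levels <- function() {
  list(
    age_group = c("50-64", "65-69", "70-74", "75-79", "80-84", "85+"),
    sah = c("excellent/very good", "good", "fair", "poor"),
    education = c("primary", "secondary", "higher"),
    job = c("inactive", "employed", "unemployed")
  )
}

#' Equivalize household income with the Buhmann scale
#'
#' Divides household net income by household size raised to the power
#' `theta`, the single-parameter (Buhmann) equivalence scale. `theta = 0`
#' ignores household composition, `theta = 1` is per-capita income; the
#' default `theta = 0.5` is the conventional square-root scale.
#'
#' @param income_hh Non-negative household net income.
#' @param hh_size Household size, integer >= 1.
#' @param theta Equivalence-scale elasticity in \[0, 1\].
#' @return Equivalent income, `income_hh / hh_size^theta`.
#' @examples
#' equivalize_income(20000, 4) # 10000
#' equivalize_income(9000, 3, theta = 1) # per-capita: 3000
#' @export
equivalize_income <- function(income_hh, hh_size, theta = 0.5) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) ||
    theta < 0 || theta > 1) {
    abort("`theta` must be a single number in [0, 1].",
      class = "hinequity_invalid_parameter"
    )
  }
  if (anyNA(hh_size) || any(hh_size < 1)) {
    abort("`hh_size` must be >= 1.", class = "hinequity_invalid_parameter")
  }
  if (anyNA(income_hh) || any(income_hh < 0)) {
    abort("`income_hh` must be non-negative.",
      class = "hinequity_invalid_parameter"
    )
  }
  income_hh / hh_size^theta
}

#' Weighted fractional income rank
#'
#' Position of each unit in the (weighted) income distribution, expressed as
#' the cumulative weight share of strictly poorer units plus half the unit's
#' own weight share. The weighted mean of the ranks is exactly 1/2. Tied
#' incomes receive the identical midpoint rank of the tied block, so the
#' result does not depend on input order.
#'
#' @param income Numeric vector of (equivalent) incomes.
#' @param weight Strictly positive sampling weights; `NULL` for equal weights.
#' @return Numeric vector of ranks in (0, 1), aligned with the input order.
#' @examples
#' weighted_frac_rank(c(1000, 2000, 3000, 4000)) # (2i - 1) / 2n
#' weighted_frac_rank(c(10, 20, 30), weight = c(1, 1, 2))
#' @export
weighted_frac_rank <- function(income, weight = NULL) {
  n <- length(income)
  if (n == 0L) {
    abort("`income` must be non-empty.", class = "hinequity_invalid_input")
  }
  if (anyNA(income)) {
    abort("`income` must not contain missing values.",
      class = "hinequity_invalid_input"
    )
  }
  w <- check_weights(weight, n)
  ord <- order(income)
  ws <- w[ord]
  # block-collapse ties so every member of a tied block gets the midpoint of
  # the block's weight span
  inc_s <- income[ord]
  cw <- cumsum(ws)
  end_idx <- c(which(inc_s[-1] != inc_s[-n]), n)
  cum_end <- cw[end_idx]
  cum_before <- c(0, cum_end[-length(cum_end)])
  rank_block <- (cum_before + cum_end) / (2 * cw[n])
  out <- numeric(n)
  out[ord] <- rep.int(rank_block, diff(c(0L, end_idx)))
  out
}

#' Add equivalent income and fractional income ranks to a dataset
#'
#' Computes `eq_income` from `income_hh` and `hh_size` with the Buhmann scale,
#' `log_eq_income`, and the weighted fractional rank `frac_rank`. Ranking is
#' performed within each level of `group` (analyses are per-country), using
#' the sampling weights.
#'
#' @param data Data frame with `income_hh`, `hh_size`, `weight`, and the
#'   grouping column.
#' @param theta Buhmann equivalence-scale elasticity, see
#'   [equivalize_income()].
#' @param group Name of the grouping column (default `"group"`); `NULL` ranks
#'   the pooled sample.
#' @return The input as a tibble with `eq_income`, `log_eq_income` and
#'   `frac_rank` columns appended (replaced if already present).
#' @examples
#' d <- generate_dataset(preset_scenario("share_like", n = 500, seed = 1))
#' add_income_ranks(d) |> dplyr::select(group, eq_income, frac_rank)
#' @export
add_income_ranks <- function(data, theta = 0.5, group = "group") {
  stopifnot(is.data.frame(data))
  for (col in c("income_hh", "hh_size", "weight")) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` is required."))
  }
  out <- tibble::as_tibble(data)
  out$eq_income <- equivalize_income(out$income_hh, out$hh_size, theta)
  out$log_eq_income <- log(pmax(out$eq_income, .Machine$double.eps))
  if (!is.null(group) && group %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::mutate(frac_rank = weighted_frac_rank(.data$eq_income, .data$weight)) |>
      dplyr::ungroup()
  } else {
    out$frac_rank <- weighted_frac_rank(out$eq_income, out$weight)
  }
  out
}

#' Validate an analysis dataset
#'
#' Checks the schema of an individual-level extract: per-column missingness,
#' out-of-range values (non-binary outcomes, non-positive weights, negative
#' counts or incomes, household size below one), and per-group sample sizes.
#' Rows failing a check are dropped (complete-case analysis); groups with
#' fewer remaining rows than `min_rows` (by default the number of model
#' columns + 1) are flagged unestimable and excluded from model-based
#' operations by the pipeline, with a warning rather than an error.
#'
#' @param data Data frame in the analysis schema.
#' @param outcomes,need,nonneed Column sets to validate; defaults are the
#'   package schema.
#' @param group Grouping column name.
#' @param min_rows Minimum rows per estimable group; `NULL` uses the number of
#'   expanded regressor columns + 1.
#' @return An object of class `hi_validation`: a list with `data` (the clean
#'   tibble), `report` (per-column missing/invalid counts), `group_sizes`,
#'   `unestimable` (character vector of group labels) and `n_dropped`.
#' @export
validate_dataset <- function(data, outcomes = outcome_vars(),
                             need = need_vars(), nonneed = nonneed_vars(),
                             group = "group", min_rows = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  core <- c(group, "income_hh", "hh_size", "weight")
  used <- intersect(c(core, outcomes, need, nonneed), names(data))
  missing_cols <- setdiff(c(core, outcomes), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Required columns absent: ",
      paste(missing_cols, collapse = ", ")
    ), class = "hinequity_invalid_input")
  }

  n0 <- nrow(data)
  invalid <- function(col) {
    x <- data[[col]]
    bad <- is.na(x)
    if (col %in% outcomes) bad <- bad | !(x %in% c(0, 1))
    if (col == "weight") bad <- bad | x <= 0
    if (col == "hh_size") bad <- bad | x < 1
    if (col == "income_hh") bad <- bad | x < 0
    if (col %in% c("chronic", "adl", "iadl")) bad <- bad | x < 0 | x != round(x)
    bad
  }
  bad_mat <- vapply(used, invalid, logical(n0))
  if (n0 == 1L) bad_mat <- matrix(bad_mat, nrow = 1, dimnames = list(NULL, used))
  report <- tibble::tibble(
    column = used,
    n_missing = unname(vapply(used, function(cl) sum(is.na(data[[cl]])), integer(1))),
    n_invalid = unname(colSums(bad_mat))
  )
  keep <- rowSums(bad_mat) == 0
  clean <- data[keep, ]
  n_dropped <- n0 - nrow(clean)
  if (n_dropped > 0) {
    rlang::inform(paste0(
      "Dropped ", n_dropped, " of ", n0,
      " rows with missing or out-of-range values."
    ))
  }

  if (is.null(min_rows)) {
    # expanded design columns: intercept + dummies for each factor
    lv <- schema_levels()
    p <- 1L
    for (v in intersect(c(need, nonneed), names(clean))) {
      p <- p + if (v %in% names(lv)) length(lv[[v]]) - 1L else 1L
    }
    min_rows <- p + 1L
  }
  sizes <- clean |>
    dplyr::count(.data[[group]], name = "n") |>
    dplyr::rename(group = 1)
  unestimable <- as.character(sizes$group[sizes$n < min_rows])
  if (length(unestimable) > 0) {
    warn(paste0(
      "Groups flagged unestimable (fewer than ", min_rows, " rows): ",
      paste(unestimable, collapse = ", ")
    ))
  }
  structure(
    list(
      data = clean, report = report, group_sizes = sizes,
      unestimable = unestimable, n_dropped = n_dropped
    ),
    class = "hi_validation"
  )
}

#' @export
print.hi_validation <- function(x, ...) {
  cat("<hi_validation>\n")
  cat("  rows kept:   ", nrow(x$data), " (", x$n_dropped, " dropped)\n", sep = "")
  cat("  groups:      ", nrow(x$group_sizes), "\n", sep = "")
  if (length(x$unestimable) > 0) {
    cat("  unestimable: ", paste(x$unestimable, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a survey extract from a delimited file
#'
#' Reads a CSV extract in the analysis schema, optionally renaming columns
#' via `col_map` (a named character vector `c(schema_name = file_name)`), and
#' coerces the categorical fields to the schema's factor levels.
#'
#' @param path Path to a CSV file with a header.
#' @param col_map Optional named character vector mapping schema names to the
#'   file's column names.
#' @return A tibble in the analysis schema.
#' @export
read_survey_extract <- function(path, col_map = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      file_name <- col_map[[schema_name]]
      if (!file_name %in% names(data)) {
        abort(paste0("Mapped column `", file_name, "` not found in file."))
      }
      names(data)[names(data) == file_name] <- schema_name
    }
  }
  lv <- schema_levels()
  for (v in intersect(names(lv), names(data))) {
    data[[v]] <- factor(as.character(data[[v]]), levels = lv[[v]])
  }
  tibble::as_tibble(data)
}
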