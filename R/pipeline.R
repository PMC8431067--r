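# Batch runner: per-group, per-outcome corrected concentration indices with
# robust SEs, horizontal inequity with bias-corrected bootstrap inference,
# decomposition tables, and a run log. Mirrors the shape of a per-country
# inequity results table.

#' Run the full inequality/inequity analysis per group and outcome
#'
#' For every group (country) and binary unmet-need outcome: validates and
#' complete-case filters the data, computes equivalent income and weighted
#' fractional ranks within the group, the Erreygers-corrected concentration
#' index with its robust standard error and star code, the probit (or OLS)
#' need/non-need decomposition, and the horizontal inequity index with
#' bias-corrected bootstrap intervals at each requested level. Groups that
#' error (degenerate outcome, separation, too few rows) yield NA rows with
#' the reason logged — a failing group never aborts the batch. Fully
#' deterministic given `seed`; each group x outcome gets an independent seed
#' derived from the master seed and the labels.
#'
#' @param data Data frame in the analysis schema (see [need_vars()]).
#' @param outcomes Binary outcome columns to analyse.
#' @param need,nonneed Need and non-need regressor names (disjoint).
#' @param model `"probit"` (default) or `"ols"`.
#' @param n_boot Bootstrap replicates for the inequity index (default 1000).
#' @param levels Confidence levels computed from the one replicate set.
#' @param theta Buhmann equivalence-scale elasticity.
#' @param seed Master integer seed.
#' @param group Grouping column name.
#' @return An object of class `hi_analysis`: list with `results` (one row
#'   per group x outcome), `contributions` (long decomposition table), and
#'   `log` (per-run seeds, timings, failure counts, status). `tidy()`
#'   returns the results table; [summarize_results()] the significance
#'   summary; `autoplot()` a forest plot.
#' @examples
#' d <- generate_dataset(preset_scenario("share_like",
#'   n = 800,
#'   groups = c("A", "B"), seed = 1
#' ))
#' fit <- run_analysis(d, n_boot = 30, seed = 1)
#' tidy(fit)
#' @export
run_analysis <- function(data, outcomes = outcome_vars(), need = need_vars(),
                         nonneed = nonneed_vars(),
                         model = c("probit", "ols"), n_boot = 1000,
                         levels = c(0.90, 0.95), theta = 0.5, seed = 1,
                         group = "group") {
  model <- match.arg(model)
  if (length(intersect(need, nonneed)) > 0) {
    abort("`need` and `nonneed` sets must be disjoint.")
  }
  if (any(outcomes %in% c(need, nonneed))) {
    abort("Outcome columns cannot also be regressors.")
  }
  val <- validate_dataset(data,
    outcomes = outcomes, need = need,
    nonneed = nonneed, group = group
  )
  d <- add_income_ranks(val$data, theta = theta, group = group)
  groups <- sort(unique(as.character(d[[group]])))

  grid <- tidyr::expand_grid(group = groups, outcome = outcomes)
  rows <- vector("list", nrow(grid))
  contribs <- vector("list", nrow(grid))
  logs <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    g <- grid$group[i]
    o <- grid$outcome[i]
    dg <- d[d[[group]] == g, ]
    run_seed <- group_seed(seed, paste0(g, "::", o))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      {
        if (g %in% val$unestimable) {
          abort("group unestimable (too few rows)",
            class = "hinequity_unestimable"
          )
        }
        cci_est <- erreygers_index(dg[[o]], dg$frac_rank, dg$weight)
        cci_inf <- analytic_inference(cci_est$value, cci_est$se)
        dec <- decompose_cci(dg, o, need = need, nonneed = nonneed, model = model)
        boot <- bootstrap_hi(dg, o,
          need = need, nonneed = nonneed,
          model = model, n_reps = n_boot, levels = levels, seed = run_seed
        )
        row <- tibble::tibble(
          group = g, outcome = o, n = nrow(dg),
          prevalence = cci_est$mean_y,
          cci = cci_est$value, cci_se = cci_est$se,
          cci_p = cci_inf$p.value, cci_stars = cci_inf$stars,
          hi = boot$estimate, hi_se = boot$se_boot,
          hi_p = boot$p.value, hi_stars = boot$stars,
          need_sum = dec$need_sum, residual_term = dec$residual_term
        )
        for (k in seq_along(levels)) {
          lv <- levels[k]
          row[[paste0("hi_ci", round(100 * lv), "_low")]] <- boot$intervals$ci_low[k]
          row[[paste0("hi_ci", round(100 * lv), "_high")]] <- boot$intervals$ci_high[k]
        }
        list(
          row = row,
          contrib = dplyr::mutate(tidy(dec), group = g, outcome = o, .before = 1),
          log = tibble::tibble(
            group = g, outcome = o, status = "ok", reason = "",
            seed = run_seed, n_boot_failed = boot$n_failed,
            elapsed_s = proc.time()[["elapsed"]] - t0
          )
        )
      },
      error = function(e) {
        reason <- if (inherits(e, "hinequity_degenerate_outcome")) {
          "degenerate-outcome"
        } else if (inherits(e, "hinequity_separation")) {
          "separation"
        } else if (inherits(e, "hinequity_unestimable")) {
          "unestimable"
        } else {
          conditionMessage(e)
        }
        row <- tibble::tibble(
          group = g, outcome = o, n = nrow(dg),
          prevalence = if (nrow(dg) > 0) w_mean(dg[[o]], dg$weight) else NA_real_,
          cci = NA_real_, cci_se = NA_real_, cci_p = NA_real_,
          cci_stars = NA_character_, hi = NA_real_, hi_se = NA_real_,
          hi_p = NA_real_, hi_stars = NA_character_,
          need_sum = NA_real_, residual_term = NA_real_
        )
        for (lv in levels) {
          row[[paste0("hi_ci", round(100 * lv), "_low")]] <- NA_real_
          row[[paste0("hi_ci", round(100 * lv), "_high")]] <- NA_real_
        }
        list(
          row = row, contrib = NULL,
          log = tibble::tibble(
            group = g, outcome = o, status = "error", reason = reason,
            seed = run_seed, n_boot_failed = NA_integer_,
            elapsed_s = proc.time()[["elapsed"]] - t0
          )
        )
      }
    )
    rows[[i]] <- res$row
    contribs[[i]] <- res$contrib
    logs[[i]] <- res$log
  }

  structure(
    list(
      results = dplyr::bind_rows(rows),
      contributions = dplyr::bind_rows(contribs),
      log = dplyr::bind_rows(logs),
      spec = list(
        outcomes = outcomes, need = need, nonneed = nonneed, model = model,
        n_boot = n_boot, levels = levels, theta = theta, seed = seed,
        group = group,
        package_version = as.character(utils::packageVersion("hinequity"))
      )
    ),
    class = "hi_analysis"
  )
}

#' @export
print.hi_analysis <- function(x, ...) {
  cat("<hi_analysis> ", nrow(x$results), " group x outcome cells (",
    sum(x$log$status == "ok"), " ok, ", sum(x$log$status != "ok"),
    " failed)\n",
    sep = ""
  )
  print(x$results)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hi_analysis <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.hi_analysis <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$results), n_ok = sum(x$log$status == "ok"),
    n_failed = sum(x$log$status != "ok"), model = x$spec$model,
    n_boot = x$spec$n_boot, seed = x$spec$seed
  )
}

#' Summarize significant inequality and inequity findings
#'
#' Lists, per outcome and confidence level, the groups with a significant
#' corrected concentration index and a significant horizontal inequity
#' index, with a direction label: positive indices mean the unmet-need
#' outcome is concentrated among the better-off, negative among the
#' worse-off.
#'
#' @param results An `hi_analysis` object or its `results` tibble (e.g. read
#'   back from CSV).
#' @param levels Confidence levels at which to flag significance (two-sided
#'   p < 1 - level).
#' @return A tibble: `outcome`, `level`, `index` (`"CCI"`/`"HI"`), `group`,
#'   `estimate`, `p.value`, `direction`.
#' @export
summarize_results <- function(results, levels = c(0.90, 0.95)) {
  if (inherits(results, "hi_analysis")) results <- results$results
  stopifnot(is.data.frame(results))
  long <- dplyr::bind_rows(
    dplyr::transmute(results,
      outcome = .data$outcome, group = .data$group, index = "CCI",
      estimate = .data$cci, p.value = .data$cci_p
    ),
    dplyr::transmute(results,
      outcome = .data$outcome, group = .data$group, index = "HI",
      estimate = .data$hi, p.value = .data$hi_p
    )
  )
  purrr::map_dfr(levels, function(lv) {
    long |>
      dplyr::filter(!is.na(.data$p.value), .data$p.value < 1 - lv) |>
      dplyr::mutate(
        level = lv,
        direction = ifelse(.data$estimate > 0,
          "concentrated among better-off",
          "concentrated among worse-off"
        )
      )
  }) |>
    dplyr::select(
      "outcome", "level", "index", "group", "estimate",
      "p.value", "direction"
    ) |>
    dplyr::arrange(.data$outcome, .data$level, .data$index, .data$group)
}

#' Write analysis results to CSV files
#'
#' Writes `results.csv`, `contributions.csv` and `log.csv` (full precision)
#' into `dir`. The results CSV round-trips: re-reading it and re-running
#' [summarize_results()] reproduces the identical summary.
#'
#' @param x An `hi_analysis` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "hi_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(x$results, file.path(dir, "results.csv"))
  readr::write_csv(x$contributions, file.path(dir, "contributions.csv"))
  readr::write_csv(x$log, file.path(dir, "log.csv"))
  invisible(dir)
}
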