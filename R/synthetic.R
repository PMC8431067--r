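# Synthetic survey generator: an ageing-survey-like extract with a fully
# specified probit data-generating process, so the inequality/inequity
# pipeline is testable end to end with known truth.
#
# Covariate dependence is generated through explicit linear-index links
# (age -> self-assessed health -> chronic burden; income -> education and
# self-assessed health), because inequity testing needs controlled
# correlation between need variables and the income rank. Outcomes follow
# y* = alpha + x'beta + z'gamma + delta * log(eq_income) + eps, y = 1{y* > 0},
# with eps standard normal (probit-consistent) by default and a logistic
# misspecification toggle.

default_covariate_model <- function() {
  list(
    age_probs = c(0.4728, 0.1363, 0.1323, 0.0964, 0.0890, 0.0732),
    age_breaks = c(50, 65, 70, 75, 80, 85, 95),
    female_p = 0.55,
    # self-assessed health: latent = sah_age*(age-68) + sah_income*zinc + N(0,1)
    sah_age = 0.04, sah_income = -0.35,
    sah_cuts = c(-0.763, 0.659, 1.757),
    worsened_base = -2.45, worsened_sah = 0.55,
    chronic_log_base = 0.30, chronic_age = 0.030, chronic_sah = 0.12,
    cancer_p = 0.037,
    adl_log_base = -1.90, adl_age = 0.045,
    iadl_log_base = -1.35, iadl_age = 0.050,
    edu_income = 0.9, edu_cuts = c(-0.75, 1.55), # logistic latent, income-graded
    job_young = c(inactive = 0.20, employed = 0.62, unemployed = 0.18),
    job_old = c(inactive = 0.95, employed = 0.04, unemployed = 0.01),
    urban_p = 0.62
  )
}

#' Configure a synthetic survey scenario
#'
#' Full parameterization of the synthetic data-generating process: sample
#' size per group, lognormal household-income model, household-size
#' distribution, sampling-weight model, covariate-link coefficients, and the
#' probit outcome models (intercept `alpha`, need slopes `beta`, non-need
#' slopes `gamma` and a direct log-equivalent-income slope `delta` per
#' outcome). `delta = 0` together with `gamma = 0` means zero true inequity
#' beyond need.
#'
#' @param n Individuals per group.
#' @param groups Character vector of group (country) labels.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param income_meanlog,income_sdlog Lognormal household-income parameters,
#'   recycled across groups.
#' @param hh_probs Probabilities of household sizes 1..5.
#' @param weight_model `"variable"` (lognormal, sdlog 0.25) or `"uniform"`
#'   (all 1).
#' @param covariates Covariate-link coefficient list; see
#'   `default_covariate_model()` in the sources. Supplied entries override
#'   defaults.
#' @param outcomes Named list (`y_postponed`, `y_denied`), each a list with
#'   `alpha`, `beta` (named need slopes on design columns), `gamma` (named
#'   non-need slopes), `delta`.
#' @param error `"normal"` (probit-consistent) or `"logistic"`
#'   (misspecification toggle; scaled to unit variance).
#' @param theta Buhmann elasticity used for the generated equivalent income.
#' @return A `scenario_config` object for [generate_dataset()].
#' @export
scenario_config <- function(n = 10000, groups = "SYN", seed = 1,
                            income_meanlog = log(20000), income_sdlog = 0.8,
                            hh_probs = c(0.27, 0.48, 0.13, 0.08, 0.04),
                            weight_model = c("variable", "uniform"),
                            covariates = list(),
                            outcomes = NULL,
                            error = c("normal", "logistic"),
                            theta = 0.5) {
  weight_model <- match.arg(weight_model)
  error <- match.arg(error)
  if (n < 1) abort("`n` must be >= 1.", class = "hinequity_config_error")
  if (length(hh_probs) != 5 || any(hh_probs < 0) ||
    abs(sum(hh_probs) - 1) > 1e-8) {
    abort("`hh_probs` must be 5 non-negative probabilities summing to 1.",
      class = "hinequity_config_error"
    )
  }
  if (any(income_sdlog <= 0)) {
    abort("`income_sdlog` must be positive.",
      class = "hinequity_config_error"
    )
  }
  cov <- utils::modifyList(default_covariate_model(), covariates)
  for (p in c("female_p", "cancer_p", "urban_p")) {
    if (cov[[p]] < 0 || cov[[p]] > 1) {
      abort(paste0("`", p, "` must be a probability in [0, 1]."),
        class = "hinequity_config_error"
      )
    }
  }
  if (abs(sum(cov$age_probs) - 1) > 1e-8 || any(cov$age_probs < 0)) {
    abort("`age_probs` must be probabilities summing to 1.",
      class = "hinequity_config_error"
    )
  }
  outcomes <- outcomes %||% preset_outcome_models("share_like")
  structure(
    list(
      n = as.integer(n), groups = groups, seed = as.integer(seed),
      income_meanlog = rep_len(income_meanlog, length(groups)),
      income_sdlog = rep_len(income_sdlog, length(groups)),
      hh_probs = hh_probs, weight_model = weight_model,
      covariates = cov, outcomes = outcomes, error = error, theta = theta
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", length(x$groups), " group(s) x ", x$n,
    " individuals, seed ", x$seed, "\n",
    sep = ""
  )
  for (o in names(x$outcomes)) {
    m <- x$outcomes[[o]]
    cat("  ", o, ": alpha = ", round(m$alpha, 3), ", delta = ", m$delta,
      ", |beta| = ", length(m$beta), ", |gamma| = ", length(m$gamma), "\n",
      sep = ""
    )
  }
  invisible(x)
}

# Shared need-slope vector (probit scale), named by design columns.
preset_need_slopes <- function() {
  c(
    `age_group65-69` = 0.05, `age_group70-74` = 0.10, `age_group75-79` = 0.15,
    `age_group80-84` = 0.20, `age_group85+` = 0.25,
    female = 0.10,
    sahgood = 0.15, sahfair = 0.30, sahpoor = 0.45,
    worsened_health = 0.30, chronic = 0.08, cancer = 0.35,
    adl = 0.05, iadl = 0.05
  )
}

zero_gamma <- function() {
  c(
    living_alone = 0, educationsecondary = 0, educationhigher = 0,
    jobemployed = 0, jobunemployed = 0, urban = 0
  )
}

# Outcome models per preset. Intercepts are calibrated (development-time,
# large-n simulation against the pooled target prevalences 0.2533 postponed /
# 0.0540 denied) and frozen; see the methods vignette.
preset_outcome_models <- function(name) {
  beta <- preset_need_slopes()
  share_gamma <- c(
    living_alone = 0.05, educationsecondary = 0, educationhigher = -0.05,
    jobemployed = 0, jobunemployed = 0.05, urban = 0.03
  )
  switch(name,
    share_like = list(
      y_postponed = list(alpha = -1.1983, beta = beta, gamma = share_gamma, delta = 0),
      y_denied = list(alpha = -2.1869, beta = beta, gamma = share_gamma, delta = 0)
    ),
    null_need_only = list(
      y_postponed = list(alpha = -1.1720, beta = beta, gamma = zero_gamma(), delta = 0),
      y_denied = list(alpha = -2.1603, beta = beta, gamma = zero_gamma(), delta = 0)
    ),
    pro_rich_denial = list(
      y_postponed = list(alpha = -1.1720, beta = beta, gamma = zero_gamma(), delta = 0),
      y_denied = list(alpha = 0.1877, beta = beta, gamma = zero_gamma(), delta = -0.25)
    ),
    pro_poor_postponement = list(
      y_postponed = list(alpha = -3.0921, beta = beta, gamma = zero_gamma(), delta = 0.2),
      y_denied = list(alpha = -2.1603, beta = beta, gamma = zero_gamma(), delta = 0)
    ),
    abort(paste0("Unknown preset: ", name), class = "hinequity_config_error")
  )
}

#' Preset synthetic scenarios
#'
#' Named, ready-to-run scenario configurations:
#' * `"share_like"` — pooled prevalences near the real survey's (postponed
#'   ~0.25, denied ~0.054), mild non-need effects.
#' * `"null_need_only"` — need effects only (`gamma = 0`, `delta = 0`):
#'   true horizontal inequity is zero.
#' * `"pro_rich_denial"` — a direct negative log-income slope on denial
#'   (the poor are denied more at equal need): true HI < 0.
#' * `"pro_poor_postponement"` — postponement loads positively on income:
#'   true HI > 0.
#'
#' @param name Preset name, see above.
#' @param n,groups,seed Passed to [scenario_config()].
#' @param ... Further overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @examples
#' preset_scenario("pro_rich_denial", n = 5000, seed = 42)
#' @export
preset_scenario <- function(name = c(
                              "share_like", "null_need_only",
                              "pro_rich_denial", "pro_poor_postponement"
                            ),
                            n = 10000, groups = "SYN", seed = 1, ...) {
  name <- match.arg(name)
  scenario_config(
    n = n, groups = groups, seed = seed,
    outcomes = preset_outcome_models(name), ...
  )
}

#' @rdname preset_scenario
#' @export
preset_scenarios <- function(n = 10000, seed = 1) {
  nm <- c(
    "share_like", "null_need_only", "pro_rich_denial",
    "pro_poor_postponement"
  )
  setNames(lapply(nm, preset_scenario, n = n, seed = seed), nm)
}

generate_group <- function(cfg, g_idx) {
  cv <- cfg$covariates
  n <- cfg$n
  lv <- schema_levels()

  band <- sample.int(6, n, replace = TRUE, prob = cv$age_probs)
  age <- runif(n, cv$age_breaks[band], cv$age_breaks[band + 1])
  age_group <- factor(lv$age_group[band], levels = lv$age_group)
  female <- rbinom(n, 1, cv$female_p)

  income_hh <- rlnorm(n, cfg$income_meanlog[g_idx], cfg$income_sdlog[g_idx])
  zinc <- (log(income_hh) - cfg$income_meanlog[g_idx]) / cfg$income_sdlog[g_idx]
  hh_size <- sample.int(5, n, replace = TRUE, prob = cfg$hh_probs)
  living_alone <- as.integer(hh_size == 1)

  sah_lat <- cv$sah_age * (age - 68) + cv$sah_income * zinc + rnorm(n)
  sah_num <- findInterval(sah_lat, cv$sah_cuts) + 1L
  sah <- factor(lv$sah[sah_num], levels = lv$sah)

  worsened <- rbinom(n, 1, stats::plogis(cv$worsened_base + cv$worsened_sah * (sah_num >= 3)))
  chronic <- rpois(n, exp(cv$chronic_log_base + cv$chronic_age * (age - 68) +
    cv$chronic_sah * (sah_num - 1)))
  cancer <- rbinom(n, 1, cv$cancer_p)
  adl <- rpois(n, exp(cv$adl_log_base + cv$adl_age * (age - 68)))
  iadl <- rpois(n, exp(cv$iadl_log_base + cv$iadl_age * (age - 68)))

  edu_lat <- cv$edu_income * zinc + stats::rlogis(n)
  edu_num <- findInterval(edu_lat, cv$edu_cuts) + 1L
  education <- factor(lv$education[edu_num], levels = lv$education)

  young <- age < 65
  job_num <- integer(n)
  if (any(young)) {
    job_num[young] <- sample.int(3, sum(young), replace = TRUE, prob = cv$job_young)
  }
  if (any(!young)) {
    job_num[!young] <- sample.int(3, sum(!young), replace = TRUE, prob = cv$job_old)
  }
  job <- factor(lv$job[job_num], levels = lv$job)
  urban <- rbinom(n, 1, cv$urban_p)

  weight <- switch(cfg$weight_model,
    uniform = rep(1, n),
    variable = rlnorm(n, 0, 0.25)
  )

  d <- tibble::tibble(
    unit_id = paste0(cfg$groups[g_idx], "-", seq_len(n)),
    group = cfg$groups[g_idx],
    income_hh = income_hh, hh_size = hh_size, weight = weight,
    age = age, age_group = age_group, female = female, sah = sah,
    worsened_health = worsened, chronic = chronic, cancer = cancer,
    adl = adl, iadl = iadl,
    living_alone = living_alone, education = education, job = job,
    urban = urban
  )
  d$eq_income <- equivalize_income(d$income_hh, d$hh_size, cfg$theta)
  d$log_eq_income <- log(d$eq_income)

  X <- build_design(d, c(need_vars(), nonneed_vars()))
  for (o in names(cfg$outcomes)) {
    m <- cfg$outcomes[[o]]
    coefs <- setNames(numeric(ncol(X)), colnames(X))
    slopes <- c(m$beta, m$gamma)
    unknown <- setdiff(names(slopes), names(coefs))
    if (length(unknown) > 0) {
      abort(paste0(
        "Outcome coefficients name unknown design columns: ",
        paste(unknown, collapse = ", ")
      ), class = "hinequity_config_error")
    }
    if (length(slopes) > 0) coefs[names(slopes)] <- slopes
    coefs["(Intercept)"] <- m$alpha
    coefs["log_eq_income"] <- coefs["log_eq_income"] + m$delta
    eta <- as.numeric(X %*% coefs)
    eps <- switch(cfg$error,
      normal = rnorm(n),
      logistic = stats::rlogis(n) * sqrt(3) / pi
    )
    d[[o]] <- as.integer(eta + eps > 0)
    d[[paste0(".eta_", o)]] <- eta
  }
  d
}

#' Generate a synthetic survey extract
#'
#' Draws the full analysis schema from a [scenario_config()]: covariates,
#' household income, sampling weights and binary outcomes from the probit
#' data-generating process, plus the derived equivalent income, its log and
#' the weighted fractional income rank (within group). Deterministic given
#' the config seed; each group has its own seed stream derived from the
#' master seed and the group label, so groups are independent of each other's
#' presence. The hidden columns `.eta_*` carry the true linear index of each
#' outcome (useful for verifying the generator).
#'
#' @param config A `scenario_config`.
#' @return A tibble, one row per individual, in the analysis schema.
#' @examples
#' d <- generate_dataset(preset_scenario("share_like", n = 1000, seed = 1))
#' dplyr::count(d, y_postponed)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- purrr::map(seq_along(config$groups), function(gi) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(group_seed(config$seed, config$groups[gi])))
    res <- generate_group(config, gi)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    res
  })
  d <- dplyr::bind_rows(out)
  add_income_ranks(d, theta = config$theta, group = "group")
}
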