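#' Published reference indices for European unmet care during COVID-19
#'
#' Published per-country estimates of income-related inequality and
#' horizontal inequity in postponed and denied care among Europeans aged 50+
#' during the first COVID-19 wave: the Erreygers-corrected concentration
#' index (robust SE) and the horizontal inequity index (bootstrapped SE) for
#' 25 countries and two unmet-need outcomes, with the significance stars as
#' printed (`*` p < 0.1, `**` p < 0.05, `***` p < 0.01). The underlying
#' survey microdata are restricted-access; this table carries only the
#' published summary estimates, used as a worked example for the inference
#' utilities (e.g. feeding the estimate/SE pairs through
#' [analytic_inference()] to recover the significance pattern).
#'
#' @return A tibble with columns `country`, `outcome`
#'   (`"postponed"`/`"denied"`), `index` (`"cci"`/`"hi"`), `estimate`, `se`,
#'   `stars`.
#' @examples
#' ref <- published_reference_indices()
#' cci <- dplyr::filter(ref, index == "cci", outcome == "denied")
#' dplyr::bind_cols(cci, analytic_inference(cci$estimate, cci$se)["stars"])
#' @export
published_reference_indices <- function() {
  path <- system.file("extdata", "reference_indices.csv",
    package = "hinequity", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      country = readr::col_character(),
      outcome = readr::col_character(),
      index = readr::col_character(),
      estimate = readr::col_double(),
      se = readr::col_double(),
      stars = readr::col_character()
    )
  ) |>
    dplyr::mutate(stars = dplyr::coalesce(.data$stars, ""))
}
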