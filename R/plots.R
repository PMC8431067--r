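# Forest-style plots of per-group indices and decomposition bar charts.

#' Forest plot of per-group indices
#'
#' Plots the corrected concentration index (with normal-approximation
#' interval from its robust SE) or the horizontal inequity index (with its
#' bias-corrected bootstrap interval) per group, significant groups
#' highlighted.
#'
#' @param object An `hi_analysis` object.
#' @param index `"hi"` (default) or `"cci"`.
#' @param level Confidence level to display (must be one of the analysis
#'   levels when `index = "hi"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hi_analysis <- function(object, index = c("hi", "cci"),
                                 level = 0.95, ...) {
  index <- match.arg(index)
  res <- object$results
  if (index == "hi") {
    lo_col <- paste0("hi_ci", round(100 * level), "_low")
    hi_col <- paste0("hi_ci", round(100 * level), "_high")
    if (!lo_col %in% names(res)) {
      abort(paste0("Level ", level, " was not computed in this analysis."))
    }
    df <- dplyr::transmute(res,
      group = .data$group, outcome = .data$outcome, estimate = .data$hi,
      lo = .data[[lo_col]], hi = .data[[hi_col]], p = .data$hi_p
    )
    ylab <- "Horizontal inequity index (BC bootstrap interval)"
  } else {
    q <- qnorm(1 - (1 - level) / 2)
    df <- dplyr::transmute(res,
      group = .data$group, outcome = .data$outcome, estimate = .data$cci,
      lo = .data$cci - q * .data$cci_se, hi = .data$cci + q * .data$cci_se,
      p = .data$cci_p
    )
    ylab <- "Erreygers-corrected concentration index"
  }
  df$significant <- !is.na(df$p) & df$p < 1 - level
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$estimate, y = .data$group,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = ylab, y = NULL,
      caption = paste0(
        100 * level,
        "% intervals; significant groups in red"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of decomposition contributions
#'
#' @param object An `hi_decomposition` object.
#' @param roll_up Sum dummy contributions within each source regressor?
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hi_decomposition <- function(object, roll_up = TRUE, ...) {
  df <- tidy(object, roll_up = roll_up)
  label_col <- if (roll_up) "regressor" else "term"
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$contribution,
      y = stats::reorder(.data[[label_col]], .data$contribution),
      fill = .data$class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "Contribution to the corrected concentration index",
      y = NULL, fill = NULL,
      subtitle = paste0(
        object$outcome, ": CCI = ", round(object$cci_total, 4),
        ", HI = ", round(object$hi, 4)
      )
    ) +
    ggplot2::theme_minimal()
}
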