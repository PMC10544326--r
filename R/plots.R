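## ggplot2 displays for the result types.

#' Forest plot of an association scan
#'
#' Odds ratios with Wald confidence intervals on a log scale, one row per
#' unit, faceted by outcome when several were scanned.
#'
#' @param object A `pb_scan` tibble from [association_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_scan
#' @export
autoplot.pb_scan <- function(object, ...) {
  dat <- dplyr::filter(object, is.finite(.data$or))
  dat$unit <- stats::reorder(dat$unit, dat$or)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$unit)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL)
  if (length(unique(dat$outcome)) > 1) {
    p <- p + ggplot2::facet_wrap(~outcome)
  }
  p
}

#' Plot a cumulative risk curve
#'
#' Carrier and population cumulative risk by age, with the plug-in
#' confidence band for carriers when available.
#'
#' @param object A `pb_risk_curve` from [cumulative_risk_curve()].
#' @param threshold Optional horizontal reference line (e.g. 0.30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_risk_curve
#' @export
autoplot.pb_risk_curve <- function(object, threshold = NULL, ...) {
  dat <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$age))
  if (any(is.finite(dat$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "steelblue", alpha = 0.2
    )
  }
  p <- p +
    ggplot2::geom_line(ggplot2::aes(y = .data$risk_carrier),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$risk_population),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = "Age (years)", y = "Cumulative risk")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotted")
  }
  p
}

#' Bar chart of carrier prevalence by unit
#'
#' @param prevalence Output of [tabulate_prevalence()].
#' @param units Optional subset of units to display.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence, units = NULL) {
  dat <- prevalence
  if (!is.null(units)) dat <- dat[dat$unit %in% units, ]
  long <- tidyr::pivot_longer(
    dat[, c("unit", "case_prevalence", "control_prevalence")],
    -"unit", names_to = "group", values_to = "prevalence"
  )
  long$group <- sub("_prevalence", "", long$group)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$unit, y = .data$prevalence,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Carrier prevalence (%)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
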