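#' Plot smoothed case-series curves
#'
#' Displays the smoothed adverse-outcome probability over the case series
#' for the reference arm, the novel arm without learning, and (if present)
#' the novel arm with learning, with shaded pointwise 95% bands.
#'
#' @param object A `learnsim_curves` from [case_series_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot learnsim_curves
#' @export
autoplot.learnsim_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$CN, y = .data$estimate,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("%s case number (treatment-specific)",
                  tools::toTitleCase(attr(object, "level") %||% "provider")),
      y = "Smoothed probability of adverse outcome",
      colour = NULL, fill = NULL,
      caption = attr(object, "smoother")
    ) +
    ggplot2::theme_minimal()
}

#' Plot odds-ratio recovery by sample size
#'
#' One point per generated dataset: the estimated novel-treatment odds
#' ratio (with CI segment) against realized sample size, faceted by the
#' specified value, with the specification as a horizontal line --
#' convergence of estimates toward the specification with growing n is the
#' expected pattern.
#'
#' @param object A `learnsim_coverage` from [coverage_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot learnsim_coverage
#' @export
autoplot.learnsim_coverage <- function(object, ...) {
  df <- dplyr::filter(object, !.data$separation)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$or_estimate)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25, colour = "grey55"
    ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$specified_or),
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~specified_or, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Realized sample size",
                  y = "Estimated novel-treatment odds ratio (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot the realized annual-volume mix of a roster
#'
#' Histogram of realized provider-year case volumes; with a bimodal volume
#' mix (e.g. high-volume 20-30 vs low-volume 5-15 cases/year) the two
#' classes appear as separated modes in configured proportions.
#'
#' @param roster A roster tibble from [build_roster()], or several stacked.
#' @return A ggplot object.
#' @export
plot_volume_mix <- function(roster) {
  vols <- tidyr::pivot_longer(
    dplyr::select(roster, dplyr::starts_with("volume_y")),
    dplyr::everything(), values_to = "volume"
  )
  vols <- dplyr::filter(vols, .data$volume > 0)
  ggplot2::ggplot(vols, ggplot2::aes(x = .data$volume)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Annual cases per provider-year", y = "Provider-years") +
    ggplot2::theme_minimal()
}

#' Plot a learning curve preview
#'
#' @inheritParams curve_preview
#' @return A ggplot object showing the solved curve, its initial magnitude
#'   and the truncation to 0 at mastery.
#' @export
plot_learning_curve <- function(form, magnitude, speed, shape = 1.5,
                                max_cases = NULL) {
  df <- curve_preview(form, magnitude, speed, shape, max_cases)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$CN, y = .data$p)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = speed, linetype = "dashed") +
    ggplot2::labs(x = "Case number", y = "Learning-associated probability",
                  title = sprintf("%s learning curve (magnitude %.3g, mastery at %d cases)",
                                  form, magnitude, speed)) +
    ggplot2::theme_minimal()
}
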