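#' Plot time-varying discrimination
#'
#' AUROC (with CI ribbon) by hours before onset, one line per scorer.
#'
#' @param object An `hd_tv_auroc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_tv_auroc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lead_hours, y = .data$auroc,
                                       colour = .data$scorer, fill = .data$scorer)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Hours before intervention onset", y = "AUROC",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Recall, precision and specificity against the alarm threshold.
#'
#' @param object An `hd_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("recall", "precision", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Alarm threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the alarm lead-time analysis
#'
#' Two panels worth of data are available; this plots the cumulative
#' first-alarm curve: the fraction of unstable patients first alarmed at
#' least `k` hours before onset.
#'
#' @param object An `hd_lead_time` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_lead_time <- function(object, ...) {
  ggplot2::ggplot(object$lead_curve, ggplot2::aes(x = .data$k, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "First alarm at least k hours before onset",
                  y = "Fraction of unstable patients") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a calibration table
#'
#' Observed event fraction against mean predicted probability per bin,
#' with the identity line.
#'
#' @param object An `hd_calibration` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_calibration <- function(object, ...) {
  dat <- object[object$count > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed event fraction",
                  size = "n") +
    ggplot2::theme_minimal()
}
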