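#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class mean spectra with standard-error bands
#'
#' @param patients A patient tibble.
#' @return A ggplot: per-class mean spectrum with a shaded standard-error
#'   ribbon, one panel per class.
#' @export
plot_class_means <- function(patients) {
  d <- class_mean_se(patients)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wavenumber, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (SNV units)")
}

#' Latent-variable score plot
#'
#' LV1 vs LV2 per patient, coloured by class and shaped by cohort — the
#' standard view for judging whether separation in the latent space follows
#' the class labels, the cohorts (batch), or both.
#'
#' @param object A fitted `plsda` model (training scores are plotted) or a
#'   score tibble from [export_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.plsda <- function(object, ...) {
  sc <- dplyr::bind_cols(
    as_tibble(object$patients),
    tibble(LV1 = object$t_scores[, 1],
           LV2 = if (object$n_lv >= 2) object$t_scores[, 2] else 0))
  plot_scores(sc)
}

#' @rdname autoplot.plsda
#' @param scores A tibble with `LV1`, `LV2`, `label` and optionally `cohort`.
#' @export
plot_scores <- function(scores, ...) {
  p <- if ("cohort" %in% names(scores)) {
    ggplot2::ggplot(scores, ggplot2::aes(x = .data$LV1, y = .data$LV2,
                                         colour = .data$label,
                                         shape = factor(.data$cohort)))
  } else {
    ggplot2::ggplot(scores, ggplot2::aes(x = .data$LV1, y = .data$LV2,
                                         colour = .data$label))
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "LV1", y = "LV2", colour = "Class", shape = "Cohort")
}

#' Selection-frequency bar plot
#'
#' Frequency of each wavenumber over the jackknife iterations of
#' [stability_selection()].
#'
#' @param object A `frequency_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.frequency_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Selection count")
}

#' Threshold-scan heat map
#'
#' Accuracy, sensitivity and specificity of the frequency-threshold models
#' from [threshold_scan()], as a metric-by-threshold heat map.
#'
#' @param object A `threshold_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.threshold_scan <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::filter(!.data$empty) |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$threshold),
                                  y = .data$metric, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Frequency threshold", y = NULL, fill = "Value")
}

#' RMSECV elimination trajectory
#'
#' @param object A `selection_result` from [iterative_selection()].
#' @param ... Unused.
#' @return A ggplot of RMSECV against the number of retained variables.
#' @exportS3Method
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$n_variables, y = .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Variables retained", y = "RMSECV")
}
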