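# ggplot2 methods for the package's result types.

#' @export
autoplot.sers_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)")
}

#' Heat map of a SERS chip scan
#'
#' Plots the per-pixel net band height (maximum intensity inside the band
#' window) on the chip grid.
#'
#' @param object A `sers_map` tibble.
#' @param band,window_halfwidth Band window used for the per-pixel height.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sers_map <- function(object, band = 1559, window_halfwidth = 10,
                              ...) {
  hmap <- object |>
    dplyr::filter(abs(.data$wavenumber - band) <= window_halfwidth) |>
    dplyr::group_by(.data$pixel, .data$row, .data$col) |>
    dplyr::summarise(height = max(.data$intensity), .groups = "drop")
  ggplot2::ggplot(hmap, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$height)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Column", y = "Row",
                  fill = sprintf("I(%g cm⁻¹)", band)) +
    ggplot2::coord_equal()
}

#' @export
autoplot.univariate_cal <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(.data$concentration, .data$mean_height)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_height - .data$sd_height,
                                        ymax = .data$mean_height + .data$sd_height),
                           width = 10, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = expression("Concentration ("*mu*"M)"),
                  y = sprintf("Net band height at %g cm⁻¹ (a.u.)",
                              object$band))
}

#' Predicted versus reference concentrations of a PLSR model
#'
#' @param object A `sers_plsr` model.
#' @param ... Unused.
#' @return A ggplot of cross-validated predictions against the reference
#'   values, with the identity line.
#' @export
autoplot.sers_plsr <- function(object, ...) {
  df <- tibble::tibble(reference = object$y,
                       predicted = object$cv_predictions[, object$lv])
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("Reference concentration ("*mu*"M)"),
                  y = expression("CV-predicted concentration ("*mu*"M)"))
}

#' @export
autoplot.sers_pca <- function(object, ...) {
  df <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE],
                          .name_repair = ~ c("PC1", "PC2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]))
}

#' Bland-Altman plot
#'
#' Differences (test - reference) against pair means, with the bias and the
#' limits of agreement as dashed lines.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$mean_pair, .data$difference)) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 2,
                        colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = c(object$lla, object$ula),
                        linetype = 2, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("Mean of methods ("*mu*"M)"),
                  y = expression("Test - reference ("*mu*"M)"))
}

#' @export
autoplot.method_scatter <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$reference, .data$test)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$reference, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, fill = "red", alpha = 0.2) +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$reference, y = .data$fit),
                       colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("Reference method ("*mu*"M)"),
                  y = expression("Test method ("*mu*"M)"))
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = sprintf("Null %s", object$statistic), y = "Count")
}

#' RMSE versus latent-variable count
#'
#' Calibration and cross-validation RMSE curves of a fitted PLSR model; the
#' gap opening between them marks overfitting.
#'
#' @param model A `sers_plsr`.
#' @return A ggplot.
#' @export
plot_rmse_curves <- function(model) {
  df <- tibble::tibble(lv = seq_len(model$max_lv),
                       RMSEC = model$rmsec, RMSECV = model$rmsecv) |>
    tidyr::pivot_longer(-"lv", names_to = "metric", values_to = "rmse")
  ggplot2::ggplot(df, ggplot2::aes(.data$lv, .data$rmse,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = model$lv, linetype = 3) +
    ggplot2::labs(x = "Latent variables",
                  y = expression("RMSE ("*mu*"M)"), colour = NULL)
}
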