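#' Plot spectra
#'
#' Overlays the spectra of a spectra tibble as absorbance against
#' wavelength, one line per scan.
#'
#' @param spectra a spectra tibble.
#' @param max_rows cap on the number of scans drawn (default 30).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, max_rows = 30) {
  spectra <- head(spectra, max_rows)
  long <- tidyr::pivot_longer(spectra,
                              cols = -dplyr::any_of(c("sample_id",
                                                      "subsample_id")),
                              names_to = "wavelength",
                              values_to = "absorbance")
  long$wavelength <- as.numeric(long$wavelength)
  long$scan <- paste(long$sample_id, long$subsample_id %||% "")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$scan)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "log(1/R)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' SECV curve of a calibration
#'
#' @param object a `nirs_calibration`.
#' @param ... unused.
#' @return A ggplot of SECV against factor count with the chosen optimum
#'   marked.
#' @method autoplot nirs_calibration
#' @export
autoplot.nirs_calibration <- function(object, ...) {
  curve <- object$secv_curve
  opt <- object$optimal_factors
  ggplot2::ggplot(curve, ggplot2::aes(.data$factors, .data$secv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = opt, linetype = "dashed") +
    ggplot2::labs(x = "PLS factors", y = "SECV",
                  title = sprintf("%s + %s: optimum at %d factor(s)",
                                  object$spec$code, object$spec$scatter,
                                  opt)) +
    ggplot2::theme_minimal()
}

#' Leaderboard overview of a grid search
#'
#' @param object a `nirs_grid_search`.
#' @param ... unused.
#' @return A ggplot of SECV per derivative code and scatter method.
#' @method autoplot nirs_grid_search
#' @export
autoplot.nirs_grid_search <- function(object, ...) {
  board <- object$leaderboard
  board <- board[is.na(board$error), ]
  ggplot2::ggplot(board, ggplot2::aes(.data$code, .data$scatter,
                                      fill = .data$secv)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "derivative code", y = "scatter correction",
                  fill = "SECV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Predicted-versus-observed plot for a validation set
#'
#' @param result a `nirs_calibration` (or grid-search winner).
#' @param spectra validation spectra tibble.
#' @param reference reference table.
#' @return A ggplot with the identity line.
#' @export
plot_predictions <- function(result, spectra, reference) {
  if (inherits(result, "nirs_grid_search")) result <- result$best
  pred <- predict(result, spectra)
  idx <- match(pred$sample_id, reference$sample_id)
  df <- tibble::tibble(observed = reference[[result$constituent]][idx],
                       predicted = pred$prediction)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("observed %s", result$constituent),
                  y = "NIRS predicted") +
    ggplot2::theme_minimal()
}
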