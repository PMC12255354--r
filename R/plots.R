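#' Plot the reconstruction-error distribution with the anomaly threshold
#'
#' Violin-style summary of reconstruction errors by group (training vs
#' testing, split by truth label when available), with the decision
#' threshold drawn as a horizontal line.
#'
#' @param results Classification tibble from [classify()].
#' @param train_errors Optional numeric vector of training errors to show
#'   alongside the test errors.
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(results, train_errors = NULL) {
  df <- dplyr::mutate(
    results,
    group = dplyr::if_else(is.na(.data$truth_label), "test",
                           paste0("test_", .data$truth_label))
  ) |>
    dplyr::select("group", "error")
  if (!is.null(train_errors))
    df <- dplyr::bind_rows(
      tibble::tibble(group = "train", error = train_errors), df)
  thr <- results$threshold[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$error,
                                   fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "reconstruction error (MSE)",
                  title = "Reconstruction errors and anomaly threshold") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-clusterecho
#' @method autoplot spectral_report
#' @export
autoplot.spectral_report <- function(object, which = c("spectra", "scatter"),
                                     ...) {
  which <- match.arg(which)
  if (which == "spectra") {
    bands <- tibble::tibble(
      lo = c(object$fund_band$center - object$fund_band$half_width,
             object$sub_band$center - object$sub_band$half_width),
      hi = c(object$fund_band$center + object$fund_band$half_width,
             object$sub_band$center + object$sub_band$half_width)
    )
    ggplot2::ggplot(object$spectra,
                    ggplot2::aes(x = .data$freq / 1e6, y = .data$magnitude,
                                 color = .data$group)) +
      ggplot2::geom_rect(data = bands,
                         ggplot2::aes(xmin = .data$lo / 1e6,
                                      xmax = .data$hi / 1e6,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.08) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "frequency (MHz)", y = "mean |DFT| magnitude",
                    title = "Group mean spectra") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$points,
                    ggplot2::aes(x = .data$fund_amp, y = .data$sub_amp,
                                 color = .data$group)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.6) +
      ggplot2::labs(x = "fundamental band amplitude",
                    y = "subharmonic band amplitude",
                    title = "Subharmonic vs fundamental amplitude") +
      ggplot2::theme_minimal()
  }
}

#' Autoplot methods for clusterecho result objects
#'
#' `autoplot.spectral_report()` draws either the group mean spectra with the
#' fundamental/subharmonic bands shaded, or the subharmonic-vs-fundamental
#' scatter with per-group OLS lines. `autoplot.lstm_autoencoder()` draws the
#' training-loss history.
#'
#' @param object A `spectral_report` or `lstm_autoencoder`.
#' @param which For spectral reports: `"spectra"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-clusterecho
#' @method autoplot lstm_autoencoder
#' @export
autoplot.lstm_autoencoder <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$history),
                       loss = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "training MSE", title = "Autoencoder training loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
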