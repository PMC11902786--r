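#' Plot spectra colored by class
#'
#' Draws every reflectance curve (or a per-class subsample) against
#' wavelength, colored by class, with the class-mean curves overlaid.
#'
#' @param object A [spectral_dataset].
#' @param max_per_class At most this many individual curves per class
#'   (default 20); class means are always drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_dataset
#' @export
autoplot.spectral_dataset <- function(object, max_per_class = 20, ...) {
  tb <- as_tibble(object)
  keep_ids <- tb |>
    dplyr::distinct(.data$.id, .data$class) |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::pull(".id")
  means <- tb |>
    dplyr::group_by(.data$class, .data$wavelength) |>
    dplyr::summarise(reflectance = mean(.data$reflectance), .groups = "drop")
  ggplot2::ggplot(ggplot2::aes(x = .data$wavelength, y = .data$reflectance,
                               colour = .data$class),
                  data = dplyr::filter(tb, .data$.id %in% keep_ids)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$.id), alpha = 0.15) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the training loss curve
#' @param object An `mbnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbnet_fit
#' @export
autoplot.mbnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#' @param object An `mbnet_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbnet_cv
#' @export
autoplot.mbnet_cv <- function(object, ...) {
  tb <- tidy(object) |>
    tidyr::pivot_longer(c("OA", "AA", "Kappa"), names_to = "metric")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Plot the ablation comparison
#' @param object An `mbnet_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbnet_ablation
#' @export
autoplot.mbnet_ablation <- function(object, ...) {
  tb <- object$report |>
    tidyr::pivot_longer(c("OA", "AA", "Kappa"), names_to = "metric")
  tb$variant <- factor(tb$variant, levels = .mbnet_variants)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$variant, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fold-mean value", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Heatmap of a confusion matrix
#'
#' Row-normalised counts (per-class recall) as a tile plot.
#'
#' @param cm A square count matrix.
#' @param class_names Optional axis labels.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm, class_names = NULL) {
  m <- .check_cm(cm)
  C <- nrow(m)
  if (is.null(class_names)) class_names <- as.character(seq_len(C) - 1L)
  frac <- m / pmax(rowSums(m), 1)
  tb <- tibble::tibble(
    true = factor(rep(class_names, times = C), levels = rev(class_names)),
    predicted = factor(rep(class_names, each = C), levels = class_names),
    count = as.vector(m),
    fraction = as.vector(frac)
  )
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true", fill = "recall") +
    ggplot2::theme_minimal()
}
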