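#' Plot a spiral drawing
#'
#' Draws the pen trajectory of a record, pen-up samples dimmed.
#'
#' @param record a [spiral_record()].
#' @return a ggplot object.
#' @export
plot_spiral <- function(record) {
  validate_spiral_record(record)
  df <- tibble::as_tibble(record)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   alpha = factor(.data$pen_state))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`0` = 0.15, `1` = 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Spiral drawing: %s (%s hand)",
                                  subject_id(record), record_hand(record)),
                  x = "x (device units)", y = "y (device units)") +
    ggplot2::theme_minimal()
}

#' Plot feature series curves
#'
#' Overlays the per-subject curves of a feature table, colored by group when
#' group labels are present.
#'
#' @param series a [feature_series()] table.
#' @param alpha line transparency.
#' @return a ggplot object.
#' @export
plot_series <- function(series, alpha = 0.5) {
  stopifnot(inherits(series, "feature_series"))
  df <- tidyr::unnest(
    tibble::tibble(
      subject_id = series$subject_id,
      group = series$group %||% "all",
      values = series$values
    ),
    "values"
  )
  df <- dplyr::mutate(df,
                      index = dplyr::row_number(),
                      .by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$values,
                                   group = .data$subject_id,
                                   color = .data$group)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.2) +
    ggplot2::labs(x = "sample", y = series$kind[1L],
                  title = sprintf("%s series", series$kind[1L])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a correlation summary
#'
#' @param object a `correlation_summary` from [group_correlation_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot correlation_summary
#' @export
autoplot.correlation_summary <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    correlation = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s correlation matrix (%s)",
                                  object$group %||% "", object$mode),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a validation report
#'
#' @param object a `validation_report` from [run_validation()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  cm <- as.data.frame(object$confusion)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "seagreen") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("%s / %s: test accuracy %.1f%%",
                                  object$classifier, object$scheme,
                                  object$metrics_test$accuracy),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
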