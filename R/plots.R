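field_to_df <- function(values) {
  tibble(
    row = rep(seq_len(nrow(values)), times = ncol(values)),
    col = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(values)
  )
}

#' Plot a temperature field
#'
#' @param object A [temperature_field()].
#' @param ... Unused.
#' @return A ggplot raster of the field (y axis flipped to image convention).
#' @method autoplot temperature_field
#' @export
autoplot.temperature_field <- function(object, ...) {
  df <- field_to_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "T (K)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a multi-channel fluorescent image
#'
#' @param object A [fluorescent_image()].
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @method autoplot fluorescent_image
#' @export
autoplot.fluorescent_image <- function(object, ...) {
  d <- dim(object$channels)
  dfs <- lapply(seq_len(d[3]), function(j) {
    df <- field_to_df(object$channels[, , j])
    df$channel <- object$channel_names[j]
    df
  })
  df <- dplyr::bind_rows(dfs)
  df$channel <- factor(df$channel, levels = object$channel_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstruction result
#'
#' @param object A [reconstruction_result()].
#' @param what `"predicted"`, `"error"` (signed error map) or `"gradient"`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @method autoplot reconstruction_result
#' @export
autoplot.reconstruction_result <- function(object, what = c("predicted", "error", "gradient"), ...) {
  what <- match.arg(what)
  m <- switch(what,
    predicted = object$predicted$values,
    error = object$error_map %||% abort("result has no error map"),
    gradient = object$gradient_norm_map %||% abort("result has no gradient map")
  )
  df <- field_to_df(m)
  if (!is.null(object$mask) && what != "predicted") df$value[!as.vector(object$mask)] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  p + switch(what,
    predicted = ggplot2::scale_fill_viridis_c(option = "inferno", name = "T (K)"),
    error = ggplot2::scale_fill_gradient2(name = "error (K)"),
    gradient = ggplot2::scale_fill_viridis_c(name = "|grad T| (K/um)")
  )
}

#' Scatter of absolute error against gradient magnitude
#'
#' Visualizes the error-gradient association of a reconstruction: one point
#' per pixel, log-log axes, with the Spearman rank correlation annotated.
#'
#' @param result A truth-based [reconstruction_result()].
#' @param max_points Subsample cap for plotting (default 5000).
#' @param seed Seed for the subsample.
#' @return A ggplot scatter.
#' @export
plot_error_gradient <- function(result, max_points = 5000L, seed = 1L) {
  an <- error_gradient_analysis(result)
  df <- an$pairs
  if (nrow(df) > max_points) {
    df <- df[with_seed(seed, sample.int(nrow(df), max_points)), ]
  }
  lab <- if (an$correlation_defined) {
    sprintf("Spearman rho = %.3f", an$spearman_rho)
  } else "correlation undefined"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gradient_k_per_um, y = .data$abs_error_k)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "|grad T| (K/um)", y = "|error| (K)", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a temperature-range sweep
#'
#' @param sweep A tibble from [range_sweep_experiment()].
#' @return A ggplot of RMSE against scene temperature span.
#' @export
plot_range_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$span_k, y = .data$rmse_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scene temperature span (K)", y = "mask-aware RMSE (K)") +
    ggplot2::theme_minimal()
}
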