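#' Root mean squared error between two temperature fields
#'
#' @param predicted,truth [temperature_field()]s (or bare matrices) of equal
#'   shape.
#' @param mask Optional logical matrix restricting the evaluated pixels
#'   (chip scenes are always scored over the channel mask).
#' @return RMSE in K.
#' @examples
#' a <- temperature_field(matrix(300, 4, 4))
#' b <- temperature_field(matrix(300.3, 4, 4))
#' rmse(a, b)
#' @export
rmse <- function(predicted, truth, mask = NULL) {
  p <- if (inherits(predicted, "temperature_field")) predicted$values else predicted
  t <- if (inherits(truth, "temperature_field")) truth$values else truth
  if (!identical(dim(p), dim(t))) abort("shape mismatch between predicted and truth")
  e <- p - t
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(p))) abort("mask shape mismatch")
    if (!any(mask)) abort("empty mask: no pixels selected")
    e <- e[mask]
  }
  sqrt(mean(e^2))
}

#' Per-pixel L2 norm of the spatial temperature gradient
#'
#' Central differences in the interior, one-sided at the borders, divided by
#' the pixel pitch; the result is the magnitude of (dT/dx, dT/dy) in K/um.
#' High-gradient pixels are where reconstruction error concentrates.
#'
#' @param field A [temperature_field()] of at least 2x2 pixels.
#' @return Numeric matrix of gradient norms (K/um).
#' @export
gradient_norm_map <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  v <- field$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2L || nc < 2L) abort("field must be at least 2x2")
  # y = rows (first index), x = columns
  gy <- v
  gy[2:(nr - 1), ] <- (v[3:nr, ] - v[1:(nr - 2), ]) / 2
  gy[1, ] <- v[2, ] - v[1, ]
  gy[nr, ] <- v[nr, ] - v[nr - 1, ]
  gx <- v
  gx[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / 2
  gx[, 1] <- v[, 2] - v[, 1]
  gx[, nc] <- v[, nc] - v[, nc - 1]
  sqrt(gx^2 + gy^2) / field$pitch_um
}

#' Reconstruction result container
#'
#' Bundles a reconstruction with its evaluation against ground truth:
#' the signed error map, RMSE (over the mask when one applies), and the
#' truth's gradient-norm map.
#'
#' @param predicted Predicted [temperature_field()].
#' @param truth Optional ground-truth field.
#' @param mask Optional logical evaluation mask.
#' @param lineage Named list (model id, dataset id, ...).
#' @return A `reconstruction_result`.
#' @export
reconstruction_result <- function(predicted, truth = NULL, mask = NULL,
                                  lineage = list()) {
  err <- NULL; r <- NA_real_; gmap <- NULL
  if (!is.null(truth)) {
    err <- predicted$values - truth$values
    r <- rmse(predicted, truth, mask)
    gmap <- gradient_norm_map(truth)
  }
  structure(
    list(predicted = predicted, truth = truth, error_map = err, rmse = r,
         mask = mask, gradient_norm_map = gmap, lineage = lineage),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  d <- dim(x$predicted$values)
  cat(sprintf("<reconstruction_result> %d x %d px", d[1], d[2]))
  if (!is.na(x$rmse)) cat(sprintf(", RMSE %.4f K%s", x$rmse,
                                  if (!is.null(x$mask)) " (masked)" else ""))
  cat("\n")
  invisible(x)
}

#' @rdname reconstruction_result
#' @param x A `reconstruction_result`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per evaluated pixel (`row`, `col`,
#'   `predicted_k`, `truth_k`, `error_k`, `abs_error_k`, `gradient_k_per_um`);
#'   `glance()`: a one-row summary.
#' @method tidy reconstruction_result
#' @export
tidy.reconstruction_result <- function(x, ...) {
  if (is.null(x$truth)) abort("tidy() needs a truth-based result")
  d <- dim(x$predicted$values)
  keep <- if (is.null(x$mask)) rep(TRUE, prod(d)) else as.vector(x$mask)
  ij <- which(matrix(keep, d[1], d[2]), arr.ind = TRUE)
  tibble(
    row = ij[, 1], col = ij[, 2],
    predicted_k = x$predicted$values[keep],
    truth_k = x$truth$values[keep],
    error_k = x$error_map[keep],
    abs_error_k = abs(x$error_map[keep]),
    gradient_k_per_um = x$gradient_norm_map[keep]
  )
}

#' @rdname reconstruction_result
#' @method glance reconstruction_result
#' @export
glance.reconstruction_result <- function(x, ...) {
  tibble(
    rmse_k = x$rmse,
    max_abs_error_k = if (is.null(x$error_map)) NA_real_ else {
      if (is.null(x$mask)) max(abs(x$error_map)) else max(abs(x$error_map[x$mask]))
    },
    mean_gradient_k_per_um = if (is.null(x$gradient_norm_map)) NA_real_ else {
      if (is.null(x$mask)) mean(x$gradient_norm_map) else mean(x$gradient_norm_map[x$mask])
    },
    n_pixels = if (is.null(x$mask)) prod(dim(x$predicted$values)) else sum(x$mask)
  )
}

#' Error-gradient association analysis
#'
#' Quantifies the association between absolute reconstruction error and the
#' local temperature-gradient magnitude: reports the mean and max gradient
#' norm, the per-pixel (|error|, gradient norm) pairs, and their Spearman
#' rank correlation. A constant error map (or constant gradient map) makes
#' the correlation undefined; it is then reported as `NA` with
#' `correlation_defined = FALSE` rather than failing.
#'
#' @param result A truth-based `reconstruction_result`.
#' @return A list with `mean_gradient`, `max_gradient` (K/um),
#'   `spearman_rho`, `correlation_defined`, and `pairs` (tibble of
#'   `abs_error_k`, `gradient_k_per_um`).
#' @export
error_gradient_analysis <- function(result) {
  stopifnot(inherits(result, "reconstruction_result"))
  if (is.null(result$error_map)) abort("result lacks a truth-based error map")
  keep <- if (is.null(result$mask)) TRUE else result$mask
  ae <- abs(result$error_map)[keep]
  gn <- result$gradient_norm_map[keep]
  defined <- stats::sd(ae) > 0 && stats::sd(gn) > 0
  rho <- if (defined) cor(ae, gn, method = "spearman") else NA_real_
  list(
    mean_gradient = mean(gn), max_gradient = max(gn),
    spearman_rho = rho, correlation_defined = defined,
    pairs = tibble(abs_error_k = ae, gradient_k_per_um = gn)
  )
}
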