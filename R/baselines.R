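#' Multivariate polynomial fit (MVPF) baseline
#'
#' The classical pointwise baseline: a least-squares polynomial of total
#' degree 2 in the C channel intensities (all monomials up to degree 2,
#' including cross terms — `choose(C + 2, 2)` coefficients) mapping per-pixel
#' intensities to temperature.
#'
#' @param intensities Matrix `n x C` of normalized channel intensities.
#' @param temperatures Numeric vector of length `n` (K).
#' @return An `mvpf_model` with the coefficient vector and monomial recipe.
#' @export
mvpf_fit <- function(intensities, temperatures) {
  X <- as.matrix(intensities)
  n <- nrow(X); C <- ncol(X)
  if (length(temperatures) != n) abort("one temperature per pixel required")
  D <- mvpf_design(X)
  if (n < ncol(D)) abort(sprintf("need at least %d training pixels", ncol(D)))
  fit <- lm.fit(D, temperatures)
  if (fit$rank < ncol(D)) {
    warn("rank-deficient MVPF design; aliased coefficients set to zero")
    fit$coefficients[is.na(fit$coefficients)] <- 0
  }
  structure(list(coefficients = fit$coefficients, n_channels = C),
            class = "mvpf_model")
}

# All monomials of total degree <= 2 in the columns of X (intercept first).
mvpf_design <- function(X) {
  C <- ncol(X)
  cols <- list(matrix(1, nrow(X), 1))
  nms <- "1"
  for (j in seq_len(C)) { cols <- c(cols, list(X[, j, drop = FALSE])); nms <- c(nms, paste0("x", j)) }
  for (j in seq_len(C)) for (k in j:C) {
    cols <- c(cols, list(X[, j, drop = FALSE] * X[, k, drop = FALSE]))
    nms <- c(nms, paste0("x", j, ":x", k))
  }
  D <- do.call(cbind, cols)
  colnames(D) <- nms
  D
}

#' @rdname mvpf_fit
#' @param model An `mvpf_model`.
#' @param intensities Matrix `n x C` of normalized intensities to predict for.
#' @return Numeric vector of predicted temperatures (K).
#' @export
mvpf_predict <- function(model, intensities) {
  stopifnot(inherits(model, "mvpf_model"))
  X <- as.matrix(intensities)
  if (ncol(X) != model$n_channels) abort("channel count mismatch")
  as.numeric(mvpf_design(X) %*% model$coefficients)
}

#' Random-forest pixelwise baseline
#'
#' A per-pixel regression forest on the C channel intensities, via
#' \pkg{ranger}. Defaults: 200 trees, unlimited depth, square-root feature
#' subsampling, fixed seed.
#'
#' @param intensities Matrix `n x C` of normalized channel intensities.
#' @param temperatures Numeric vector of length `n` (K).
#' @param num_trees Number of trees (default 200).
#' @param max_depth Maximum tree depth; 0 (default) = unlimited.
#' @param mtry Features tried per split; default `floor(sqrt(C))`.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return An `rf_model` wrapping the fitted forest.
#' @export
rf_fit <- function(intensities, temperatures, num_trees = 200, max_depth = 0,
                   mtry = NULL, seed = 1L, ...) {
  X <- as.matrix(intensities)
  if (nrow(X) != length(temperatures)) abort("one temperature per pixel required")
  df <- as.data.frame(X)
  names(df) <- paste0("ch", seq_len(ncol(X)))
  df$.t <- temperatures
  fit <- ranger::ranger(
    dependent.variable.name = ".t", data = df,
    num.trees = num_trees, max.depth = max_depth,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(X)))),
    seed = seed, num.threads = 1, ...
  )
  structure(list(forest = fit, n_channels = ncol(X)), class = "rf_model")
}

#' @rdname rf_fit
#' @param model An `rf_model`.
#' @return Numeric vector of predicted temperatures (K).
#' @export
rf_predict <- function(model, intensities) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(intensities)
  if (ncol(X) != model$n_channels) abort("channel count mismatch")
  df <- as.data.frame(X)
  names(df) <- paste0("ch", seq_len(ncol(X)))
  stats::predict(model$forest, data = df, num.threads = 1)$predictions
}

# Per-pixel (intensity, temperature) pairs from an image/field pair,
# flattened in column-major pixel order; the training fodder for the
# pointwise baselines.
pixel_table <- function(image, field = NULL, mask = NULL) {
  d <- dim(image$channels)
  keep <- if (is.null(mask)) rep(TRUE, d[1] * d[2]) else as.vector(mask)
  X <- matrix(0, sum(keep), d[3])
  for (j in seq_len(d[3])) {
    ch <- as.vector(image$channels[, , j])
    X[, j] <- normalize_counts(ch[keep])
  }
  t <- if (!is.null(field)) as.vector(field$values)[keep] else NULL
  list(intensities = X, temperatures = t, keep = keep, shape = d[1:2])
}

#' Reconstruct a full field with a pointwise baseline
#'
#' Applies an MVPF or random-forest predictor to every pixel of an image.
#'
#' @param model An `mvpf_model` or `rf_model`.
#' @param image A [fluorescent_image()].
#' @param channels Optional integer subset of channels to feed the model.
#' @return A [temperature_field()].
#' @export
pointwise_predict_field <- function(model, image, channels = NULL) {
  d <- dim(image$channels)
  ch_sel <- channels %||% seq_len(d[3])
  img <- image
  img$channels <- image$channels[, , ch_sel, drop = FALSE]
  pt <- pixel_table(img)
  pred <- if (inherits(model, "mvpf_model")) {
    mvpf_predict(model, pt$intensities)
  } else if (inherits(model, "rf_model")) {
    rf_predict(model, pt$intensities)
  } else abort("model must be mvpf_model or rf_model")
  temperature_field(matrix(pred, d[1], d[2]), pitch_um = 1,
                    meta = list(generator = class(model)[1]))
}
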