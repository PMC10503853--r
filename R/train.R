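#' Train a patch-recurrent network
#'
#' Minibatch Adam on mean-squared error over kelvin targets, with early
#' stopping on validation RMSE. Targets are standardized internally (train-set
#' mean and standard deviation, stored in the model and inverted on output) so
#' optimization is well conditioned regardless of the absolute kelvin scale.
#' Training with a fixed seed is reproducible run to run on one machine.
#'
#' @param config A [net_config()], or an `ft_model` to continue training.
#' @param train_batch A `sequence_batch` or `tile_batch` with targets
#'   (variant-appropriate: sequences for FTLSTM/BFTLSTM, tiles for MFTLSTM).
#' @param val_batch Optional held-out batch of the same type, used for early
#'   stopping and the reported validation RMSE. Build it from different source
#'   images than `train_batch`: overlapping patches leak heavily within one
#'   image, so splits must be at the whole-image level.
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 256).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Integer seed (shuffling, dropout).
#' @param verbose Print per-epoch losses.
#' @return A trained `ft_model`; `lineage` records per-epoch training loss
#'   (K^2, standardized scale), validation RMSE (K), and the seed.
#' @export
train_model <- function(config, train_batch, val_batch = NULL, epochs = 20L,
                        lr = 1e-3, batch_size = 256L, patience = 10L,
                        seed = 1L, verbose = FALSE) {
  model <- if (inherits(config, "ft_model")) config else init_model(config)
  if (is.null(train_batch$targets)) abort("train_batch has no targets")
  is_tiles <- inherits(train_batch, "tile_batch")
  if (model$variant == "MFTLSTM" && !is_tiles) abort("MFTLSTM trains on tile batches")
  if (model$variant != "MFTLSTM" && is_tiles) abort("sequence models train on sequence batches")

  tm <- mean(train_batch$targets)
  ts <- stats::sd(train_batch$targets)
  if (!is.finite(ts) || ts == 0) ts <- 1
  # per-channel input standardization (conditioning; constants travel with
  # the model). Continued training keeps the original constants.
  if (is.null(model$norm$x_mean)) {
    nd <- length(dim(train_batch$inputs))
    ch_stats <- apply(train_batch$inputs, nd, function(v) c(mean(v), stats::sd(v)))
    x_sd <- ch_stats[2, ]
    x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
    model$norm <- list(t_mean = tm, t_sd = ts,
                       x_mean = unname(ch_stats[1, ]), x_sd = unname(x_sd))
  } else {
    model$norm$t_mean <- tm
    model$norm$t_sd <- ts
  }
  ytr <- (train_batch$targets - tm) / ts
  n <- dim(train_batch$inputs)[1]

  opt <- adam_init(model$params)
  train_loss <- numeric(0)
  val_rmse <- numeric(0)
  best <- list(params = model$params, val = Inf, epoch = 0L)
  seeds <- derive_seeds(seed, epochs)

  for (ep in seq_len(epochs)) {
    ep_loss <- 0; ep_n <- 0
    with_seed(seeds[ep], {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- if (is_tiles) train_batch$inputs[idx, , , , drop = FALSE]
              else train_batch$inputs[idx, , , drop = FALSE]
        yb <- if (is_tiles) ytr[idx, , , drop = FALSE] else ytr[idx, , drop = FALSE]
        fw <- model_core_forward(model, xb, training = TRUE)
        resid <- fw$y - yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        }
        dy <- 2 * resid / length(resid)
        grads <- model_backprop(model, fw$cache, dy)
        st <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
    })
    train_loss <- c(train_loss, ep_loss / ep_n)
    if (!is.null(val_batch)) {
      vr <- eval_rmse(model, val_batch)
      val_rmse <- c(val_rmse, vr)
      if (vr < best$val - 1e-12) best <- list(params = model$params, val = vr, epoch = ep)
      if (verbose) {
        message(sprintf("epoch %d: train MSE %.5f, val RMSE %.4f K", ep, tail(train_loss, 1), vr))
      }
      if (ep - best$epoch >= patience) break
    } else if (verbose) {
      message(sprintf("epoch %d: train MSE %.5f", ep, tail(train_loss, 1)))
    }
  }
  if (!is.null(val_batch) && is.finite(best$val)) model$params <- best$params
  model$lineage <- list(
    train_loss = train_loss, val_rmse = val_rmse, seed = seed,
    epochs_run = length(train_loss),
    final_val_rmse = if (length(val_rmse)) best$val else NA_real_
  )
  model
}

# Patch-level validation RMSE in kelvin (eval mode, batched to bound memory).
eval_rmse <- function(model, batch, chunk = 4096L) {
  n <- dim(batch$inputs)[1]
  is_tiles <- inherits(batch, "tile_batch")
  sse <- 0; cnt <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xb <- if (is_tiles) batch$inputs[idx, , , , drop = FALSE]
          else batch$inputs[idx, , , drop = FALSE]
    yb <- if (is_tiles) batch$targets[idx, , , drop = FALSE]
          else batch$targets[idx, , drop = FALSE]
    pred <- denorm(model, model_core_forward(model, xb)$y)
    sse <- sse + sum((pred - (yb + batch$target_center))^2)
    cnt <- cnt + length(yb)
  }
  sqrt(sse / cnt)
}

#' @rdname train_model
#' @param x A trained `ft_model`.
#' @param ... Unused.
#' @return `tidy()`: per-epoch tibble (`epoch`, `train_mse`, `val_rmse_k`);
#'   `glance()`: one-row summary (variant, parameters, epochs, final val RMSE).
#' @method tidy ft_model
#' @export
tidy.ft_model <- function(x, ...) {
  tl <- x$lineage$train_loss
  if (is.null(tl)) abort("model has no training lineage")
  vr <- x$lineage$val_rmse
  tibble(
    epoch = seq_along(tl), train_mse = tl,
    val_rmse_k = if (length(vr)) vr else NA_real_
  )
}

#' @rdname train_model
#' @method glance ft_model
#' @export
glance.ft_model <- function(x, ...) {
  tibble(
    variant = x$variant,
    n_parameters = count_parameters(x),
    channels_in = x$config$channels_in,
    hidden1 = x$config$hidden1, hidden2 = x$config$hidden2,
    epochs_run = x$lineage$epochs_run %||% 0L,
    val_rmse_k = x$lineage$final_val_rmse %||% NA_real_
  )
}

#' Reconstruct a full temperature map from a fluorescent image
#'
#' The end-to-end inverse step: extracts patches at the configured stride
#' (sequences or tiles to match the model; pixels for the pointwise
#' baselines), predicts per patch, stitches overlapping predictions by
#' per-pixel mean, and — when ground truth is supplied — evaluates the signed
#' error map, RMSE and gradient-norm map.
#'
#' @param model An `ft_model`, `mvpf_model` or `rf_model`.
#' @param image A [fluorescent_image()].
#' @param truth Optional ground-truth [temperature_field()].
#' @param stride Patch stride for extraction (default 1, dense).
#' @param mask Optional logical evaluation mask (chip scenes).
#' @param channels Optional channel subset fed to the model.
#' @param chunk Patches per forward chunk (memory bound).
#' @param patch_mask Optional logical matrix: only patches whose footprint
#'   lies entirely inside it are predicted (mask-restricted reconstruction
#'   for chip scenes, where out-of-channel pixels carry no signal). The
#'   stitched field is partial; evaluation is restricted to `mask` pixels
#'   actually covered.
#' @return A [reconstruction_result()].
#' @export
reconstruct <- function(model, image, truth = NULL, stride = 1L, mask = NULL,
                        channels = NULL, chunk = 4096L, patch_mask = NULL) {
  stopifnot(inherits(image, "fluorescent_image"))
  if (!is.null(channels)) {
    image$channels <- image$channels[, , channels, drop = FALSE]
    image$channel_names <- image$channel_names[channels]
  }
  if (inherits(model, c("mvpf_model", "rf_model"))) {
    pred <- pointwise_predict_field(model, image)
    pred$pitch_um <- if (!is.null(truth)) truth$pitch_um else 1
    return(reconstruction_result(pred, truth, mask,
                                 lineage = list(model = class(model)[1])))
  }
  d <- dim(image$channels)
  if (is.function(model)) {
    # test double / custom per-patch predictor: called on the sequence batch
    batch <- extract_sequences(image, stride = stride)
    if (!is.null(patch_mask)) batch <- filter_patches_in_mask(batch, patch_mask)
    preds <- model(batch)
  } else {
    stopifnot(inherits(model, "ft_model"))
    if (d[1] < PATCH_LEN && model$variant == "MFTLSTM") abort("image smaller than a tile")
    batch <- if (model$variant == "MFTLSTM") {
      extract_tiles(image, stride = stride)
    } else {
      extract_sequences(image, stride = stride)
    }
    if (!is.null(patch_mask)) batch <- filter_patches_in_mask(batch, patch_mask)
    n <- dim(batch$inputs)[1]
    is_tiles <- inherits(batch, "tile_batch")
    preds <- if (is_tiles) array(0, c(n, PATCH_LEN, PATCH_LEN)) else matrix(0, n, PATCH_LEN)
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      sub <- batch
      sub$inputs <- if (is_tiles) batch$inputs[idx, , , , drop = FALSE]
                    else batch$inputs[idx, , , drop = FALSE]
      p <- predict_patches(model, sub)
      if (is_tiles) preds[idx, , ] <- p else preds[idx, ] <- p
    }
  }
  pred <- stitch(preds, batch$origins, batch$image_shape,
                 pitch_um = if (!is.null(truth)) truth$pitch_um else 1,
                 fill = if (is.null(patch_mask)) NULL else "mean")
  if (!is.null(patch_mask)) {
    covered <- pred$meta$coverage > 0L
    mask <- if (is.null(mask)) covered else (mask & covered)
  }
  reconstruction_result(pred, truth, mask, lineage = list(
    model = if (is.function(model)) "custom" else model$variant, stride = stride
  ))
}
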