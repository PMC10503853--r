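#' Generate a synthetic benchmark dataset (paired fields and images)
#'
#' The package's replica of the synthetic study conditions: ground-truth
#' fields are randomized annulus (pipe cross-section) solutions of the steady
#' heat equation inside a 298-308 K window (half of them with the sinusoidal
#' top/bottom boundary modulation), pixelwise Gaussian temperature noise of
#' 0.1 K is added, and the noisy fields are rendered into quantized 5-channel
#' 16-bit images through the sharp five-band calibration. Targets for
#' learning are the *clean* fields, so models are scored on their ability to
#' undo the injected noise.
#'
#' Each image's wall temperatures are drawn so the single-scene span is a few
#' kelvin (`span_range`, default 2-6 K) with the scene midpoint ranging over
#' the full window, so the dataset covers all of `t_range` while individual
#' fields stay smoothness-dominated: per-pixel temperature steps well below
#' the 0.1 K noise, the regime in which recurrent spatial context can beat
#' pointwise inversion. Steep scenes (10 K across one small image) would make
#' local smoothing counterproductive and no method could denoise.
#'
#' @param n_images Number of field/image pairs.
#' @param shape `c(rows, cols)` per image.
#' @param t_range Temperature window in K (default `c(298, 308)`).
#' @param span_range Range the per-image wall-temperature span is drawn from
#'   (K); scenes are placed uniformly inside `t_range`.
#' @param noise_sd Temperature noise standard deviation in K (default 0.1).
#' @param seed Integer master seed.
#' @param model A [qd_spectrum_model()].
#' @param bank A [filter_bank()] (default the five sharp bands).
#' @param n_cal Number of calibration temperatures across `t_range`.
#' @param quantize Quantize rendered images to integer counts.
#' @param cal Optional pre-fitted calibration (else fitted from `n_cal`
#'   uniform temperatures).
#' @return A `ft_dataset`: list with `cal`, `items` (each `clean` field,
#'   `noisy` field, `image`), and the generation parameters.
#' @export
make_benchmark_dataset <- function(n_images = 40L, shape = c(48, 48),
                                   t_range = c(298, 308),
                                   span_range = c(2, 6), noise_sd = 0.1,
                                   seed = 1L, model = qd_spectrum_model(),
                                   bank = filter_bank_sharp5(), n_cal = 21L,
                                   quantize = TRUE, cal = NULL) {
  if (is.null(cal)) {
    cal_temps <- seq(t_range[1], t_range[2], length.out = n_cal)
    cal <- fit_calibration(cal_temps, band_intensity_table(model, cal_temps, bank),
                           t_range = t_range)
  }
  seeds <- derive_seeds(seed, 3L * n_images)
  span_range <- pmin(span_range, diff(t_range))
  r_max <- floor(min(shape) / 2) - 1
  items <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    pars <- with_seed(seeds[k], {
      s <- runif(1, span_range[1], span_range[2])
      mid <- runif(1, t_range[1] + s / 2, t_range[2] - s / 2)
      list(
        r_i = max(3, round(runif(1, 0.15, 0.3) * min(shape))),
        r_o = round(runif(1, 0.85, 1) * r_max),
        t_a = mid - s / 2, t_b = mid + s / 2,
        flip = runif(1) < 0.5,
        wave = runif(1) < 0.5,
        jitter = round(runif(2, -0.08, 0.08) * min(shape))
      )
    })
    t_i <- if (pars$flip) pars$t_a else pars$t_b
    t_o <- if (pars$flip) pars$t_b else pars$t_a
    spec <- field_spec(
      "pipe_cross_section", shape = shape, t_range = t_range,
      r_inner_px = pars$r_i, r_outer_px = max(pars$r_o, pars$r_i + 3),
      t_inner = t_i, t_outer = t_o,
      center_px = c((shape[1] + 1) / 2 + pars$jitter[1],
                    (shape[2] + 1) / 2 + pars$jitter[2]),
      boundary_wave = if (pars$wave) list(amplitude_k = 1, period_px = 16) else NULL
    )
    clean <- generate_pipe_field(spec)
    noisy <- add_temperature_noise(clean, noise_sd, seeds[n_images + k])
    # noise tails may leave the declared window by a hair: clip, don't error
    image <- render_image(noisy, cal, quantize = quantize, clip = "clip")
    items[[k]] <- list(clean = clean, noisy = noisy, image = image)
  }
  structure(
    list(cal = cal, items = items,
         params = list(n_images = n_images, shape = shape, t_range = t_range,
                       noise_sd = noise_sd, seed = seed, quantize = quantize)),
    class = "ft_dataset"
  )
}

#' @export
print.ft_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("<ft_dataset> %d images of %d x %d px, [%g, %g] K, noise %g K\n",
              p$n_images, p$shape[1], p$shape[2], p$t_range[1], p$t_range[2],
              p$noise_sd))
  invisible(x)
}

# Concatenate patch batches along the sample axis.
bind_batches <- function(batches) {
  b1 <- batches[[1]]
  is_tiles <- inherits(b1, "tile_batch")
  join <- function(get) do.call(rbind, lapply(batches, get))
  n_tot <- sum(vapply(batches, function(b) dim(b$inputs)[1], numeric(1)))
  dims <- dim(b1$inputs); dims[1] <- n_tot
  inputs <- array(0, dims)
  targets <- if (!is.null(b1$targets)) array(0, c(n_tot, dims[-c(1, length(dims))])) else NULL
  if (!is_tiles && !is.null(targets)) targets <- matrix(0, n_tot, PATCH_LEN)
  if (is_tiles && !is.null(targets)) targets <- array(0, c(n_tot, PATCH_LEN, PATCH_LEN))
  at <- 0L
  for (b in batches) {
    n <- dim(b$inputs)[1]
    rows <- (at + 1L):(at + n)
    if (is_tiles) {
      inputs[rows, , , ] <- b$inputs
      if (!is.null(targets)) targets[rows, , ] <- b$targets
    } else {
      inputs[rows, , ] <- b$inputs
      if (!is.null(targets)) targets[rows, ] <- b$targets
    }
    at <- at + n
  }
  out <- b1
  out$inputs <- inputs
  out$targets <- targets
  out$origins <- dplyr::bind_rows(lapply(batches, function(b) b$origins))
  out
}

subsample_batch <- function(batch, n_keep, seed) {
  n <- dim(batch$inputs)[1]
  if (n_keep >= n) return(batch)
  idx <- with_seed(seed, sample.int(n, n_keep))
  is_tiles <- inherits(batch, "tile_batch")
  batch$inputs <- if (is_tiles) batch$inputs[idx, , , , drop = FALSE]
                  else batch$inputs[idx, , , drop = FALSE]
  if (!is.null(batch$targets)) {
    batch$targets <- if (is_tiles) batch$targets[idx, , , drop = FALSE]
                     else batch$targets[idx, , drop = FALSE]
  }
  batch$origins <- batch$origins[idx, ]
  batch
}

#' Pool training and validation patches from a dataset
#'
#' Splits the dataset's images 80/20 into training and validation *at the
#' whole-image level* (overlapping patches from one image leak badly, so the
#' split is never at patch level), extracts dense stride-1 patches from each
#' image against the clean-field targets, pools them, and optionally
#' subsamples to a budget.
#'
#' @param dataset A `ft_dataset` from [make_benchmark_dataset()].
#' @param type `"sequences"` (1x5) or `"tiles"` (5x5).
#' @param val_frac Fraction of images held out for validation (default 0.2).
#' @param n_train,n_val Optional patch budgets after pooling.
#' @param stride Extraction stride (default 1).
#' @param seed Integer seed (image shuffle and subsampling).
#' @return List with `train` and `val` batches.
#' @export
pool_patches <- function(dataset, type = c("sequences", "tiles"),
                         val_frac = 0.2, n_train = NULL, n_val = NULL,
                         stride = 1L, seed = 1L) {
  type <- match.arg(type)
  n_img <- length(dataset$items)
  n_val_img <- max(1L, round(val_frac * n_img))
  ord <- with_seed(seed, sample.int(n_img))
  val_ids <- ord[seq_len(n_val_img)]
  extract <- function(item) {
    if (type == "sequences") extract_sequences(item$image, item$clean, stride = stride)
    else extract_tiles(item$image, item$clean, stride = stride)
  }
  tr <- bind_batches(lapply(dataset$items[-val_ids], extract))
  va <- bind_batches(lapply(dataset$items[val_ids], extract))
  seeds <- derive_seeds(seed, 2L)
  if (!is.null(n_train)) tr <- subsample_batch(tr, n_train, seeds[1])
  if (!is.null(n_val)) va <- subsample_batch(va, n_val, seeds[2])
  list(train = tr, val = va, val_image_ids = sort(val_ids))
}

#' Train the full model suite on a benchmark dataset
#'
#' Trains the three recurrent variants (matched data budgets and epochs) and
#' fits the two pointwise baselines on the same images, returning everything
#' needed for the comparison experiments.
#'
#' @param dataset A `ft_dataset`.
#' @param hidden `c(hidden1, hidden2)` for all recurrent cores.
#' @param epochs Maximum epochs per network.
#' @param n_train,n_val Patch budgets per network type.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Integer master seed.
#' @param variants Model variants to train (default all three).
#' @param baselines Fit MVPF and RF baselines too (default TRUE).
#' @param rf_num_trees Trees for the RF baseline (default 100 at desk scale).
#' @param verbose Print progress.
#' @return A list with `models` (named list of `ft_model`), `mvpf`, `rf`,
#'   `pools` (the patch pools) and `summary` (tibble of validation RMSEs).
#' @export
train_benchmark_suite <- function(dataset, hidden = c(32L, 16L), epochs = 15L,
                                  n_train = 6000L, n_val = 2000L, lr = 3e-3,
                                  batch_size = 256L, seed = 1L,
                                  variants = c("FTLSTM", "BFTLSTM", "MFTLSTM"),
                                  baselines = TRUE, rf_num_trees = 100,
                                  verbose = FALSE) {
  seeds <- derive_seeds(seed, 8L)
  C <- dim(dataset$items[[1]]$image$channels)[3]
  pools_seq <- pool_patches(dataset, "sequences", n_train = n_train,
                            n_val = n_val, seed = seeds[1])
  pools_tile <- if ("MFTLSTM" %in% variants) {
    pool_patches(dataset, "tiles", n_train = max(1L, round(n_train / 2)),
                 n_val = max(1L, round(n_val / 2)), seed = seeds[1])
  } else NULL
  models <- list()
  for (v in variants) {
    cfg <- net_config(v, channels_in = C, hidden1 = hidden[1], hidden2 = hidden[2],
                      seed = seeds[2])
    pool <- if (v == "MFTLSTM") pools_tile else pools_seq
    if (verbose) message("training ", v)
    models[[v]] <- train_model(cfg, pool$train, pool$val, epochs = epochs,
                               lr = lr, batch_size = batch_size,
                               seed = seeds[3], verbose = verbose)
  }
  mvpf <- rf <- NULL
  if (baselines) {
    # same images as the network training pool, per-pixel
    train_ids <- setdiff(seq_along(dataset$items), pools_seq$val_image_ids)
    px <- lapply(dataset$items[train_ids], function(it) pixel_table(it$image, it$clean))
    X <- do.call(rbind, lapply(px, `[[`, "intensities"))
    yv <- unlist(lapply(px, `[[`, "temperatures"))
    budget <- min(nrow(X), 20000L)
    keep <- with_seed(seeds[4], sample.int(nrow(X), budget))
    mvpf <- mvpf_fit(X[keep, , drop = FALSE], yv[keep])
    rf <- rf_fit(X[keep, , drop = FALSE], yv[keep], num_trees = rf_num_trees,
                 seed = seeds[5])
  }
  summary <- dplyr::bind_rows(lapply(names(models), function(v) {
    tibble(model = v, val_rmse_k = models[[v]]$lineage$final_val_rmse)
  }))
  list(models = models, mvpf = mvpf, rf = rf,
       pools = list(sequences = pools_seq, tiles = pools_tile),
       summary = summary)
}

#' One scaled-down architecture-comparison trial
#'
#' The canonical desk-scale experiment behind the architecture comparison:
#' generate a fresh benchmark dataset, train the three recurrent variants and
#' the pointwise baselines under matched budgets (two-phase Adam schedule:
#' a high-rate phase then a low-rate polish), reconstruct the held-out
#' images, and tabulate per-model reconstruction RMSE alongside patch-level
#' validation RMSE. Problem sizes are chosen so one trial runs in minutes on
#' one CPU while preserving the qualitative behaviour of the full-size study
#' (see the methods vignette).
#'
#' @param seed Integer master seed for the whole trial.
#' @param n_images Images in the generated dataset.
#' @param shape Image shape.
#' @param hidden `c(hidden1, hidden2)` for the recurrent cores.
#' @param n_train_seq,n_val_seq Sequence-patch budgets.
#' @param n_train_tile,n_val_tile Tile-patch budgets.
#' @param epochs_main,epochs_polish Epochs of the two Adam phases.
#' @param lr_main,lr_polish Learning rates of the two phases.
#' @param include_rf Also fit the random-forest baseline.
#' @param verbose Print progress.
#' @return A list: `comparison` (tibble `model`, `recon_rmse_k`,
#'   `val_rmse_k`), `models`, `mvpf`, `rf`, `dataset`, `val_ids`.
#' @export
benchmark_ordering_trial <- function(seed, n_images = 40L, shape = c(48, 48),
                                     hidden = c(32L, 16L),
                                     n_train_seq = 8000L, n_val_seq = 2000L,
                                     n_train_tile = 3500L, n_val_tile = 1200L,
                                     epochs_main = 40L, epochs_polish = 15L,
                                     lr_main = 1e-2, lr_polish = 2e-3,
                                     include_rf = FALSE, verbose = FALSE) {
  seeds <- derive_seeds(seed, 10L)
  ds <- make_benchmark_dataset(n_images = n_images, shape = shape, seed = seeds[1])
  pool_s <- pool_patches(ds, "sequences", n_train = n_train_seq,
                         n_val = n_val_seq, seed = seeds[2])
  pool_t <- pool_patches(ds, "tiles", n_train = n_train_tile,
                         n_val = n_val_tile, seed = seeds[2])
  val_ids <- pool_s$val_image_ids
  two_phase <- function(variant, pool, batch_size) {
    cfg <- net_config(variant, channels_in = 5, hidden1 = hidden[1],
                      hidden2 = hidden[2], seed = seeds[3])
    m <- train_model(cfg, pool$train, pool$val, epochs = epochs_main,
                     lr = lr_main, batch_size = batch_size,
                     patience = epochs_main, seed = seeds[4], verbose = verbose)
    train_model(m, pool$train, pool$val, epochs = epochs_polish,
                lr = lr_polish, batch_size = batch_size,
                patience = epochs_polish, seed = seeds[5], verbose = verbose)
  }
  if (verbose) message("training FTLSTM")
  models <- list(FTLSTM = two_phase("FTLSTM", pool_s, 256L))
  if (verbose) message("training BFTLSTM")
  models$BFTLSTM <- two_phase("BFTLSTM", pool_s, 256L)
  if (verbose) message("training MFTLSTM")
  models$MFTLSTM <- two_phase("MFTLSTM", pool_t, 96L)

  train_ids <- setdiff(seq_along(ds$items), val_ids)
  px <- lapply(ds$items[train_ids], function(it) pixel_table(it$image, it$clean))
  X <- do.call(rbind, lapply(px, `[[`, "intensities"))
  yv <- unlist(lapply(px, `[[`, "temperatures"))
  keep <- with_seed(seeds[6], sample.int(nrow(X), min(nrow(X), 20000L)))
  mvpf <- suppressWarnings(mvpf_fit(X[keep, , drop = FALSE], yv[keep]))
  rf <- if (include_rf) rf_fit(X[keep, , drop = FALSE], yv[keep],
                               num_trees = 100, seed = seeds[7]) else NULL

  all_models <- c(models, list(MVPF = mvpf))
  if (!is.null(rf)) all_models$RF <- rf
  rows <- lapply(names(all_models), function(nm) {
    rs <- vapply(val_ids, function(id) {
      reconstruct(all_models[[nm]], ds$items[[id]]$image,
                  truth = ds$items[[id]]$clean)$rmse
    }, numeric(1))
    tibble(
      model = nm, recon_rmse_k = mean(rs),
      val_rmse_k = if (nm %in% names(models)) {
        models[[nm]]$lineage$final_val_rmse
      } else NA_real_
    )
  })
  list(comparison = dplyr::bind_rows(rows), models = models, mvpf = mvpf,
       rf = rf, dataset = ds, val_ids = val_ids)
}

#' Reconstruction comparison on held-out images
#'
#' Reconstructs each held-out image with every supplied model and reports the
#' full-image RMSE against the clean ground truth, averaged over images — the
#' protocol behind the architecture comparison (the more directions a network
#' scans, the better it exploits the smoothness that heat diffusion imposes).
#'
#' @param suite A [train_benchmark_suite()] result.
#' @param dataset The `ft_dataset` the suite was trained on (held-out images
#'   are taken from its validation split) or a fresh test dataset.
#' @param items Optional explicit item indices to evaluate.
#' @return A tibble with `model`, `image`, `rmse_k`.
#' @export
reconstruction_comparison <- function(suite, dataset, items = NULL) {
  ids <- items %||% suite$pools$sequences$val_image_ids
  all_models <- c(suite$models, list(MVPF = suite$mvpf, RF = suite$rf))
  all_models <- all_models[!vapply(all_models, is.null, logical(1))]
  rows <- list()
  for (id in ids) {
    it <- dataset$items[[id]]
    for (nm in names(all_models)) {
      res <- reconstruct(all_models[[nm]], it$image, truth = it$clean)
      rows[[length(rows) + 1L]] <- tibble(model = nm, image = id, rmse_k = res$rmse)
    }
  }
  dplyr::bind_rows(rows)
}

#' Extrapolation experiment
#'
#' Evaluates a trained model inside its training temperature window and on
#' scenes spanning a wider window it never saw (rendered through the same
#' frozen calibration, clipping out-of-range counts), reporting the paired
#' RMSEs. Reconstruction of unseen temperatures is expected to degrade.
#'
#' @param models Named list of predictors (`ft_model`, `mvpf_model`,
#'   `rf_model`).
#' @param cal The frozen `calibration_model` of the training conditions.
#' @param train_t_range Temperature window the models were trained on.
#' @param test_t_range Wider window for the extrapolation scenes.
#' @param n_images Test images per window.
#' @param shape Image shape.
#' @param noise_sd Temperature noise (K).
#' @param seed Integer seed.
#' @return A tibble with `model`, `range` (`"in_range"`/`"extended"`),
#'   `rmse_k`, plus the per-image results in the `results` attribute.
#' @export
extrapolation_experiment <- function(models, cal, train_t_range = c(298, 308),
                                     test_t_range = c(298, 312), n_images = 3L,
                                     shape = c(32, 32), noise_sd = 0.1,
                                     seed = 99L) {
  gen_seed <- derive_seeds(seed, 1L)
  ds_in <- make_benchmark_dataset(
    n_images = n_images, shape = shape, t_range = train_t_range,
    noise_sd = noise_sd, seed = gen_seed, cal = cal
  )
  # extended window: the same generator draw over the wider wall-temperature
  # range (identical geometry seeds, so equal ranges give identical scenes);
  # every noisy field is re-rendered through the *frozen* training
  # calibration, clipping counts outside its anchors
  ds_ext <- make_benchmark_dataset(
    n_images = n_images, shape = shape, t_range = test_t_range,
    noise_sd = noise_sd, seed = gen_seed
  )
  for (k in seq_along(ds_ext$items)) {
    ds_ext$items[[k]]$image <- render_image(ds_ext$items[[k]]$noisy, cal,
                                            quantize = TRUE, clip = "clip")
  }
  ds_ext$cal <- cal
  rows <- list()
  for (nm in names(models)) {
    for (rg in c("in_range", "extended")) {
      ds <- if (rg == "in_range") ds_in else ds_ext
      rmses <- vapply(ds$items, function(it) {
        reconstruct(models[[nm]], it$image, truth = it$clean)$rmse
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(model = nm, range = rg,
                                          rmse_k = mean(rmses))
    }
  }
  dplyr::bind_rows(rows)
}

#' Temperature-range sweep over a chip series
#'
#' Reconstructs every scene of a heater sweep with one model and reports the
#' mask-aware RMSE per scene, sorted by the scene's temperature span. Wider
#' spans mean steeper gradients around the heat sources, and reconstruction
#' error grows with them.
#'
#' @param series A rendered [build_chip_series()].
#' @param model A predictor accepted by [reconstruct()].
#' @param channels Channel subset fed to the model; default drops the
#'   620/10 band (the sixth device filter adds little information), the
#'   five-of-six selection rule. Use `channels = NULL` semantics via
#'   `keep_all = TRUE` to retain all six.
#' @param keep_all Retain all channels (default FALSE).
#' @return A tibble with `setting`, `span_k`, `probe_t`, `rmse_k`, sorted by
#'   span; per-scene results in the `results` attribute.
#' @export
range_sweep_experiment <- function(series, model, channels = NULL,
                                   keep_all = FALSE) {
  stopifnot(inherits(series, "chip_series"))
  if (is.null(series$images)) abort("series has no rendered images; pass `cal` to build_chip_series()")
  n_ch <- dim(series$images[[1]]$channels)[3]
  if (is.null(channels)) {
    channels <- if (keep_all) seq_len(n_ch) else default_chip_channels(series$images[[1]])
  }
  # patch-based models only see full-signal patches (inside the channel);
  # pointwise models score every mask pixel
  restrict <- inherits(model, "ft_model") || is.function(model)
  rows <- list(); results <- list()
  for (k in seq_along(series$scenes)) {
    sc <- series$scenes[[k]]
    res <- reconstruct(model, series$images[[k]], truth = sc$field,
                       mask = sc$mask, channels = channels,
                       patch_mask = if (restrict) sc$mask else NULL)
    results[[k]] <- res
    rows[[k]] <- tibble(
      setting = k, span_k = diff(range(sc$field$values)),
      probe_t = sc$probe_t, rmse_k = res$rmse
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$span_k)
  attr(out, "results") <- results
  out
}

#' Pool training patches from a chip series
#'
#' Extracts dense patches from every (masked) chip image against the
#' ground-truth field, holding out one scene (by default the middle setting)
#' for validation. Inputs are the masked images — zero counts outside the
#' channel — while targets cover the whole field, as the chip ground truth is
#' model-derived everywhere.
#'
#' @param series A rendered [build_chip_series()].
#' @param type `"sequences"` or `"tiles"`.
#' @param channels Channel subset; default the five-of-six selection.
#' @param val_scene Index of the held-out scene (default middle setting).
#' @param n_train,n_val Optional patch budgets.
#' @param stride Extraction stride.
#' @param seed Seed for subsampling.
#' @param mask_only Keep only patches whose full footprint lies inside the
#'   channel mask (default TRUE): outside the channel there is no
#'   fluorescence, so zero-signal patches carry no temperature information
#'   and only poison training.
#' @return List with `train` and `val` batches.
#' @export
pool_chip_patches <- function(series, type = c("tiles", "sequences"),
                              channels = NULL, val_scene = NULL,
                              n_train = NULL, n_val = NULL, stride = 1L,
                              seed = 1L, mask_only = TRUE) {
  type <- match.arg(type)
  stopifnot(inherits(series, "chip_series"))
  if (is.null(series$images)) abort("series has no rendered images")
  n_ch <- dim(series$images[[1]]$channels)[3]
  if (is.null(channels)) channels <- default_chip_channels(series$images[[1]])
  if (is.null(val_scene)) val_scene <- ceiling(length(series$scenes) / 2)
  extract <- function(k) {
    img <- series$images[[k]]
    img$channels <- img$channels[, , channels, drop = FALSE]
    img$channel_names <- img$channel_names[channels]
    fld <- series$scenes[[k]]$field
    b <- if (type == "tiles") extract_tiles(img, fld, stride = stride)
         else extract_sequences(img, fld, stride = stride)
    if (mask_only) b <- filter_patches_in_mask(b, series$scenes[[k]]$mask)
    b
  }
  tr <- bind_batches(lapply(setdiff(seq_along(series$scenes), val_scene), extract))
  va <- bind_batches(lapply(val_scene, extract))
  seeds <- derive_seeds(seed, 2L)
  if (!is.null(n_train)) tr <- subsample_batch(tr, n_train, seeds[1])
  if (!is.null(n_val)) va <- subsample_batch(va, n_val, seeds[2])
  list(train = tr, val = va, val_scene = val_scene)
}

# Keep only patches whose footprint is entirely inside the mask.
filter_patches_in_mask <- function(batch, mask) {
  is_tiles <- inherits(batch, "tile_batch")
  n <- nrow(batch$origins)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- if (is_tiles) {
      r <- batch$origins$top_row[i]; cc <- batch$origins$left_col[i]
      all(mask[r:(r + PATCH_LEN - 1L), cc:(cc + PATCH_LEN - 1L)])
    } else {
      r <- batch$origins$row[i]; cc <- batch$origins$start_col[i]
      all(mask[r, cc:(cc + PATCH_LEN - 1L)])
    }
  }
  if (!any(keep)) abort("no patch fits entirely inside the mask")
  idx <- which(keep)
  batch$inputs <- if (is_tiles) batch$inputs[idx, , , , drop = FALSE]
                  else batch$inputs[idx, , , drop = FALSE]
  if (!is.null(batch$targets)) {
    batch$targets <- if (is_tiles) batch$targets[idx, , , drop = FALSE]
                     else batch$targets[idx, , drop = FALSE]
  }
  batch$origins <- batch$origins[idx, ]
  batch
}

#' Fit a pointwise MVPF baseline on a chip series
#'
#' Pools the channel-mask pixels of every scene (intensities against the
#' ground-truth field) and fits the degree-2 multivariate polynomial.
#'
#' @param series A rendered [build_chip_series()].
#' @param channels Channel subset; default the five-of-six selection.
#' @param keep_all Retain all channels.
#' @param max_pixels Subsample cap on training pixels (default 20000).
#' @param seed Seed for the subsample.
#' @return An `mvpf_model`.
#' @export
fit_chip_mvpf <- function(series, channels = NULL, keep_all = FALSE,
                          max_pixels = 20000L, seed = 1L) {
  stopifnot(inherits(series, "chip_series"))
  if (is.null(series$images)) abort("series has no rendered images")
  n_ch <- dim(series$images[[1]]$channels)[3]
  if (is.null(channels)) {
    channels <- if (keep_all) seq_len(n_ch) else default_chip_channels(series$images[[1]])
  }
  tabs <- lapply(seq_along(series$scenes), function(k) {
    sc <- series$scenes[[k]]
    img <- series$images[[k]]
    img$channels <- img$channels[, , channels, drop = FALSE]
    pt <- pixel_table(img, sc$field, sc$mask)
    cbind(pt$intensities, pt$temperatures)
  })
  px <- do.call(rbind, tabs)
  if (nrow(px) > max_pixels) {
    px <- px[with_seed(seed, sample.int(nrow(px), max_pixels)), , drop = FALSE]
  }
  mvpf_fit(px[, -ncol(px), drop = FALSE], px[, ncol(px)])
}

# Five-of-six selection: drop the 620/10 band when present.
default_chip_channels <- function(image) {
  idx <- seq_along(image$channel_names)
  drop <- which(image$channel_names == "bp620w10")
  if (length(drop)) idx[-drop] else idx
}
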