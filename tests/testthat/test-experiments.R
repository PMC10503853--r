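test_that("the benchmark generator produces in-window, reproducible datasets", {
  ds <- make_benchmark_dataset(n_images = 5, shape = c(16, 16), seed = 21)
  expect_length(ds$items, 5L)
  for (it in ds$items) {
    expect_true(all(it$clean$values >= 298 & it$clean$values <= 308))
    expect_identical(dim(it$image$channels), c(16L, 16L, 5L))
    expect_true(isTRUE(it$image$meta$quantized))
  }
  ds2 <- make_benchmark_dataset(n_images = 5, shape = c(16, 16), seed = 21)
  expect_identical(ds$items[[3]]$image$channels, ds2$items[[3]]$image$channels)
  ds3 <- make_benchmark_dataset(n_images = 5, shape = c(16, 16), seed = 22)
  expect_false(identical(ds$items[[3]]$clean$values, ds3$items[[3]]$clean$values))
})

test_that("single-scene spans are a few kelvin while the set covers the window", {
  ds <- make_benchmark_dataset(n_images = 30, shape = c(16, 16), seed = 5,
                               span_range = c(2, 6))
  spans <- vapply(ds$items, function(it) diff(range(it$clean$values)), numeric(1))
  expect_true(all(spans <= 6 + 2 + 1e-9))   # span + boundary wave headroom
  lo <- min(vapply(ds$items, function(it) min(it$clean$values), numeric(1)))
  hi <- max(vapply(ds$items, function(it) max(it$clean$values), numeric(1)))
  expect_lt(lo, 300.5)
  expect_gt(hi, 305.5)
})

test_that("patch pooling splits at the whole-image level with honored budgets", {
  ds <- make_benchmark_dataset(n_images = 10, shape = c(12, 12), seed = 6)
  pool <- pool_patches(ds, "sequences", val_frac = 0.2, n_train = 200,
                       n_val = 80, seed = 7)
  expect_identical(dim(pool$train$inputs)[1], 200L)
  expect_identical(dim(pool$val$inputs)[1], 80L)
  expect_length(pool$val_image_ids, 2L)
  # reproducible split
  pool2 <- pool_patches(ds, "sequences", val_frac = 0.2, n_train = 200,
                        n_val = 80, seed = 7)
  expect_identical(pool$val_image_ids, pool2$val_image_ids)
  expect_identical(pool$train$inputs, pool2$train$inputs)
})

test_that("the training suite returns trained models and baselines", {
  ds <- make_benchmark_dataset(n_images = 8, shape = c(12, 12), seed = 8)
  suite <- suppressWarnings(train_benchmark_suite(ds, hidden = c(6, 4), epochs = 2,
                                 n_train = 200, n_val = 80, seed = 9,
                                 variants = c("FTLSTM"), rf_num_trees = 10))
  expect_named(suite$models, "FTLSTM")
  expect_s3_class(suite$mvpf, "mvpf_model")
  expect_s3_class(suite$rf, "rf_model")
  expect_identical(nrow(suite$summary), 1L)
  comp <- reconstruction_comparison(suite, ds)
  expect_true(all(c("FTLSTM", "MVPF", "RF") %in% comp$model))
  expect_true(all(is.finite(comp$rmse_k)))
})

test_that("the chip range sweep table is span-sorted and mask-aware", {
  series <- build_chip_series(heater_dts_k = c(2, 12, 30),
                              base_spec = chip_field_spec(shape = c(24, 32)),
                              seed = 10, noise_sd = 0)
  cal <- fit_probe_calibration(series)
  series <- build_chip_series(heater_dts_k = c(2, 12, 30),
                              base_spec = chip_field_spec(shape = c(24, 32)),
                              cal = cal, seed = 10, noise_sd = 0)
  mv <- suppressWarnings(fit_chip_mvpf(series, max_pixels = 5000))
  tab <- range_sweep_experiment(series, mv)
  expect_identical(nrow(tab), 3L)
  expect_true(!is.unsorted(tab$span_k))
  # identical scenes give identical RMSE
  series2 <- series
  series2$scenes <- series$scenes[c(1, 1)]
  series2$images <- series$images[c(1, 1)]
  series2$settings <- series$settings[c(1, 1), ]
  tab2 <- range_sweep_experiment(series2, mv)
  expect_equal(tab2$rmse_k[1], tab2$rmse_k[2], tolerance = 1e-12)
})

test_that("a perfect test double gives zero RMSE across a single-span sweep", {
  series <- build_chip_series(heater_dts_k = c(5, 5.00001),
                              base_spec = chip_field_spec(shape = c(24, 32)),
                              seed = 11, noise_sd = 0)
  cal <- fit_probe_calibration(
    build_chip_series(heater_dts_k = c(2, 5, 9),
                      base_spec = chip_field_spec(shape = c(24, 32)),
                      seed = 11, noise_sd = 0)
  )
  series <- build_chip_series(heater_dts_k = c(5, 5.00001),
                              base_spec = chip_field_spec(shape = c(24, 32)),
                              cal = cal, seed = 11, noise_sd = 0)
  rmses <- vapply(seq_along(series$scenes), function(k) {
    truth <- series$scenes[[k]]$field
    oracle <- function(batch) {
      preds <- matrix(0, nrow(batch$origins), 5)
      for (p in 1:5) {
        preds[, p] <- truth$values[cbind(batch$origins$row,
                                         batch$origins$start_col + p - 1)]
      }
      preds
    }
    reconstruct(oracle, series$images[[k]], truth = truth,
                mask = series$scenes[[k]]$mask)$rmse
  }, numeric(1))
  expect_true(all(rmses < 1e-12))
})
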