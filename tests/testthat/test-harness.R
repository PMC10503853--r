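test_that("rmse matches closed forms and validates inputs", {
  a <- temperature_field(matrix(300, 4, 4))
  expect_identical(rmse(a, a), 0)
  b <- temperature_field(matrix(300.3, 4, 4))
  expect_equal(rmse(a, b), 0.3, tolerance = 1e-12)
  c <- temperature_field(matrix(300 + c(0.1, -0.1, 0.1, -0.1), 2, 2))
  expect_equal(rmse(a$values[1:2, 1:2], c$values), 0.1, tolerance = 1e-12)
  expect_error(rmse(a, temperature_field(matrix(300, 3, 3))), "shape")
  expect_error(rmse(a, b, matrix(FALSE, 4, 4)), "empty mask")
})

test_that("rmse obeys the triangle inequality on shared masks", {
  set.seed(5)
  for (rep in 1:5) {
    a <- rand_field(6, 6, seed = rep)
    b <- rand_field(6, 6, seed = rep + 10)
    c <- rand_field(6, 6, seed = rep + 20)
    mask <- matrix(runif(36) > 0.3, 6, 6)
    if (!any(mask)) mask[1, 1] <- TRUE
    expect_lte(rmse(a, c, mask), rmse(a, b, mask) + rmse(b, c, mask) + 1e-12)
  }
})

test_that("gradient norm map matches closed forms", {
  u <- temperature_field(matrix(305, 6, 8))
  expect_true(all(gradient_norm_map(u) == 0))
  ramp <- temperature_field(matrix(0.5 * (seq_len(10) - 1), 6, 10, byrow = TRUE))
  g <- gradient_norm_map(ramp)
  expect_equal(g[3, 5], 0.5, tolerance = 1e-12)
  expect_equal(g[1, 1], 0.5, tolerance = 1e-12)  # one-sided at borders
  xy <- outer(0.4 * seq_len(8), 0.3 * seq_len(9), "+")
  g2 <- gradient_norm_map(temperature_field(xy))
  expect_equal(g2[4, 5], 0.5, tolerance = 1e-12)  # sqrt(0.3^2 + 0.4^2)
  # pitch scales the units
  g3 <- gradient_norm_map(temperature_field(xy, pitch_um = 2))
  expect_equal(g3[4, 5], 0.25, tolerance = 1e-12)
})

test_that("gradient norm is invariant under constant shifts", {
  f <- rand_field(7, 7, seed = 31)
  shifted <- temperature_field(f$values + 5, pitch_um = f$pitch_um)
  expect_equal(gradient_norm_map(f), gradient_norm_map(shifted), tolerance = 1e-12)
})

test_that("error-gradient analysis reports rank correlations and edge cases", {
  truth <- rand_field(10, 10, seed = 7)
  g <- gradient_norm_map(truth)
  # |error| equal to the gradient norm: perfect monotone association
  pred <- temperature_field(truth$values + g, pitch_um = truth$pitch_um)
  res <- reconstruction_result(pred, truth)
  an <- error_gradient_analysis(res)
  expect_true(an$correlation_defined)
  expect_equal(an$spearman_rho, 1, tolerance = 1e-12)
  expect_equal(an$mean_gradient, mean(g), tolerance = 1e-12)
  expect_equal(an$max_gradient, max(g), tolerance = 1e-12)
  # shuffled errors: association near zero at n = 1e4
  set.seed(8)
  big <- temperature_field(matrix(cumsum(rnorm(1e4, 0, 0.1)), 100, 100))
  gb <- gradient_norm_map(big)
  shuffled <- temperature_field(big$values + sample(as.vector(gb)))
  an2 <- error_gradient_analysis(reconstruction_result(shuffled, big))
  expect_lt(abs(an2$spearman_rho), 0.05)
  # constant error map: undefined, flagged, no crash
  an3 <- error_gradient_analysis(
    reconstruction_result(temperature_field(truth$values + 0.5), truth)
  )
  expect_false(an3$correlation_defined)
  expect_true(is.na(an3$spearman_rho))
})

test_that("training runs, descends on a learnable toy task, and reproduces", {
  ds <- make_benchmark_dataset(n_images = 6, shape = c(12, 12), seed = 3)
  pool <- pool_patches(ds, "sequences", n_train = 300, n_val = 100, seed = 4)
  cfg <- net_config("FTLSTM", channels_in = 5, hidden1 = 8, hidden2 = 4, seed = 5)
  m1 <- train_model(cfg, pool$train, pool$val, epochs = 1, seed = 6)
  expect_length(m1$lineage$train_loss, 1L)
  m <- train_model(cfg, pool$train, pool$val, epochs = 25, lr = 1e-2,
                   patience = 25, seed = 6)
  expect_lt(tail(m$lineage$train_loss, 1), m$lineage$train_loss[1])
  m2 <- train_model(cfg, pool$train, pool$val, epochs = 25, lr = 1e-2,
                    patience = 25, seed = 6)
  expect_identical(m$lineage$val_rmse, m2$lineage$val_rmse)
  # tidy/glance views of the lineage
  td <- tidy(m)
  expect_identical(nrow(td), m$lineage$epochs_run)
  expect_identical(glance(m)$variant, "FTLSTM")
})

test_that("training rejects mismatched batch types", {
  ds <- make_benchmark_dataset(n_images = 3, shape = c(10, 10), seed = 3)
  seqs <- pool_patches(ds, "sequences", n_train = 50, n_val = 20, seed = 1)
  tiles <- pool_patches(ds, "tiles", n_train = 50, n_val = 20, seed = 1)
  expect_error(train_model(net_config("MFTLSTM", channels_in = 5), seqs$train),
               "tile")
  expect_error(train_model(net_config("FTLSTM", channels_in = 5), tiles$train),
               "sequence")
})

test_that("a test double wired to the truth reconstructs with zero RMSE", {
  cal <- fix_cal5()
  f <- fix_pipe_field()
  img <- render_image(f, cal)
  oracle <- function(batch) {
    preds <- matrix(0, nrow(batch$origins), 5)
    for (k in 1:5) {
      preds[, k] <- f$values[cbind(batch$origins$row, batch$origins$start_col + k - 1)]
    }
    preds
  }
  res <- reconstruct(oracle, img, truth = f)
  expect_equal(res$rmse, 0, tolerance = 1e-12)
  expect_false(any(res$predicted$meta$coverage == 0))
})

test_that("reconstruction covers every pixel for any image at least 5x5", {
  cal <- fix_cal5()
  m <- init_model(net_config("MFTLSTM", channels_in = 5, hidden1 = 4, hidden2 = 3))
  for (shape in list(c(5, 5), c(5, 9), c(8, 6))) {
    f <- temperature_field(matrix(runif(prod(shape), 299, 307), shape[1], shape[2]))
    res <- reconstruct(m, render_image(f, cal), truth = f)
    expect_false(any(res$predicted$meta$coverage == 0))
  }
})

test_that("reconstruction result invariants hold and tidiers work", {
  cal <- fix_cal5()
  f <- fix_pipe_field()
  img <- render_image(f, cal)
  pred <- pointwise_invert(img, cal)
  res <- reconstruction_result(pred, f)
  expect_equal(res$rmse^2, mean(res$error_map^2), tolerance = 1e-12)
  td <- tidy(res)
  expect_identical(nrow(td), as.integer(prod(dim(f$values))))
  expect_equal(sqrt(mean(td$error_k^2)), res$rmse, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(gl$rmse_k, res$rmse)
  # masked variant
  mask <- matrix(FALSE, 24, 24); mask[5:10, 5:10] <- TRUE
  resm <- reconstruction_result(pred, f, mask)
  expect_equal(resm$rmse^2, mean(resm$error_map[mask]^2), tolerance = 1e-12)
})

test_that("range-equal extrapolation experiment returns coinciding RMSEs", {
  cal <- fix_cal5()
  f <- fix_pipe_field()
  img <- render_image(f, cal)
  pt <- fluorotherm:::pixel_table(img, f)
  mv <- suppressWarnings(mvpf_fit(pt$intensities, pt$temperatures))
  tab <- extrapolation_experiment(list(MVPF = mv), cal,
                                  train_t_range = c(298, 308),
                                  test_t_range = c(298, 308),
                                  n_images = 2, shape = c(16, 16), seed = 9)
  expect_equal(tab$rmse_k[tab$range == "in_range"],
               tab$rmse_k[tab$range == "extended"], tolerance = 1e-12)
})
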