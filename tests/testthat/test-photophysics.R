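test_that("emission spectrum peaks where the model says it should", {
  qd <- fix_qd()
  wl <- seq(500, 750, by = 0.1)
  s_ref <- emission_spectrum(qd, qd$t_ref, wl)
  expect_equal(s_ref$wavelength_nm[which.max(s_ref$intensity)], 620, tolerance = 0.11)
  # +10 K shifts the argmax by shift coefficient * 10 = 1 nm
  s_hot <- emission_spectrum(qd, qd$t_ref + 10, wl)
  expect_equal(s_hot$wavelength_nm[which.max(s_hot$intensity)], 621, tolerance = 0.11)
  expect_true(all(s_hot$intensity >= 0))
  # quenching reduces total area
  area <- function(s) sum(diff(s$wavelength_nm) * (head(s$intensity, -1) + tail(s$intensity, -1)) / 2)
  expect_lt(area(s_hot), area(s_ref))
  expect_error(emission_spectrum(qd, 1000), "validity")
})

test_that("band integration is an identity for an all-pass filter and additive", {
  qd <- fix_qd()
  wl <- seq(480, 780, by = 0.25)
  sp <- emission_spectrum(qd, 300, wl)
  total <- sum(diff(wl) * (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  allpass <- filter_bank(tibble::tibble(
    name = "all", kind = "band-pass", center_nm = 630, fwhm_nm = 300,
    edge_softness_nm = 0
  ))
  expect_equal(unname(band_integrate(sp, allpass)), total, tolerance = 1e-12)
  # two sharp bands tiling the support sum to the full integral (quadrature
  # of a cut indicator carries an O(grid step) edge term)
  halves <- filter_bank(tibble::tibble(
    name = c("lo", "hi"), kind = "band-pass",
    center_nm = c(555, 705), fwhm_nm = c(150.5, 149.5), edge_softness_nm = 0
  ))
  two <- band_integrate(sp, halves)
  expect_equal(sum(two), total, tolerance = 2e-3)
  # homogeneity of degree 1
  sp2 <- sp; sp2$intensity <- 3 * sp$intensity
  expect_equal(unname(band_integrate(sp2, allpass)), 3 * total, tolerance = 1e-9)
})

test_that("device bank has soft overlapping edges, benchmark bank sharp ones", {
  b5 <- fix_bank5()
  wl <- seq(480, 780, by = 0.5)
  tr <- vapply(seq_len(5), function(b) {
    fluorotherm:::band_transmission(b5$bands[b, ], wl)
  }, numeric(length(wl)))
  expect_true(all(tr %in% c(0, 1)))              # ideal cut-offs
  expect_true(all(rowSums(tr) <= 1 + 1e-12))     # sharp bands do not overlap
  b6 <- filter_bank_device6()
  tr6 <- vapply(seq_len(6), function(b) {
    fluorotherm:::band_transmission(b6$bands[b, ], wl)
  }, numeric(length(wl)))
  expect_true(all(tr6 >= 0 & tr6 <= 1))
  # neighbouring band-passes genuinely overlap (650/40 with 660/10)
  both <- tr6[, 2] > 0.1 & tr6[, 3] > 0.1
  expect_gt(sum(both), 0)
})

test_that("calibration anchors scale the extreme intensities to exactly 0 and 65535", {
  qd <- fix_qd()
  temps <- seq(298, 308, by = 0.5)
  bi <- band_intensity_table(qd, temps, fix_bank5())
  cal <- fit_calibration(temps, bi)
  sc <- scale_counts(cal, bi)
  expect_identical(min(sc), 0)
  expect_identical(max(sc), 65535)
})

test_that("a quadratic generator is recovered exactly and 3 points interpolate", {
  temps <- c(298, 300, 303, 305, 308)
  truth <- cbind(2 * temps^2 - 1000 * temps + 130000,
                 -1 * temps^2 + 700 * temps - 80000)
  cal <- fit_calibration(temps, truth)
  sc <- scale_counts(cal, truth)
  pred <- vapply(1:2, function(j) fluorotherm:::cal_predict(cal, temps, j),
                 numeric(length(temps)))
  expect_lt(max(abs(pred - sc)), 1e-6)
  # exactly three distinct temperatures: the quadratic interpolates them
  t3 <- c(298, 303, 308)
  y3 <- cbind(t3^2 - 500 * t3, 3 * t3 + 7)
  cal3 <- fit_calibration(t3, y3)
  sc3 <- scale_counts(cal3, y3)
  pred3 <- vapply(1:2, function(j) fluorotherm:::cal_predict(cal3, t3, j),
                  numeric(3))
  expect_lt(max(abs(pred3 - sc3)), 1e-6)
  expect_error(fit_calibration(c(300, 300, 301), truth[1:3, ]), "3 distinct")
})

test_that("degenerate constant channels are flagged, not fatal", {
  temps <- seq(298, 308, by = 1)
  bi <- cbind(temps * 10, rep(500, length(temps)))
  expect_warning(cal <- fit_calibration(temps, bi), "degenerate")
  expect_true(cal$coefficients$degenerate[2])
  expect_false(cal$coefficients$monotone[2])
})

test_that("rendering a uniform field gives uniform channels with the right count", {
  cal <- fix_cal5()
  f <- temperature_field(matrix(303, 6, 7))
  img <- render_image(f, cal)
  expect_identical(dim(img$channels)[3], 5L)
  for (j in 1:5) expect_equal(length(unique(as.vector(img$channels[, , j]))), 1L)
})

test_that("rendering is monotone channelwise where the calibration is monotone", {
  cal <- fix_cal5()
  t1 <- temperature_field(matrix(300, 2, 2))
  t2 <- temperature_field(matrix(304, 2, 2))
  i1 <- render_image(t1, cal, quantize = FALSE)
  i2 <- render_image(t2, cal, quantize = FALSE)
  for (j in which(cal$coefficients$monotone)) {
    d <- i2$channels[1, 1, j] - i1$channels[1, 1, j]
    slope_sign <- sign(2 * cal$coefficients$a[j] * 302 + cal$coefficients$b[j])
    expect_true(sign(d) == slope_sign)
  }
})

test_that("render -> pointwise invert is the identity without quantization", {
  cal <- fix_cal5()
  f <- fix_pipe_field()
  img <- render_image(f, cal, quantize = FALSE)
  back <- pointwise_invert(img, cal)
  expect_lt(max(abs(back$values - f$values)), 1e-6)
})

test_that("quantized inversion error obeys the slope propagation bound", {
  cal <- fix_cal5()
  f <- fix_pipe_field()
  back <- pointwise_invert(render_image(f, cal, quantize = TRUE), cal)
  tg <- seq(298, 308, by = 0.01)
  min_slope <- min(vapply(which(cal$coefficients$monotone), function(j) {
    min(abs(2 * cal$coefficients$a[j] * tg + cal$coefficients$b[j]))
  }, numeric(1)))
  expect_lt(max(abs(back$values - f$values)), 1 / min_slope)
})

test_that("inversion through noise recovers the clean field at about the noise level", {
  cal <- fix_cal5()
  f <- temperature_field(matrix(303, 60, 60), meta = list(t_range = c(298, 308)))
  n_mc <- 5
  rs <- vapply(seq_len(n_mc), function(k) {
    noisy <- add_temperature_noise(f, 0.1, seed = 100 + k)
    rmse(pointwise_invert(render_image(noisy, cal, clip = "clip"), cal), f)
  }, numeric(1))
  expect_equal(mean(rs), 0.1, tolerance = 0.2 * 0.1)
})

test_that("out-of-range rendering errors by default and clips on request", {
  cal <- fix_cal5()
  f <- temperature_field(matrix(c(310, 303, 303, 303), 2, 2))
  expect_error(render_image(f, cal), "outside calibration range")
  img <- render_image(f, cal, clip = "clip")
  expect_true(all(img$channels >= 0 & img$channels <= 65535))
  expect_gt(img$meta$clip_fraction, 0)
})

test_that("pixel binning averages blocks with round-half-even requantization", {
  img <- fluorescent_image(matrix(1:16, 4, 4, byrow = TRUE),
                           meta = list(quantized = TRUE))
  out <- bin_pixels(img, 4)
  expect_identical(dim(out$channels)[1:2], c(1L, 1L))
  expect_identical(as.vector(out$channels), 8)   # mean 8.5 rounds half-even to 8
  expect_identical(bin_pixels(img, 1), img)
  expect_error(bin_pixels(img, 0), "positive")
  # trailing remainder is cropped with a warning
  img5 <- fluorescent_image(matrix(0, 5, 5))
  expect_warning(out5 <- bin_pixels(img5, 2), "cropping")
  expect_identical(dim(out5$channels)[1:2], c(2L, 2L))
})

test_that("binning commutes with rendering a blockwise-constant field", {
  cal <- fix_cal5()
  blocks <- matrix(c(300, 302, 304, 306), 2, 2)
  f_big <- temperature_field(blocks[rep(1:2, each = 2), rep(1:2, each = 2)])
  binned_then <- bin_pixels(render_image(f_big, cal, quantize = FALSE), 2,
                            quantize = FALSE)
  rendered_small <- render_image(temperature_field(blocks), cal, quantize = FALSE)
  expect_equal(binned_then$channels, rendered_small$channels, tolerance = 1e-9)
})

test_that("spectral tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  wl <- seq(600, 640, by = 2)
  tab <- data.frame(wavelength_nm = wl, T298 = dnorm(wl, 620, 10),
                    T308 = dnorm(wl, 621, 10))
  write.csv(tab, path, row.names = FALSE)
  st <- read_spectral_table(path)
  expect_equal(st$temperatures, c(298, 308))
  expect_equal(st$intensity[, 1], tab$T298)
})
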