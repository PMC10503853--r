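test_that("pipe field matches the closed-form annulus conduction profile", {
  # odd grid so the centre falls on a pixel and radii are exact integers
  spec <- field_spec("pipe_cross_section", shape = c(101, 101),
                     t_range = c(298, 308), r_inner_px = 10, r_outer_px = 40,
                     t_inner = 308, t_outer = 298, center_px = c(51, 51))
  f <- generate_pipe_field(spec)
  # oracle: direct formula at every annulus pixel
  ctr <- c(51, 51)
  for (px in list(c(51, 71), c(51, 31), c(71, 51), c(39, 67))) {
    r <- sqrt(sum((px - ctr)^2))
    expected <- if (r <= 10) 308 else if (r >= 40) 298 else {
      308 + (298 - 308) * log(r / 10) / log(40 / 10)
    }
    expect_equal(f$values[px[1], px[2]], expected, tolerance = 1e-12)
  }
  # spot value from the closed form: r = 20 -> 308 - 10*ln2/ln4 = 303
  expect_equal(f$values[51, 71], 303, tolerance = 1e-9)
  # whole-annulus agreement with a vectorized oracle
  ry <- matrix(seq_len(101) - 51, 101, 101)
  rx <- t(ry)
  r <- sqrt(rx^2 + ry^2)
  oracle <- matrix(298, 101, 101)
  oracle[r <= 10] <- 308
  ann <- r > 10 & r < 40
  oracle[ann] <- 308 + (298 - 308) * log(r[ann] / 10) / log(40 / 10)
  expect_lt(max(abs(f$values - oracle)), 1e-9)
})

test_that("constant Dirichlet data forces a constant pipe field", {
  spec <- field_spec("pipe_cross_section", shape = c(20, 20),
                     t_range = c(298, 308), r_inner_px = 4, r_outer_px = 8,
                     t_inner = 300, t_outer = 300)
  f <- generate_pipe_field(spec)
  expect_true(all(f$values == 300))
})

test_that("pipe field respects the declared window and rejects bad geometry", {
  f <- generate_pipe_field(dataset1_field_spec())
  expect_true(all(f$values >= 298 & f$values <= 308))
  bad <- field_spec("pipe_cross_section", shape = c(20, 20), t_range = c(298, 308),
                    r_inner_px = 9, r_outer_px = 5, t_inner = 308, t_outer = 298)
  expect_error(generate_pipe_field(bad), "geometry")
  out <- field_spec("pipe_cross_section", shape = c(20, 20), t_range = c(298, 308),
                    r_inner_px = 4, r_outer_px = 8, t_inner = 320, t_outer = 298)
  expect_error(generate_pipe_field(out), "t_range")
})

test_that("boundary wave modulates the top and bottom edges periodically", {
  base <- field_spec("pipe_cross_section", shape = c(30, 32), t_range = c(290, 316),
                     r_inner_px = 5, r_outer_px = 12, t_inner = 308, t_outer = 300)
  waved <- base
  waved$boundary_wave <- list(amplitude_k = 1, period_px = 16)
  f0 <- generate_pipe_field(base)
  f1 <- generate_pipe_field(waved)
  delta <- f1$values[1, ] - f0$values[1, ]
  expect_equal(delta, sin(2 * pi * seq_len(32) / 16), tolerance = 1e-9)
  # interior far from the edges is untouched
  expect_equal(f1$values[15, ], f0$values[15, ])
})

test_that("steady solve with uniform Dirichlet edges returns a uniform field", {
  spec <- field_spec("fd_poisson", shape = c(12, 15), t_range = c(290, 380),
                     edges = list(left = 330, right = 330, top = 330, bottom = 330))
  f <- solve_steady_field(spec)
  expect_lt(max(abs(f$values - 330)), 1e-8)
})

test_that("steady solve reproduces the 1-D conduction ramp with insulated sides", {
  spec <- field_spec("fd_poisson", shape = c(20, 30), t_range = c(290, 380),
                     edges = list(left = 290, right = 380,
                                  top = "insulated", bottom = "insulated"))
  f <- solve_steady_field(spec)
  oracle <- matrix(seq(290, 380, length.out = 30), 20, 30, byrow = TRUE)
  expect_lt(max(abs(f$values - oracle)), 1e-4)
})

test_that("steady solve satisfies the discrete Laplace residual everywhere", {
  spec <- field_spec("fd_poisson", shape = c(25, 35), t_range = c(290, 380),
                     edges = list(left = 293, right = 300, top = 295, bottom = 310),
                     sources = list(list(kind = "vline", index = 12, from = 6,
                                         to = 18, t = 360)))
  f <- solve_steady_field(spec, tol = 1e-6)
  v <- f$values
  # residual at interior pixels that are not the heater line
  for (i in 2:24) for (j in 2:34) {
    if (j == 12 && i >= 6 && i <= 18) next
    res <- abs(4 * v[i, j] - v[i - 1, j] - v[i + 1, j] - v[i, j - 1] - v[i, j + 1])
    expect_lt(res, 1e-6)
  }
  expect_true(all(v >= 290 & v <= 380))
})

test_that("heater temperature outside the envelope is rejected", {
  spec <- field_spec("fd_poisson", shape = c(10, 10), t_range = c(290, 380),
                     edges = list(left = 293, right = 293, top = 293, bottom = 293),
                     sources = list(list(kind = "vline", index = 5, from = 3,
                                         to = 7, t = 400)))
  expect_error(solve_steady_field(spec), "t_range")
})

test_that("temperature noise is Gaussian with the requested spread", {
  f <- temperature_field(matrix(303, 400, 400))
  g <- add_temperature_noise(f, 0.1, seed = 42)
  d <- g$values - f$values
  expect_equal(sd(d), 0.1, tolerance = 0.01)
  expect_lt(abs(mean(d)), 5 * 0.1 / sqrt(length(d)))
  # distribution shape: KS against the normal the noise claims to be
  ks <- suppressWarnings(ks.test(as.vector(d) / 0.1, "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("noise is deterministic per seed and degenerate at sigma zero", {
  f <- fix_pipe_field()
  a <- add_temperature_noise(f, 0.1, seed = 7)
  b <- add_temperature_noise(f, 0.1, seed = 7)
  c <- add_temperature_noise(f, 0.1, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_identical(add_temperature_noise(f, 0, seed = 1)$values, f$values)
  expect_error(add_temperature_noise(f, -0.1, seed = 1), "non-negative")
})

test_that("noise does not perturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(add_temperature_noise(fix_pipe_field(), 0.1, seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})
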