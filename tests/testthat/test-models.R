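# Plain-loop LSTM trace: the independent oracle for the recurrent cores.
# Scalar-level implementation of the standard gated update, no shared code
# with the package's batched version (gate blocks ordered i, f, o, g).
oracle_lstm <- function(Wx, Wh, b, xs) {
  H <- ncol(Wh) / 4
  h <- numeric(H); cc <- numeric(H)
  sig <- function(z) 1 / (1 + exp(-z))
  out <- matrix(0, length(xs), H)
  for (t in seq_along(xs)) {
    z <- as.numeric(xs[[t]] %*% Wx + h %*% Wh + b)
    gi <- sig(z[1:H]); gf <- sig(z[(H + 1):(2 * H)])
    go <- sig(z[(2 * H + 1):(3 * H)]); gc <- tanh(z[(3 * H + 1):(4 * H)])
    cc <- gf * cc + gi * gc
    h <- go * tanh(cc)
    out[t, ] <- h
  }
  out
}

tiny_batch <- function(n = 3, ch = 2, seed = 1) {
  set.seed(seed)
  img <- fluorescent_image(array(runif(6 * 9 * ch, 0, 65535), c(6, 9, ch)))
  extract_sequences(img)
}

tiny_tiles <- function(ch = 2, seed = 1) {
  set.seed(seed)
  img <- fluorescent_image(array(runif(7 * 7 * ch, 0, 65535), c(7, 7, ch)))
  extract_tiles(img)
}

test_that("parameter counts match the closed-form gated-recurrent formula", {
  # 4*(in+H+1)*H per layer, head H2+1; reference config gives 8,226,869
  expect_identical(count_parameters(net_config("FTLSTM", channels_in = 5)),
                   8226869L)
  set.seed(2)
  for (rep in 1:5) {
    C <- sample(2:6, 1); h1 <- sample(4:40, 1); h2 <- sample(3:30, 1)
    closed <- function(n_in, h) 4L * (n_in + h + 1L) * h
    core <- closed(C, h1) + closed(h1, h2)
    cfg_f <- net_config("FTLSTM", channels_in = C, hidden1 = h1, hidden2 = h2)
    expect_identical(count_parameters(cfg_f), core + h2 + 1L)
    expect_identical(count_parameters(init_model(cfg_f)), core + h2 + 1L)
    cfg_b <- net_config("BFTLSTM", channels_in = C, hidden1 = h1, hidden2 = h2)
    expect_identical(count_parameters(cfg_b), 2L * core + h2 + 1L)
    expect_identical(count_parameters(init_model(cfg_b)), 2L * core + h2 + 1L)
    cfg_m <- net_config("MFTLSTM", channels_in = C, hidden1 = h1, hidden2 = h2)
    expect_identical(count_parameters(cfg_m), 4L * core + h2 + 1L)
    expect_identical(count_parameters(init_model(cfg_m)), 4L * core + h2 + 1L)
  }
})

test_that("forward passes satisfy their shape contracts", {
  b <- tiny_batch()
  m_f <- init_model(net_config("FTLSTM", channels_in = 2, hidden1 = 6, hidden2 = 4))
  expect_identical(dim(ftlstm_forward(m_f, b)), c(30L, 5L))
  m_b <- init_model(net_config("BFTLSTM", channels_in = 2, hidden1 = 6, hidden2 = 4))
  expect_identical(dim(bftlstm_forward(m_b, b)), c(30L, 5L))
  bt <- tiny_tiles()
  m_m <- init_model(net_config("MFTLSTM", channels_in = 2, hidden1 = 6, hidden2 = 4))
  expect_identical(dim(mftlstm_forward(m_m, bt)), c(9L, 5L, 5L))
  # channel mismatch is caught
  b3 <- tiny_batch(ch = 3)
  expect_error(ftlstm_forward(m_f, b3), "channels")
})

test_that("the one-directional core agrees with a scalar-loop oracle", {
  cfg <- net_config("FTLSTM", channels_in = 2, hidden1 = 3, hidden2 = 2, seed = 4)
  m <- init_model(cfg)
  b <- tiny_batch(seed = 11)
  y <- ftlstm_forward(m, b)
  # trace sequence 7 by hand through both layers and the head
  n <- 7
  xs <- lapply(1:5, function(t) b$inputs[n, t, ])
  h1 <- oracle_lstm(m$params$core$l1$Wx, m$params$core$l1$Wh, m$params$core$l1$b, xs)
  h2 <- oracle_lstm(m$params$core$l2$Wx, m$params$core$l2$Wh, m$params$core$l2$b,
                    lapply(1:5, function(t) h1[t, ]))
  y_oracle <- as.numeric(h2 %*% m$params$head$w + m$params$head$b)
  expect_equal(unname(y[n, ]),
               y_oracle * m$norm$t_sd + m$norm$t_mean, tolerance = 1e-12)
})

test_that("bidirectional fusion aligns the reverse scan by source position", {
  cfg <- net_config("BFTLSTM", channels_in = 2, hidden1 = 3, hidden2 = 2, seed = 5)
  m <- init_model(cfg)
  b <- tiny_batch(seed = 12)
  y <- bftlstm_forward(m, b)
  n <- 4
  xs <- lapply(1:5, function(t) b$inputs[n, t, ])
  run_core <- function(core, xs) {
    h1 <- oracle_lstm(core$l1$Wx, core$l1$Wh, core$l1$b, xs)
    oracle_lstm(core$l2$Wx, core$l2$Wh, core$l2$b, lapply(1:5, function(t) h1[t, ]))
  }
  fwd <- run_core(m$params$fwd, xs)
  rev_scan <- run_core(m$params$rev, xs[5:1])
  fused <- fwd + rev_scan[5:1, ]   # position k pairs with reverse step 6-k
  y_oracle <- as.numeric(fused %*% m$params$head$w + m$params$head$b)
  expect_equal(unname(y[n, ]), y_oracle * m$norm$t_sd + m$norm$t_mean,
               tolerance = 1e-12)
})

test_that("multi-directional fusion indexes row and column scans by source pixel", {
  cfg <- net_config("MFTLSTM", channels_in = 2, hidden1 = 3, hidden2 = 2, seed = 6)
  m <- init_model(cfg)
  bt <- tiny_tiles(seed = 13)
  y <- mftlstm_forward(m, bt)
  n <- 5
  tile <- bt$inputs[n, , , ]
  run_core <- function(core, xs) {
    h1 <- oracle_lstm(core$l1$Wx, core$l1$Wh, core$l1$b, xs)
    oracle_lstm(core$l2$Wx, core$l2$Wh, core$l2$b, lapply(1:5, function(t) h1[t, ]))
  }
  bidir <- function(fwd, rev, xs) {
    run_core(fwd, xs) + run_core(rev, xs[5:1])[5:1, , drop = FALSE]
  }
  y_oracle <- matrix(0, 5, 5)
  for (i in 1:5) {
    row_feat <- bidir(m$params$row_fwd, m$params$row_rev,
                      lapply(1:5, function(t) tile[i, t, ]))
    for (j in 1:5) {
      col_feat <- bidir(m$params$col_fwd, m$params$col_rev,
                        lapply(1:5, function(t) tile[t, j, ]))
      fused <- row_feat[j, ] + col_feat[i, ]
      y_oracle[i, j] <- sum(fused * m$params$head$w) + m$params$head$b
    }
  }
  expect_equal(y[n, , ], y_oracle * m$norm$t_sd + m$norm$t_mean, tolerance = 1e-12)
})

test_that("evaluation forward passes are deterministic and batch-order invariant", {
  b <- tiny_batch(seed = 20)
  m <- init_model(net_config("BFTLSTM", channels_in = 2, hidden1 = 5, hidden2 = 3,
                             dropout = 0.5))
  y1 <- bftlstm_forward(m, b)
  y2 <- bftlstm_forward(m, b)   # dropout must not fire in evaluation
  expect_identical(y1, y2)
  perm <- sample(nrow(y1))
  bp <- b
  bp$inputs <- b$inputs[perm, , , drop = FALSE]
  expect_equal(bftlstm_forward(m, bp), y1[perm, ], tolerance = 1e-12)
})

test_that("weight-tied bidirectional model maps palindromes to palindromes", {
  m <- init_model(net_config("BFTLSTM", channels_in = 2, hidden1 = 6, hidden2 = 4,
                             tie_directions = TRUE, seed = 3))
  set.seed(30)
  half <- array(runif(4 * 2 * 2), c(4, 2, 2))
  pal <- array(0, c(4, 5, 2))
  pal[, 1:2, ] <- half
  pal[, 3, ] <- runif(8)
  pal[, 4:5, ] <- half[, 2:1, , drop = FALSE]
  batch <- structure(list(inputs = pal, targets = NULL,
                          origins = tibble::tibble(row = 1:4, start_col = 1L),
                          image_shape = c(4L, 10L), target_center = 0),
                     class = "sequence_batch")
  y <- bftlstm_forward(m, batch)
  expect_equal(y, y[, 5:1], tolerance = 1e-12)
})

test_that("weight-tied multi-directional model commutes with tile transposition", {
  m <- init_model(net_config("MFTLSTM", channels_in = 2, hidden1 = 6, hidden2 = 4,
                             tie_directions = FALSE, tie_orientations = TRUE,
                             seed = 8))
  bt <- tiny_tiles(seed = 14)
  y <- mftlstm_forward(m, bt)
  btt <- bt
  btt$inputs <- aperm(bt$inputs, c(1, 3, 2, 4))
  yt <- mftlstm_forward(m, btt)
  for (n in seq_len(dim(y)[1])) {
    expect_equal(yt[n, , ], t(y[n, , ]), tolerance = 1e-12)
  }
})

test_that("backpropagation matches numerical gradients", {
  for (variant in c("FTLSTM", "BFTLSTM", "MFTLSTM")) {
    cfg <- net_config(variant, channels_in = 2, hidden1 = 4, hidden2 = 3,
                      dropout = 0, seed = 7)
    m <- init_model(cfg)
    set.seed(40)
    N <- 2
    X <- if (variant == "MFTLSTM") array(runif(N * 50), c(N, 5, 5, 2)) else
      array(runif(N * 10), c(N, 5, 2))
    Y <- if (variant == "MFTLSTM") array(rnorm(N * 25), c(N, 5, 5)) else
      matrix(rnorm(N * 5), N, 5)
    fw <- fluorotherm:::model_core_forward(m, X, training = TRUE)
    dy <- 2 * (fw$y - Y) / length(Y)
    gr <- fluorotherm:::model_backprop(m, fw$cache, dy)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      mean((fluorotherm:::model_core_forward(m2, X)$y - Y)^2)
    }
    # probe a handful of coordinates in every tensor
    probe <- function(path) {
      p <- m$params; g <- gr
      for (k in path) { p <- p[[k]]; g <- g[[k]] }
      set.seed(41)
      for (i in sample(length(p), min(4, length(p)))) {
        pp <- m$params
        bump <- function(tree, path, i, v) {
          if (!length(path)) { tree[i] <- v; return(tree) }
          tree[[path[1]]] <- bump(tree[[path[1]]], path[-1], i, v)
          tree
        }
        num <- (loss_at(bump(pp, path, i, p[i] + 1e-6)) -
                loss_at(bump(pp, path, i, p[i] - 1e-6))) / 2e-6
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
    walk <- function(tree, path = character()) {
      if (is.numeric(tree)) probe(path)
      else for (nm in names(tree)) walk(tree[[nm]], c(path, nm))
    }
    walk(m$params)
  }
})

test_that("degenerate all-identical sequences are valid inputs", {
  m <- init_model(net_config("FTLSTM", channels_in = 2, hidden1 = 4, hidden2 = 3))
  b <- tiny_batch()
  b$inputs[] <- 0.5
  y <- ftlstm_forward(m, b)
  expect_true(all(is.finite(y)))
  expect_equal(max(apply(y, 2, sd)), 0, tolerance = 1e-12)
})
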