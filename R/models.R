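#' Network configuration
#'
#' Describes one of the three patch-recurrent architectures: the
#' one-directional sequence network (`FTLSTM`), its bidirectional variant
#' (`BFTLSTM`), and the multi-directional tile network (`MFTLSTM`). All share
#' the same trunk: two stacked LSTM layers (hidden sizes `hidden1` then
#' `hidden2`) followed by a fully connected head with dropout that maps each
#' position's `hidden2`-dim feature to one temperature.
#'
#' @param variant One of `"FTLSTM"`, `"BFTLSTM"`, `"MFTLSTM"`.
#' @param channels_in Number of image channels C.
#' @param hidden1,hidden2 Hidden state sizes of the two LSTM layers
#'   (defaults 1024 and 612).
#' @param dropout Dropout fraction on the head input, active only during
#'   training (default 0.2).
#' @param tie_directions Share weights between the forward and reverse cores
#'   of bidirectional scans (default `FALSE`; used by symmetry diagnostics).
#' @param tie_orientations Share weights between the row and column cores of
#'   the multi-directional network (default `FALSE`).
#' @param flat_head Use one flattened 25*hidden2 -> 25 head for the tile
#'   network instead of the shared per-position head (default `FALSE`).
#' @param seed Integer seed for weight initialization.
#' @return A `net_config` object.
#' @export
net_config <- function(variant = c("FTLSTM", "BFTLSTM", "MFTLSTM"),
                       channels_in = 5L, hidden1 = 1024L, hidden2 = 612L,
                       dropout = 0.2, tie_directions = FALSE,
                       tie_orientations = FALSE, flat_head = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  hidden1 <- as.integer(hidden1); hidden2 <- as.integer(hidden2)
  if (hidden1 < 1L || hidden2 < 1L) abort("hidden sizes must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(variant = variant, channels_in = as.integer(channels_in),
         hidden1 = hidden1, hidden2 = hidden2, dropout = dropout,
         tie_directions = tie_directions, tie_orientations = tie_orientations,
         flat_head = flat_head, seed = as.integer(seed)),
    class = "net_config"
  )
}

head_init <- function(h2, flat = FALSE) {
  s <- 1 / sqrt(h2)
  if (flat) {
    n_in <- 25L * h2
    list(w = matrix(runif(n_in * 25L, -s, s) / 5, n_in, 25L), b = numeric(25L))
  } else {
    list(w = matrix(runif(h2, -s, s), h2, 1L), b = 0)
  }
}

#' Initialize an untrained network
#'
#' Allocates the parameter tensors for the configured variant. Weight
#' initialization is uniform within +/- 1/sqrt(hidden) with forget-gate
#' biases raised to 1. With `tie_directions`/`tie_orientations` the shared
#' core is stored once and reused in every scan that ties to it, so gradient
#' updates act on genuinely shared weights.
#'
#' @param config A [net_config()].
#' @return An `ft_model` with untrained parameters.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "net_config"))
  C <- config$channels_in; h1 <- config$hidden1; h2 <- config$hidden2
  params <- with_seed(config$seed, {
    p <- switch(config$variant,
      FTLSTM = list(core = core_init(C, h1, h2)),
      BFTLSTM = {
        q <- list(fwd = core_init(C, h1, h2))
        if (!config$tie_directions) q$rev <- core_init(C, h1, h2)
        q
      },
      MFTLSTM = {
        q <- list(row_fwd = core_init(C, h1, h2))
        if (!config$tie_directions) q$row_rev <- core_init(C, h1, h2)
        if (!config$tie_orientations) {
          q$col_fwd <- core_init(C, h1, h2)
          if (!config$tie_directions) q$col_rev <- core_init(C, h1, h2)
        }
        q
      }
    )
    p$head <- head_init(h2, flat = config$flat_head && config$variant == "MFTLSTM")
    p
  })
  structure(
    list(variant = config$variant, config = config, params = params,
         norm = list(t_mean = 0, t_sd = 1), lineage = list()),
    class = "ft_model"
  )
}

#' @export
print.ft_model <- function(x, ...) {
  cat(sprintf("<ft_model> %s, C=%d, hidden %d/%d, %s parameters\n",
              x$variant, x$config$channels_in, x$config$hidden1, x$config$hidden2,
              format(count_parameters(x), big.mark = ",")))
  if (length(x$lineage)) {
    cat(sprintf("  trained %d epoch(s), final val RMSE %.4g K\n",
                length(x$lineage$train_loss), x$lineage$final_val_rmse))
  }
  invisible(x)
}

#' Count trainable parameters
#'
#' Each LSTM layer contributes `4 * (n_in + hidden + 1) * hidden` parameters;
#' the shared head contributes `hidden2 + 1`. Tied cores are counted once.
#'
#' @param x An `ft_model` or `net_config`.
#' @return Integer parameter count.
#' @examples
#' count_parameters(net_config("FTLSTM", channels_in = 5))  # 8226869
#' @export
count_parameters <- function(x) {
  if (inherits(x, "ft_model")) {
    tot <- 0
    count1 <- function(p) {
      if (is.numeric(p)) tot <<- tot + length(p) else for (q in p) count1(q)
    }
    count1(x$params)
    return(as.integer(tot))
  }
  stopifnot(inherits(x, "net_config"))
  C <- x$channels_in; h1 <- x$hidden1; h2 <- x$hidden2
  core <- lstm_n_params(C, h1) + lstm_n_params(h1, h2)
  n_cores <- switch(x$variant,
    FTLSTM = 1L,
    BFTLSTM = if (x$tie_directions) 1L else 2L,
    MFTLSTM = (if (x$tie_orientations) 1L else 2L) * (if (x$tie_directions) 1L else 2L)
  )
  head <- if (x$flat_head && x$variant == "MFTLSTM") (25L * h2 + 1L) * 25L else h2 + 1L
  n_cores * core + head
}

# --- internal forward/backward per variant ----------------------------------
# All of these operate on *standardized* targets; the public forward
# functions denormalize through model$norm.

get_core <- function(params, config, which) {
  switch(which,
    fwd = params$fwd,
    rev = if (config$tie_directions) params$fwd else params$rev,
    row_fwd = params$row_fwd,
    row_rev = if (config$tie_directions) params$row_fwd else params$row_rev,
    col_fwd = if (config$tie_orientations) params$row_fwd else params$col_fwd,
    col_rev = {
      if (config$tie_orientations && config$tie_directions) params$row_fwd
      else if (config$tie_orientations) params$row_rev
      else if (config$tie_directions) params$col_fwd
      else params$col_rev
    }
  )
}

core_key <- function(config, which) {
  switch(which,
    fwd = "fwd",
    rev = if (config$tie_directions) "fwd" else "rev",
    row_fwd = "row_fwd",
    row_rev = if (config$tie_directions) "row_fwd" else "row_rev",
    col_fwd = if (config$tie_orientations) "row_fwd" else "col_fwd",
    col_rev = {
      if (config$tie_orientations && config$tie_directions) "row_fwd"
      else if (config$tie_orientations) "row_rev"
      else if (config$tie_directions) "col_fwd"
      else "col_rev"
    }
  )
}

# inputs array N x 5 x C -> list of 5 matrices N x C
as_steps <- function(inputs) {
  Tn <- dim(inputs)[2]
  lapply(seq_len(Tn), function(t) {
    m <- inputs[, t, ]
    if (!is.matrix(m)) m <- matrix(m, dim(inputs)[1], dim(inputs)[3])
    m
  })
}

make_dropout_masks <- function(n, B, H, p) {
  if (p <= 0) return(NULL)
  lapply(seq_len(n), function(i) {
    matrix(stats::rbinom(B * H, 1, 1 - p) / (1 - p), B, H)
  })
}

# Shared per-position head over a list of feature matrices (B x H2 each).
head_forward_list <- function(head, feats, masks = NULL) {
  Tn <- length(feats)
  B <- nrow(feats[[1]])
  y <- matrix(0, B, Tn)
  used <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    f <- feats[[t]]
    if (!is.null(masks)) f <- f * masks[[t]]
    used[[t]] <- f
    y[, t] <- f %*% head$w + head$b
  }
  list(y = y, used = used)
}

head_backward_list <- function(head, hf, dy, masks = NULL) {
  Tn <- ncol(dy)
  dw <- matrix(0, nrow(head$w), 1)
  db <- 0
  dfeats <- vector("list", Tn)
  tw <- t(head$w)
  for (t in seq_len(Tn)) {
    dyt <- dy[, t, drop = FALSE]
    dw <- dw + crossprod(hf$used[[t]], dyt)
    db <- db + sum(dyt)
    df <- dyt %*% tw
    if (!is.null(masks)) df <- df * masks[[t]]
    dfeats[[t]] <- df
  }
  list(grads = list(w = dw, b = db), dfeats = dfeats)
}

# FTLSTM: forward scan, standardized output B x 5 (+ cache for training)
ftlstm_core <- function(params, config, X, training = FALSE) {
  steps <- as_steps(X)
  fw <- core_forward(params$core, steps, keep_cache = training)
  masks <- if (training) {
    make_dropout_masks(length(fw$h), nrow(fw$h[[1]]), config$hidden2, config$dropout)
  } else NULL
  hf <- head_forward_list(params$head, fw$h, masks)
  list(y = hf$y, cache = list(core = fw$cache, head = hf, masks = masks, steps = steps))
}

ftlstm_backprop <- function(params, config, cache, dy) {
  hb <- head_backward_list(params$head, cache$head, dy, cache$masks)
  cb <- core_backward(params$core, cache$core, hb$dfeats)
  list(core = cb$grads, head = hb$grads)
}

rev_list <- function(x) x[rev(seq_along(x))]

# Bidirectional fusion of two headless cores over a step list; returns fused
# per-position features (aligned by source position) plus caches.
bidir_forward <- function(p_fwd, p_rev, steps, training = FALSE) {
  ff <- core_forward(p_fwd, steps, keep_cache = training)
  fr <- core_forward(p_rev, rev_list(steps), keep_cache = training)
  Tn <- length(steps)
  fused <- lapply(seq_len(Tn), function(t) ff$h[[t]] + fr$h[[Tn + 1 - t]])
  list(fused = fused, cache = list(f = ff$cache, r = fr$cache))
}

bidir_backward <- function(p_fwd, p_rev, cache, dfused) {
  Tn <- length(dfused)
  bf <- core_backward(p_fwd, cache$f, dfused)
  br <- core_backward(p_rev, cache$r, rev_list(dfused))
  list(g_fwd = bf$grads, g_rev = br$grads)
}

bftlstm_core <- function(params, config, X, training = FALSE) {
  steps <- as_steps(X)
  bd <- bidir_forward(get_core(params, config, "fwd"),
                      get_core(params, config, "rev"), steps, training)
  masks <- if (training) {
    make_dropout_masks(length(bd$fused), nrow(bd$fused[[1]]), config$hidden2, config$dropout)
  } else NULL
  hf <- head_forward_list(params$head, bd$fused, masks)
  list(y = hf$y, cache = list(bd = bd$cache, head = hf, masks = masks))
}

bftlstm_backprop <- function(params, config, cache, dy) {
  hb <- head_backward_list(params$head, cache$head, dy, cache$masks)
  bb <- bidir_backward(get_core(params, config, "fwd"),
                       get_core(params, config, "rev"), cache$bd, hb$dfeats)
  g <- list(head = hb$grads)
  kf <- core_key(config, "fwd"); kr <- core_key(config, "rev")
  g[[kf]] <- bb$g_fwd
  g[[kr]] <- if (kr == kf) add_grads(g[[kf]], bb$g_rev) else bb$g_rev
  g
}

# MFTLSTM helpers: tiles N x 5 x 5 x C. Row block layout stacks the 5 row
# (or column) sequences of every tile: stacked row index m = (i-1)*N + b for
# tile b, row i.
tile_row_steps <- function(inputs) {
  N <- dim(inputs)[1]; C <- dim(inputs)[4]
  lapply(seq_len(PATCH_LEN), function(t) {
    do.call(rbind, lapply(seq_len(PATCH_LEN), function(i) {
      m <- inputs[, i, t, ]
      if (!is.matrix(m)) m <- matrix(m, N, C)
      m
    }))
  })
}

tile_col_steps <- function(inputs) {
  N <- dim(inputs)[1]; C <- dim(inputs)[4]
  lapply(seq_len(PATCH_LEN), function(t) {
    do.call(rbind, lapply(seq_len(PATCH_LEN), function(j) {
      m <- inputs[, t, j, ]
      if (!is.matrix(m)) m <- matrix(m, N, C)
      m
    }))
  })
}

mftlstm_core <- function(params, config, X, training = FALSE) {
  N <- dim(X)[1]
  H2 <- config$hidden2
  r_steps <- tile_row_steps(X)
  c_steps <- tile_col_steps(X)
  rb <- bidir_forward(get_core(params, config, "row_fwd"),
                      get_core(params, config, "row_rev"), r_steps, training)
  cb <- bidir_forward(get_core(params, config, "col_fwd"),
                      get_core(params, config, "col_rev"), c_steps, training)
  # fused feature for pixel (i, j): row scan block i at position j plus
  # column scan block j at position i
  fused <- vector("list", PATCH_LEN * PATCH_LEN)
  for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
    ri <- ((i - 1L) * N + 1L):(i * N)
    cj <- ((j - 1L) * N + 1L):(j * N)
    fused[[(i - 1L) * PATCH_LEN + j]] <- rb$fused[[j]][ri, , drop = FALSE] +
      cb$fused[[i]][cj, , drop = FALSE]
  }
  if (isTRUE(config$flat_head)) {
    flat <- do.call(cbind, fused)                  # N x 25*H2
    mask <- if (training && config$dropout > 0) {
      matrix(stats::rbinom(length(flat), 1, 1 - config$dropout) / (1 - config$dropout),
             nrow(flat), ncol(flat))
    } else NULL
    used <- if (is.null(mask)) flat else flat * mask
    yf <- sweep(used %*% params$head$w, 2, params$head$b, "+")   # N x 25
    y <- array(0, c(N, PATCH_LEN, PATCH_LEN))
    for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
      y[, i, j] <- yf[, (i - 1L) * PATCH_LEN + j]
    }
    return(list(y = y, cache = list(rb = rb$cache, cb = cb$cache,
                                    flat_used = used, flat_mask = mask, N = N)))
  }
  masks <- if (training) {
    make_dropout_masks(length(fused), N, H2, config$dropout)
  } else NULL
  hf <- head_forward_list(params$head, fused, masks)
  y <- array(0, c(N, PATCH_LEN, PATCH_LEN))
  for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
    y[, i, j] <- hf$y[, (i - 1L) * PATCH_LEN + j]
  }
  list(y = y, cache = list(rb = rb$cache, cb = cb$cache, head = hf,
                           masks = masks, N = N))
}

mftlstm_backprop <- function(params, config, cache, dy) {
  N <- cache$N
  H2 <- config$hidden2
  dy_flat <- matrix(0, N, PATCH_LEN * PATCH_LEN)
  for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
    dy_flat[, (i - 1L) * PATCH_LEN + j] <- dy[, i, j]
  }
  if (isTRUE(config$flat_head)) {
    dw <- crossprod(cache$flat_used, dy_flat)
    db <- colSums(dy_flat)
    dflat <- dy_flat %*% t(params$head$w)
    if (!is.null(cache$flat_mask)) dflat <- dflat * cache$flat_mask
    hb <- list(grads = list(w = dw, b = db),
               dfeats = lapply(seq_len(PATCH_LEN * PATCH_LEN), function(k) {
                 dflat[, ((k - 1L) * H2 + 1L):(k * H2), drop = FALSE]
               }))
  } else {
    hb <- head_backward_list(params$head, cache$head, dy_flat, cache$masks)
  }
  dR <- lapply(seq_len(PATCH_LEN), function(t) matrix(0, PATCH_LEN * N, H2))
  dC <- lapply(seq_len(PATCH_LEN), function(t) matrix(0, PATCH_LEN * N, H2))
  for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
    df <- hb$dfeats[[(i - 1L) * PATCH_LEN + j]]
    ri <- ((i - 1L) * N + 1L):(i * N)
    cj <- ((j - 1L) * N + 1L):(j * N)
    dR[[j]][ri, ] <- dR[[j]][ri, ] + df
    dC[[i]][cj, ] <- dC[[i]][cj, ] + df
  }
  rb <- bidir_backward(get_core(params, config, "row_fwd"),
                       get_core(params, config, "row_rev"), cache$rb, dR)
  cb <- bidir_backward(get_core(params, config, "col_fwd"),
                       get_core(params, config, "col_rev"), cache$cb, dC)
  g <- list(head = hb$grads)
  acc <- function(g, key, grads) {
    if (is.null(g[[key]])) g[[key]] <- grads else g[[key]] <- add_grads(g[[key]], grads)
    g
  }
  g <- acc(g, core_key(config, "row_fwd"), rb$g_fwd)
  g <- acc(g, core_key(config, "row_rev"), rb$g_rev)
  g <- acc(g, core_key(config, "col_fwd"), cb$g_fwd)
  g <- acc(g, core_key(config, "col_rev"), cb$g_rev)
  g
}

# Standardize inputs with the model's stored per-channel constants
# (identity for untrained models). Conditioning only; inverted nowhere
# because the network consumes, never emits, intensities.
standardize_inputs <- function(model, inputs) {
  xm <- model$norm$x_mean
  if (is.null(xm)) return(inputs)
  xs <- model$norm$x_sd
  nd <- length(dim(inputs))
  sweep(sweep(inputs, nd, xm, "-"), nd, xs, "/")
}

model_core_forward <- function(model, inputs, training = FALSE) {
  inputs <- standardize_inputs(model, inputs)
  switch(model$variant,
    FTLSTM = ftlstm_core(model$params, model$config, inputs, training),
    BFTLSTM = bftlstm_core(model$params, model$config, inputs, training),
    MFTLSTM = mftlstm_core(model$params, model$config, inputs, training)
  )
}

model_backprop <- function(model, cache, dy) {
  switch(model$variant,
    FTLSTM = {
      g <- ftlstm_backprop(model$params, model$config, cache, dy)
      list(core = g$core, head = g$head)
    },
    BFTLSTM = bftlstm_backprop(model$params, model$config, cache, dy),
    MFTLSTM = mftlstm_backprop(model$params, model$config, cache, dy)
  )
}

denorm <- function(model, y) y * model$norm$t_sd + model$norm$t_mean

#' Forward pass of the one-directional sequence network
#'
#' Scans each 1x5 pixel sequence left to right through the two stacked LSTM
#' layers and maps every position's hidden feature to a temperature through
#' the shared fully connected head. Evaluation mode: dropout inactive,
#' deterministic.
#'
#' @param model An `ft_model` with `variant = "FTLSTM"`.
#' @param batch A `sequence_batch` from [extract_sequences()].
#' @return `N x 5` matrix of temperatures in K.
#' @export
ftlstm_forward <- function(model, batch) {
  stopifnot(inherits(model, "ft_model"), model$variant == "FTLSTM",
            inherits(batch, "sequence_batch"))
  check_channels(model, dim(batch$inputs)[3])
  denorm(model, model_core_forward(model, batch$inputs)$y) + batch$target_center
}

#' Forward pass of the bidirectional sequence network
#'
#' Two headless cores scan the sequence and its reversal; the reverse scan's
#' per-position features are re-aligned by source position and added
#' elementwise to the forward features before the shared head.
#'
#' @param model An `ft_model` with `variant = "BFTLSTM"`.
#' @param batch A `sequence_batch`.
#' @return `N x 5` matrix of temperatures in K.
#' @export
bftlstm_forward <- function(model, batch) {
  stopifnot(inherits(model, "ft_model"), model$variant == "BFTLSTM",
            inherits(batch, "sequence_batch"))
  check_channels(model, dim(batch$inputs)[3])
  denorm(model, model_core_forward(model, batch$inputs)$y) + batch$target_center
}

#' Forward pass of the multi-directional tile network
#'
#' Each of the 5 rows and 5 columns of the tile passes through a headless
#' bidirectional core; the row-scan and column-scan feature grids are aligned
#' by source pixel and added elementwise, and the shared head emits one
#' temperature per pixel, yielding a 5x5 output.
#'
#' @param model An `ft_model` with `variant = "MFTLSTM"`.
#' @param batch A `tile_batch` from [extract_tiles()].
#' @return `N x 5 x 5` array of temperatures in K.
#' @export
mftlstm_forward <- function(model, batch) {
  stopifnot(inherits(model, "ft_model"), model$variant == "MFTLSTM",
            inherits(batch, "tile_batch"))
  check_channels(model, dim(batch$inputs)[4])
  denorm(model, model_core_forward(model, batch$inputs)$y) + batch$target_center
}

check_channels <- function(model, c_in) {
  if (c_in != model$config$channels_in) {
    abort(sprintf("input has %d channels but the model expects %d",
                  c_in, model$config$channels_in))
  }
}

#' Predict patch temperatures with any trained model
#'
#' Dispatches to the right forward pass for the model variant and batch type.
#'
#' @param model An `ft_model`.
#' @param batch A `sequence_batch` (FTLSTM/BFTLSTM) or `tile_batch` (MFTLSTM).
#' @return Kelvin predictions, `N x 5` or `N x 5 x 5`.
#' @export
predict_patches <- function(model, batch) {
  switch(model$variant,
    FTLSTM = ftlstm_forward(model, batch),
    BFTLSTM = bftlstm_forward(model, batch),
    MFTLSTM = mftlstm_forward(model, batch)
  )
}
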