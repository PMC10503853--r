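# Batched LSTM primitives -----------------------------------------------------
#
# A single LSTM layer is parameterised by
#   Wx : in  x 4H   input-to-gate weights
#   Wh : H   x 4H   recurrent weights
#   b  : 4H         gate biases
# with gate blocks ordered (input, forget, output, cell) — the three
# sigmoid gates contiguous so one sigmoid call covers them — giving the
# standard gated-recurrent parameter count 4 * (in + H + 1) * H. Forward and
# backward passes operate on whole batches as dense matrix products so the
# heavy lifting stays in BLAS.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(n_in, n_hidden) {
  # uniform +/- 1/sqrt(H) with forget-gate bias raised to 1 (standard practice
  # so early training does not forget aggressively)
  s <- 1 / sqrt(n_hidden)
  b <- runif(4 * n_hidden, -s, s)
  b[(n_hidden + 1):(2 * n_hidden)] <- 1
  list(
    Wx = matrix(runif(n_in * 4 * n_hidden, -s, s), n_in, 4 * n_hidden),
    Wh = matrix(runif(n_hidden * 4 * n_hidden, -s, s), n_hidden, 4 * n_hidden),
    b = b
  )
}

lstm_n_params <- function(n_in, n_hidden) 4L * (n_in + n_hidden + 1L) * n_hidden

# X: list of T matrices, each B x n_in. Returns hidden states per step and
# (optionally) the caches needed for the backward pass.
lstm_forward <- function(par, X, keep_cache = TRUE) {
  H <- ncol(par$Wh) / 4L
  Tn <- length(X)
  B <- nrow(X[[1]])
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  ii <- 1:H; ff <- (H + 1):(2 * H); oo <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
  sg <- 1:(3 * H)
  bmat <- matrix(par$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    Z <- X[[t]] %*% par$Wx + h %*% par$Wh + bmat
    Z[, sg] <- sigmoid(Z[, sg])
    gi <- Z[, ii, drop = FALSE]
    gf <- Z[, ff, drop = FALSE]
    go <- Z[, oo, drop = FALSE]
    gc_ <- tanh(Z[, gg, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gc_
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    hs[[t]] <- h
    if (keep_cache) {
      cache[[t]] <- list(x = X[[t]], gi = gi, gf = gf, gc = gc_, go = go,
                         c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
  }
  list(h = hs, cache = cache)
}

# dH: list of T matrices (B x H), gradient of the loss w.r.t. each step's
# hidden output. Returns parameter gradients and the gradient w.r.t. the
# layer inputs (list of T matrices B x n_in).
lstm_backward <- function(par, cache, dH) {
  Tn <- length(dH)
  H <- ncol(par$Wh) / 4
  B <- nrow(dH[[1]])
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(length(par$b))
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tWx <- t(par$Wx)
  tWh <- t(par$Wh)
  ii <- 1:H; ff <- (H + 1):(2 * H); oo <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
  dZ <- matrix(0, B, 4 * H)
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    dh <- dH[[t]] + dh_next
    dgo <- dh * ca$tc
    dc <- dh * ca$go * (1 - ca$tc^2) + dc_next
    dgi <- dc * ca$gc
    dgc <- dc * ca$gi
    dgf <- dc * ca$c_prev
    dc_next <- dc * ca$gf
    dZ[, ii] <- dgi * ca$gi * (1 - ca$gi)
    dZ[, ff] <- dgf * ca$gf * (1 - ca$gf)
    dZ[, oo] <- dgo * ca$go * (1 - ca$go)
    dZ[, gg] <- dgc * (1 - ca$gc^2)
    dWx <- dWx + crossprod(ca$x, dZ)
    dWh <- dWh + crossprod(ca$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[[t]] <- dZ %*% tWx
    dh_next <- dZ %*% tWh
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

# Two stacked LSTM layers (the shared "core" of every network variant):
# hidden sizes H1 then H2; the per-step H2-dim outputs feed fusion/heads.
core_init <- function(n_in, h1, h2) {
  list(l1 = lstm_init(n_in, h1), l2 = lstm_init(h1, h2))
}

core_forward <- function(core, X, keep_cache = TRUE) {
  f1 <- lstm_forward(core$l1, X, keep_cache)
  f2 <- lstm_forward(core$l2, f1$h, keep_cache)
  list(h = f2$h, cache = list(f1 = f1$cache, f2 = f2$cache))
}

core_backward <- function(core, cache, dH) {
  b2 <- lstm_backward(core$l2, cache$f2, dH)
  b1 <- lstm_backward(core$l1, cache$f1, b2$dX)
  list(grads = list(l1 = b1$grads, l2 = b2$grads), dX = b1$dX)
}

# Flatten/unflatten parameter trees for the optimizer ------------------------

flatten_params <- function(p) {
  if (is.numeric(p)) return(list(p))
  unlist(lapply(p, flatten_params), recursive = FALSE)
}

map2_params <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in names(a)) out[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
  out
}

zeros_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, zeros_like)
}

# Adam update on an arbitrary nested parameter/gradient tree.
adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# Accumulate gradient tree b into a (same structure).
add_grads <- function(a, b) map2_params(a, b, `+`)
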