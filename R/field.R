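#' Temperature field container
#'
#' A `temperature_field` holds a 2-D grid of temperatures in kelvin together
#' with the physical pixel pitch and a free-form provenance record. It is the
#' ground truth for image rendering and the target of every reconstruction.
#' The grid uses the row-major image convention: element `[i, j]` is row `i`
#' (y, counted from the top) and column `j` (x), 1-based.
#'
#' @param values Numeric matrix of temperatures (K). All values must be finite.
#' @param pitch_um Pixel pitch in micrometres (> 0). Defaults to 1 so gradient
#'   maps are directly in K/um.
#' @param meta Named list of provenance entries (generator, parameters, seed,
#'   declared `t_range`, ...). Stored as-is.
#' @return An object of class `temperature_field` with elements `values`,
#'   `pitch_um` and `meta`.
#' @examples
#' f <- temperature_field(matrix(300, 8, 8))
#' dim(f)
#' @export
temperature_field <- function(values, pitch_um = 1, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (!all(is.finite(values))) abort("temperature field contains non-finite values")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0) {
    abort("`pitch_um` must be a single positive number.")
  }
  structure(
    list(values = values, pitch_um = as.numeric(pitch_um), meta = meta),
    class = "temperature_field"
  )
}

#' @export
dim.temperature_field <- function(x) dim(x$values)

#' @export
print.temperature_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<temperature_field> %d x %d px, pitch %g um, range [%.3f, %.3f] K\n",
    d[1], d[2], x$pitch_um, min(x$values), max(x$values)
  ))
  if (!is.null(x$meta$generator)) cat("  generator:", x$meta$generator, "\n")
  invisible(x)
}

#' @export
mean.temperature_field <- function(x, ...) mean(x$values, ...)

#' Specify a ground-truth temperature field
#'
#' A `field_spec` parameterises one of the generator families:
#' `"pipe_cross_section"` (closed-form annulus conduction profile),
#' `"plate_dirichlet"` / `"fd_poisson"` (finite-difference solution of the
#' steady heat equation on a rectangle with Dirichlet or insulated edges and
#' optional interior fixed-temperature heater lines).
#'
#' @param kind One of `"pipe_cross_section"`, `"plate_dirichlet"`, `"fd_poisson"`.
#' @param shape Integer vector `c(rows, cols)`.
#' @param t_range Length-2 numeric, declared `c(t_min, t_max)` window in K.
#' @param ... Family-specific parameters, e.g. for the pipe: `r_inner_px`,
#'   `r_outer_px`, `t_inner`, `t_outer`, `center_px`, `boundary_wave`
#'   (list with `amplitude_k`, `period_px`); for the finite-difference
#'   families: `edges` (named list `left/right/top/bottom`, each a kelvin value
#'   or `"insulated"`), `sources` (list of heater lines, each
#'   `list(kind = "vline"|"hline", index, from, to, t)`).
#' @return A `field_spec` object.
#' @export
field_spec <- function(kind = c("pipe_cross_section", "plate_dirichlet", "fd_poisson"),
                       shape, t_range, ...) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) abort("`shape` must be c(rows, cols), both >= 2")
  t_range <- as.numeric(t_range)
  if (length(t_range) != 2L || t_range[1] >= t_range[2]) {
    abort("`t_range` must be c(t_min, t_max) with t_min < t_max")
  }
  spec <- c(list(kind = kind, shape = shape, t_range = t_range), list(...))
  structure(spec, class = "field_spec")
}

#' Default synthetic-benchmark field specification
#'
#' The stock annulus ("pipe cross-section") spec used for the synthetic
#' benchmark: a 298-308 K window, inner wall hot, outer wall cold, with an
#' optional sinusoidal modulation of the top/bottom boundary rows that
#' recreates periodic edge features (the hardest pixels to reconstruct).
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param t_range Temperature window in K.
#' @param boundary_wave `NULL`, or a list with `amplitude_k` and `period_px`.
#' @return A `field_spec`.
#' @export
dataset1_field_spec <- function(shape = c(50, 50), t_range = c(298, 308),
                                boundary_wave = list(amplitude_k = 1, period_px = 16)) {
  r_out <- floor(min(shape) / 2) - 1
  field_spec(
    "pipe_cross_section", shape = shape, t_range = t_range,
    r_inner_px = max(3, round(r_out / 4)), r_outer_px = r_out,
    t_inner = t_range[2], t_outer = t_range[1],
    boundary_wave = boundary_wave
  )
}

#' Generate an annulus (pipe cross-section) temperature field
#'
#' Evaluates the closed-form steady conduction profile through a pipe wall:
#' inside the inner radius the field is at the inner-wall temperature, outside
#' the outer radius at the outer-wall temperature, and within the annulus
#' \deqn{T(r) = T_i + (T_o - T_i) \log(r/r_i) / \log(r_o/r_i).}
#' Optionally a sinusoidal Dirichlet modulation is added on the top and bottom
#' boundary rows (decaying into the interior over a few pixels) to mimic
#' periodic edge structure.
#'
#' @param spec A `field_spec` with `kind = "pipe_cross_section"`.
#' @param noise_seed Optional integer; when given, pixelwise Gaussian noise of
#'   `noise_sd` (default 0 i.e. none) is applied via [add_temperature_noise()].
#' @param noise_sd Noise standard deviation in K used when `noise_seed` given.
#' @return A [temperature_field()].
#' @examples
#' sp <- field_spec("pipe_cross_section", shape = c(64, 64), t_range = c(298, 308),
#'                  r_inner_px = 10, r_outer_px = 30, t_inner = 308, t_outer = 298)
#' f <- generate_pipe_field(sp)
#' range(f$values)
#' @export
generate_pipe_field <- function(spec, noise_seed = NULL, noise_sd = 0.1) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$kind != "pipe_cross_section") abort("spec kind must be 'pipe_cross_section'")
  r_i <- spec$r_inner_px
  r_o <- spec$r_outer_px
  if (is.null(r_i) || is.null(r_o) || r_i >= r_o || r_i <= 0) {
    abort("invalid annulus geometry: need 0 < r_inner_px < r_outer_px")
  }
  t_i <- spec$t_inner
  t_o <- spec$t_outer
  tr <- spec$t_range
  if (min(t_i, t_o) < tr[1] || max(t_i, t_o) > tr[2]) {
    abort("wall temperatures outside the declared t_range")
  }
  nr <- spec$shape[1]; nc <- spec$shape[2]
  ctr <- spec$center_px %||% c((nr + 1) / 2, (nc + 1) / 2)
  ry <- matrix(seq_len(nr) - ctr[1], nr, nc)
  rx <- matrix(seq_len(nc) - ctr[2], nr, nc, byrow = TRUE)
  r <- sqrt(rx^2 + ry^2)
  vals <- matrix(t_o, nr, nc)
  vals[r <= r_i] <- t_i
  ann <- r > r_i & r < r_o
  vals[ann] <- t_i + (t_o - t_i) * log(r[ann] / r_i) / log(r_o / r_i)
  if (!is.null(spec$boundary_wave)) {
    bw <- spec$boundary_wave
    amp <- bw$amplitude_k %||% 1
    per <- bw$period_px %||% 16
    decay_px <- bw$decay_px %||% 3
    wave <- amp * sin(2 * pi * seq_len(nc) / per)
    for (k in 0:(min(decay_px, nr %/% 2) - 1)) {
      w <- exp(-k / max(1, decay_px / 2))
      vals[1 + k, ] <- vals[1 + k, ] + w * wave
      vals[nr - k, ] <- vals[nr - k, ] + w * wave
    }
    # keep the declared window honest
    vals <- pmin(pmax(vals, tr[1]), tr[2])
  }
  f <- temperature_field(vals, pitch_um = spec$pitch_um %||% 1, meta = list(
    generator = "generate_pipe_field",
    t_range = tr,
    params = list(r_inner_px = r_i, r_outer_px = r_o, t_inner = t_i, t_outer = t_o,
                  boundary_wave = spec$boundary_wave)
  ))
  if (!is.null(noise_seed)) f <- add_temperature_noise(f, noise_sd, noise_seed) else f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve a steady-state heat-diffusion field by finite differences
#'
#' Solves the 5-point-stencil discrete Laplace equation on a rectangular grid
#' with per-edge Dirichlet values or insulated (mirror/Neumann) edges and
#' optional interior fixed-temperature heater lines. The sparse linear system
#' is solved directly, then the interior residual
#' `|4 T[i,j] - T[i-1,j] - T[i+1,j] - T[i,j-1] - T[i,j+1]|` is checked against
#' `tol` at every free pixel.
#'
#' @param spec A `field_spec` with `kind` `"fd_poisson"` or `"plate_dirichlet"`;
#'   fields `edges` (named list left/right/top/bottom: kelvin value or
#'   `"insulated"`) and optional `sources` (heater lines).
#' @param tol Maximum allowed interior residual in K (default 1e-6).
#' @return A [temperature_field()].
#' @examples
#' sp <- field_spec("fd_poisson", shape = c(20, 30), t_range = c(290, 380),
#'                  edges = list(left = 290, right = 380,
#'                               top = "insulated", bottom = "insulated"))
#' f <- solve_steady_field(sp)
#' @export
solve_steady_field <- function(spec, tol = 1e-6) {
  stopifnot(inherits(spec, "field_spec"))
  if (!spec$kind %in% c("fd_poisson", "plate_dirichlet")) {
    abort("spec kind must be 'fd_poisson' or 'plate_dirichlet'")
  }
  nr <- spec$shape[1]; nc <- spec$shape[2]
  edges <- spec$edges
  if (is.null(edges)) abort("spec must provide `edges`")
  for (e in c("left", "right", "top", "bottom")) {
    if (is.null(edges[[e]])) abort(sprintf("edge '%s' missing from spec$edges", e))
  }
  tr <- spec$t_range

  fixed <- matrix(NA_real_, nr, nc)       # NA = free unknown
  is_dirichlet <- function(e) is.numeric(edges[[e]])
  if (is_dirichlet("top"))    fixed[1, ]  <- edges$top
  if (is_dirichlet("bottom")) fixed[nr, ] <- edges$bottom
  if (is_dirichlet("left"))   fixed[, 1]  <- edges$left
  if (is_dirichlet("right"))  fixed[, nc] <- edges$right
  for (s in spec$sources %||% list()) {
    tv <- s$t
    if (tv < tr[1] || tv > tr[2]) abort("heater-line temperature outside t_range")
    if (s$kind == "vline") {
      rows <- seq(max(1, s$from), min(nr, s$to))
      fixed[rows, s$index] <- tv
    } else if (s$kind == "hline") {
      cols <- seq(max(1, s$from), min(nc, s$to))
      fixed[s$index, cols] <- tv
    } else abort("source kind must be 'vline' or 'hline'")
  }
  if (all(!is.na(fixed))) {
    return(temperature_field(fixed, pitch_um = spec$pitch_um %||% 1,
                             meta = list(generator = "solve_steady_field", t_range = tr)))
  }

  idx <- matrix(0L, nr, nc)
  free <- which(is.na(fixed))
  idx[free] <- seq_along(free)
  n <- length(free)
  rhs <- numeric(n)
  deg <- integer(n)
  fr <- ((free - 1L) %% nr) + 1L
  fc <- ((free - 1L) %/% nr) + 1L
  off_i <- vector("list", 4); off_j <- vector("list", 4)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (d in seq_along(shifts)) {
    rr <- fr + shifts[[d]][1]; cc <- fc + shifts[[d]][2]
    inb <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc  # mirror ghosts drop out
    deg <- deg + as.integer(inb)
    nb <- cbind(rr[inb], cc[inb])
    nb_free <- is.na(fixed[nb])
    k_in <- which(inb)
    rhs[k_in[!nb_free]] <- rhs[k_in[!nb_free]] + fixed[nb[!nb_free, , drop = FALSE]]
    off_i[[d]] <- k_in[nb_free]
    off_j[[d]] <- idx[nb[nb_free, , drop = FALSE]]
  }
  A <- Matrix::sparseMatrix(
    i = c(unlist(off_i), seq_len(n)),
    j = c(unlist(off_j), seq_len(n)),
    x = c(rep(-1, length(unlist(off_i))), as.numeric(deg)),
    dims = c(n, n)
  )
  sol <- as.numeric(Matrix::solve(A, rhs))
  vals <- fixed
  vals[free] <- sol

  res <- fd_residual(vals, free_mask = is.na(fixed))
  if (res > tol) {
    abort(sprintf("finite-difference solve did not meet tolerance: residual %.3g K > %.3g K",
                  res, tol))
  }
  temperature_field(vals, pitch_um = spec$pitch_um %||% 1, meta = list(
    generator = "solve_steady_field", t_range = tr,
    params = list(edges = edges, sources = spec$sources), residual_k = res
  ))
}

# Max |deg*T - sum(in-domain neighbours)| over free interior pixels
# (mirror ghosts at domain borders contribute nothing, matching the solver).
fd_residual <- function(vals, free_mask) {
  nr <- nrow(vals); nc <- ncol(vals)
  res <- 0
  for (k in which(free_mask)) {
    r <- ((k - 1L) %% nr) + 1L
    c <- ((k - 1L) %/% nr) + 1L
    s <- 0; deg <- 0
    if (r > 1L) { s <- s + vals[r - 1L, c]; deg <- deg + 1 }
    if (r < nr) { s <- s + vals[r + 1L, c]; deg <- deg + 1 }
    if (c > 1L) { s <- s + vals[r, c - 1L]; deg <- deg + 1 }
    if (c < nc) { s <- s + vals[r, c + 1L]; deg <- deg + 1 }
    res <- max(res, abs(deg * vals[r, c] - s))
  }
  res
}

#' Add pixelwise Gaussian temperature noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma_k` to
#' every pixel, emulating sensor noise on the temperature map before image
#' rendering. Deterministic for a fixed seed.
#'
#' @param field A [temperature_field()].
#' @param sigma_k Noise standard deviation in K (>= 0).
#' @param seed Integer seed (required for reproducibility).
#' @return A new `temperature_field`; `meta$noise` records `sigma_k` and `seed`.
#' @examples
#' f <- temperature_field(matrix(300, 10, 10))
#' g <- add_temperature_noise(f, 0.1, seed = 7)
#' sd(g$values - f$values)
#' @export
add_temperature_noise <- function(field, sigma_k, seed) {
  stopifnot(inherits(field, "temperature_field"))
  if (!is.numeric(sigma_k) || length(sigma_k) != 1L || sigma_k < 0) {
    abort("`sigma_k` must be a single non-negative number")
  }
  if (sigma_k == 0) {
    out <- field
    out$meta$noise <- list(sigma_k = 0, seed = seed)
    return(out)
  }
  vals <- field$values
  noise <- with_seed(seed, rnorm(length(vals), 0, sigma_k))
  out <- field
  out$values <- vals + matrix(noise, nrow(vals), ncol(vals))
  out$meta$noise <- list(sigma_k = sigma_k, seed = seed)
  out
}
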