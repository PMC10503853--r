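#' Serpentine quantum-dot channel mask
#'
#' Builds the binary mask of a boustrophedon (zig-zag) channel: `n_passes`
#' horizontal runs of the stated width, joined by vertical links at alternating
#' ends, tracing from the top of the frame to the bottom. The mask marks where
#' quantum dots (and hence fluorescent signal) exist.
#'
#' @param shape `c(rows, cols)` of the frame.
#' @param n_passes Number of horizontal runs (>= 1).
#' @param channel_width_px Channel width in pixels (>= 1).
#' @param margin_px Margin kept clear at the left/right frame edges.
#' @return A logical matrix of `shape`; `TRUE` marks channel pixels.
#' @examples
#' m <- make_serpentine_mask(c(40, 56), n_passes = 4, channel_width_px = 3)
#' mean(m)
#' @export
make_serpentine_mask <- function(shape, n_passes = 4L, channel_width_px = 3L,
                                 margin_px = 3L) {
  shape <- as.integer(shape)
  n_passes <- as.integer(n_passes)
  w <- as.integer(channel_width_px)
  if (n_passes < 1L || w < 1L) abort("n_passes and channel_width_px must be >= 1")
  nr <- shape[1]; nc <- shape[2]
  gap <- if (n_passes == 1L) 0 else (nr - 2L * margin_px - w) / (n_passes - 1L)
  if (nc - 2L * margin_px < w || (n_passes > 1L && gap < w)) {
    abort("serpentine geometry does not fit the frame")
  }
  mask <- matrix(FALSE, nr, nc)
  col_lo <- margin_px + 1L; col_hi <- nc - margin_px
  tops <- margin_px + 1L + round((seq_len(n_passes) - 1L) * gap)
  for (p in seq_len(n_passes)) {
    rows <- tops[p]:(tops[p] + w - 1L)
    mask[rows, col_lo:col_hi] <- TRUE
    if (p < n_passes) {
      # vertical link at alternating ends
      link_cols <- if (p %% 2L == 1L) (col_hi - w + 1L):col_hi else col_lo:(col_lo + w - 1L)
      mask[tops[p]:(tops[p + 1L] + w - 1L), link_cols] <- TRUE
    }
  }
  mask
}

#' Microfluidic chip scene
#'
#' Bundles a solved temperature field, the serpentine channel mask, and the
#' simulated thermocouple: `probe_xy` is snapped to the nearest channel pixel
#' and `probe_t` is read from the field there — the single location where both
#' fluorescence and temperature are known, as in the single-point calibration
#' protocol.
#'
#' @param field A [temperature_field()].
#' @param mask Logical matrix, same shape as the field, with >= 1 `TRUE` pixel.
#' @param probe_xy `c(row, col)` of the thermocouple (snapped to the channel).
#' @return A `chip_scene` object with `field`, `mask`, `probe_xy`, `probe_t`.
#' @export
chip_scene <- function(field, mask, probe_xy = NULL) {
  stopifnot(inherits(field, "temperature_field"))
  if (!is.logical(mask) || !identical(dim(mask), dim(field$values))) {
    abort("`mask` must be a logical matrix with the field's shape")
  }
  if (!any(mask)) abort("mask must mark at least one channel pixel")
  d <- dim(mask)
  if (is.null(probe_xy)) probe_xy <- c(round(d[1] / 2), round(d[2] / 2))
  if (any(probe_xy < 1) || probe_xy[1] > d[1] || probe_xy[2] > d[2]) {
    abort("probe_xy out of bounds")
  }
  ch <- which(mask, arr.ind = TRUE)
  dist2 <- (ch[, 1] - probe_xy[1])^2 + (ch[, 2] - probe_xy[2])^2
  nearest <- ch[which.min(dist2), ]
  probe_xy <- as.integer(nearest)
  structure(
    list(field = field, mask = mask, probe_xy = probe_xy,
         probe_t = field$values[probe_xy[1], probe_xy[2]]),
    class = "chip_scene"
  )
}

#' @export
print.chip_scene <- function(x, ...) {
  cat(sprintf(
    "<chip_scene> %d x %d px, span %.2f K, probe (%d, %d) at %.2f K\n",
    nrow(x$mask), ncol(x$mask), diff(range(x$field$values)),
    x$probe_xy[1], x$probe_xy[2], x$probe_t
  ))
  invisible(x)
}

#' Render a chip scene into a masked fluorescent image
#'
#' Renders the scene's field and zeroes every channel outside the channel
#' mask (configurable background floor), mirroring the masking of camera
#' frames to the quantum-dot channel only. The probe location and
#' temperature are recorded in the image meta so downstream calibration can
#' use only that point. With `forward = "calibration"` (the default, and the
#' contract against [render_image()]) the calibration quadratics are the
#' forward map; with `forward = "physical"` the image comes from the
#' emission/filter model via [render_physical()] — the experimental
#' situation, in which the quadratics only approximate the true map. A
#' noise field can be supplied to render from noisy temperatures while the
#' scene keeps the clean ground truth.
#'
#' @param scene A [chip_scene()].
#' @param cal A `calibration_model`.
#' @param background Counts assigned outside the mask (default 0).
#' @param quantize,clip Passed to the renderer.
#' @param forward `"calibration"` or `"physical"`.
#' @param model,bank Emission model and filter bank for the physical forward.
#' @param render_field Optional [temperature_field()] actually rendered
#'   (e.g. a noisy copy); defaults to the scene's field.
#' @return A [fluorescent_image()].
#' @export
render_chip <- function(scene, cal, background = 0, quantize = TRUE,
                        clip = c("error", "clip"),
                        forward = c("calibration", "physical"),
                        model = qd_spectrum_model(),
                        bank = filter_bank_device6(),
                        render_field = NULL) {
  stopifnot(inherits(scene, "chip_scene"))
  forward <- match.arg(forward)
  fld <- render_field %||% scene$field
  img <- if (forward == "physical") {
    render_physical(fld, model, bank, cal, quantize = quantize)
  } else {
    render_image(fld, cal, quantize = quantize, clip = clip)
  }
  for (j in seq_len(dim(img$channels)[3])) {
    ch <- img$channels[, , j]
    ch[!scene$mask] <- background
    img$channels[, , j] <- ch
  }
  img$meta$probe_xy <- scene$probe_xy
  img$meta$probe_t <- scene$probe_t
  img$meta$masked <- TRUE
  img
}

#' Default chip field specification
#'
#' A rectangular chip with all four edges held at a shell temperature and two
#' interior vertical heater lines at a hotter fixed temperature — the
#' finite-difference stand-in for the device's embedded liquid-metal heaters,
#' with the fixed boundary standing in for natural convection.
#'
#' @param shape `c(rows, cols)`.
#' @param ambient_k Baseline (unheated) chip temperature.
#' @param heater_dt_k Heater-line temperature excess over ambient (K).
#' @param shell_frac Fraction of `heater_dt_k` applied to the boundary (the
#'   shell warms with the heaters, but less).
#' @param t_range Declared envelope, default `c(290, 380)` K.
#' @param pitch_um Pixel pitch (default 100 um — chip scale).
#' @return A `field_spec` of kind `fd_poisson`.
#' @export
chip_field_spec <- function(shape = c(40, 56), ambient_k = 293, heater_dt_k = 40,
                            shell_frac = 0.35, t_range = c(290, 380),
                            pitch_um = 100) {
  shell <- ambient_k + shell_frac * heater_dt_k
  heat <- ambient_k + heater_dt_k
  if (heat > t_range[2]) abort("heater temperature exceeds the declared t_range")
  q <- round(shape[2] / 3)
  field_spec(
    "fd_poisson", shape = shape, t_range = t_range,
    edges = list(left = shell, right = shell, top = shell, bottom = shell),
    sources = list(
      list(kind = "vline", index = q, from = round(shape[1] / 4),
           to = round(3 * shape[1] / 4), t = heat),
      list(kind = "vline", index = shape[2] - q, from = round(shape[1] / 4),
           to = round(3 * shape[1] / 4), t = heat)
    ),
    pitch_um = pitch_um,
    ambient_k = ambient_k, heater_dt_k = heater_dt_k, shell_frac = shell_frac
  )
}

#' Build a heater-sweep series of chip scenes
#'
#' One scene per heater setting: the chip field is re-solved with the heater
#' lines at increasing temperature excess, the same serpentine mask and
#' probe are reused, and each setting is rendered through the *physical*
#' emission/filter model from a noisy copy of the field while the scene
#' keeps the clean solution as ground truth — the experimental structure, in
#' which the ground truth is model-derived and noiseless but the camera
#' counts carry sensor noise and the analyst's quadratic calibration only
#' approximates the true temperature-intensity map. Probe temperatures
#' increase strictly with heater strength and the default series stays
#' within 290-380 K while spanning scene temperature ranges from about 1 K
#' to about 50 K.
#'
#' @param heater_dts_k Heater temperature excesses over ambient (K), one per
#'   setting (>= 2 settings).
#' @param base_spec A [chip_field_spec()]-style spec used as the template.
#' @param cal A `calibration_model` (fit one from the series itself with
#'   [fit_probe_calibration()] if `NULL`; the rendered images are then
#'   attached in a second pass).
#' @param seed Integer seed for the per-scene noise.
#' @param noise_sd Temperature-noise standard deviation in K (default 0:
#'   chip sensor noise lives in the count domain).
#' @param noise_sd_counts Camera-noise standard deviation in grayscale
#'   counts, applied inside the channel mask after rendering (default 50).
#' @param mask Serpentine mask (default built to fit the spec shape).
#' @param probe_xy Probe location (default frame centre, snapped to channel).
#' @param quantize,background Passed to [render_chip()].
#' @param model,bank Emission model and filter bank for the physical render.
#' @return A `chip_series`: list with `scenes` (list of `chip_scene`, fields
#'   are the clean ground truth), `images` (list of `fluorescent_image` or
#'   `NULL` when `cal` is `NULL`), `cal`, and a `settings` tibble (heater
#'   excess, probe temperature, span).
#' @export
build_chip_series <- function(heater_dts_k = c(1, 6, 14, 24, 38, 56, 80),
                              base_spec = chip_field_spec(),
                              cal = NULL, seed = 1L, noise_sd = 0,
                              noise_sd_counts = 50,
                              mask = NULL, probe_xy = NULL,
                              quantize = TRUE, background = 0,
                              model = qd_spectrum_model(),
                              bank = filter_bank_device6()) {
  if (length(heater_dts_k) < 2L) abort("need at least 2 heater settings")
  shape <- base_spec$shape
  if (is.null(mask)) mask <- make_serpentine_mask(shape)
  seeds <- derive_seeds(seed, 2L * length(heater_dts_k))
  scenes <- vector("list", length(heater_dts_k))
  noisy_fields <- vector("list", length(heater_dts_k))
  for (k in seq_along(heater_dts_k)) {
    sp <- chip_field_spec(
      shape = shape, ambient_k = base_spec$ambient_k %||% 293,
      heater_dt_k = heater_dts_k[k],
      shell_frac = base_spec$shell_frac %||% 0.35,
      t_range = base_spec$t_range, pitch_um = base_spec$pitch_um %||% 100
    )
    fld <- solve_steady_field(sp)
    scenes[[k]] <- chip_scene(fld, mask, probe_xy)
    noisy_fields[[k]] <- if (noise_sd > 0) {
      add_temperature_noise(fld, noise_sd, seeds[k])
    } else fld
  }
  images <- NULL
  if (!is.null(cal)) {
    nsc <- length(scenes)
    images <- lapply(seq_along(scenes), function(k) {
      img <- render_chip(scenes[[k]], cal, background = background,
                         quantize = quantize, forward = "physical",
                         model = model, bank = bank,
                         render_field = noisy_fields[[k]])
      if (noise_sd_counts > 0) {
        img <- add_count_noise(img, noise_sd_counts, seeds[nsc + k],
                               mask = scenes[[k]]$mask)
      }
      img
    })
  }
  settings <- tibble(
    setting = seq_along(heater_dts_k),
    heater_dt_k = heater_dts_k,
    probe_t = vapply(scenes, function(s) s$probe_t, numeric(1)),
    span_k = vapply(scenes, function(s) diff(range(s$field$values)), numeric(1))
  )
  structure(list(scenes = scenes, images = images, cal = cal, settings = settings),
            class = "chip_series")
}

#' @export
print.chip_series <- function(x, ...) {
  cat(sprintf("<chip_series> %d scenes%s\n", length(x$scenes),
              if (is.null(x$images)) " (unrendered)" else ""))
  print(x$settings)
  invisible(x)
}

#' Single-known-point calibration from a chip series
#'
#' Mirrors the experimental protocol in which the thermocouple pixel is the
#' only place where both temperature and fluorescence are known: for each
#' scene, the raw band intensities at the probe temperature are computed from
#' the emission model and filter bank, and the quadratic calibration is fitted
#' to those probe points alone (then applied chip-wide).
#'
#' @param series A [build_chip_series()] result (>= 3 scenes).
#' @param model A [qd_spectrum_model()].
#' @param bank A [filter_bank()] (default the six-filter device bank).
#' @param t_range Validity range, default the declared chip envelope.
#' @param headroom Exposure headroom fraction on the per-channel anchors
#'   (default 0.15), so scene temperatures slightly outside the probe's
#'   operating points still register unclipped counts.
#' @return A `calibration_model`.
#' @export
fit_probe_calibration <- function(series, model = qd_spectrum_model(),
                                  bank = filter_bank_device6(),
                                  t_range = c(290, 380), headroom = 0.15) {
  stopifnot(inherits(series, "chip_series"))
  probe_ts <- series$settings$probe_t
  bi <- band_intensity_table(model, probe_ts, bank)
  # each filter image is its own full-range camera exposure: per-channel anchors
  fit_calibration(probe_ts, bi, t_range = t_range, anchors = "per_channel",
                  headroom = headroom)
}
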