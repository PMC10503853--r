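#' Multi-channel fluorescent image container
#'
#' Holds a stack of 2-D grayscale channels on the 16-bit count scale, one
#' channel per spectral band or filter. Quantized (camera) images hold
#' integer counts in `[0, 65535]`; unquantized images are idealized
#' floating-point renderings and may carry the calibration fit's residual
#' slightly past the digital range (clipping is part of digitization).
#'
#' @param channels 3-D numeric array `rows x cols x n_channels` (a matrix is
#'   promoted to a single channel).
#' @param channel_names Character vector, one name per channel.
#' @param meta Named list of provenance entries.
#' @return A `fluorescent_image` object.
#' @export
fluorescent_image <- function(channels, channel_names = NULL, meta = list()) {
  if (is.matrix(channels)) channels <- array(channels, c(dim(channels), 1L))
  if (length(dim(channels)) != 3L) abort("`channels` must be rows x cols x channels")
  if (!all(is.finite(channels))) abort("channel counts must be finite")
  if (isTRUE(meta$quantized) && (min(channels) < 0 || max(channels) > 65535)) {
    abort("quantized channel counts must lie in [0, 65535]")
  }
  nc <- dim(channels)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) abort("one name per channel required")
  structure(
    list(channels = channels, channel_names = channel_names,
         bit_depth = 16L, meta = meta),
    class = "fluorescent_image"
  )
}

#' @export
dim.fluorescent_image <- function(x) dim(x$channels)

#' @export
print.fluorescent_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<fluorescent_image> %d x %d px, %d channels (16-bit)\n", d[1], d[2], d[3]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a per-channel quadratic temperature-intensity calibration
#'
#' Implements the benchmark calibration protocol: the global minimum and
#' maximum raw intensities across all provided bands and temperatures are
#' mapped affinely to grayscale 0 and 65,535 (these anchors are frozen into
#' the model), then each channel's scaled counts are fitted with a
#' least-squares quadratic in temperature, `counts = a T^2 + b T + c`.
#' Channels whose fitted quadratic is strictly monotone over `t_range` are
#' flagged monotone; pointwise inversion consults the flag.
#'
#' @param temperatures Numeric vector of calibration temperatures in K
#'   (>= 3 distinct values required).
#' @param band_intensities Matrix `length(temperatures) x n_channels` of raw
#'   band intensities (e.g. from [band_intensity_table()]).
#' @param t_range Validity interval; defaults to the range of `temperatures`.
#' @param channel_names Optional channel names (defaults to the matrix
#'   column names).
#' @param anchors `"global"` (one min/max across all bands — the synthetic
#'   benchmark protocol) or `"per_channel"` (each band's own min/max maps to
#'   0 and 65,535 — the filter-wheel protocol, where every filter image is a
#'   separate full-range camera exposure).
#' @param headroom Fraction of the anchor range kept as margin on both sides
#'   (default 0: the extremes map *exactly* to 0 and 65,535). Device
#'   exposures are set with headroom so scenes slightly outside the
#'   calibrated temperature range still register unclipped signal.
#' @return A `calibration_model`: tibble of coefficients (`channel`, `a`, `b`,
#'   `c`, `monotone`), scaling anchors, and `t_range`.
#' @examples
#' qd <- qd_spectrum_model()
#' bank <- filter_bank_sharp5()
#' temps <- seq(298, 308, by = 0.5)
#' cal <- fit_calibration(temps, band_intensity_table(qd, temps, bank))
#' tidy(cal)
#' @export
fit_calibration <- function(temperatures, band_intensities,
                            t_range = range(temperatures), channel_names = NULL,
                            anchors = c("global", "per_channel"),
                            headroom = 0) {
  anchors <- match.arg(anchors)
  if (length(unique(temperatures)) < 3L) {
    abort("calibration needs at least 3 distinct temperatures")
  }
  bi <- as.matrix(band_intensities)
  if (nrow(bi) != length(temperatures)) {
    abort("band_intensities must have one row per temperature")
  }
  if (is.null(channel_names)) channel_names <- colnames(bi) %||% paste0("ch", seq_len(ncol(bi)))
  if (anchors == "global") {
    i_min <- min(bi); i_max <- max(bi)
  } else {
    i_min <- apply(bi, 2, min); i_max <- apply(bi, 2, max)
  }
  if (any(i_max <= i_min)) abort("degenerate calibration set: constant intensities")
  if (headroom > 0) {
    span <- i_max - i_min
    i_min <- i_min - headroom * span
    i_max <- i_max + headroom * span
  }
  scaled <- sweep(sweep(bi, 2, i_min, "-"), 2, (i_max - i_min) / 65535, "/")

  co <- lapply(seq_len(ncol(scaled)), function(j) {
    y <- scaled[, j]
    if (stats::var(y) == 0) {
      cf <- c(0, 0, y[1])
      flag_degenerate <- TRUE
    } else {
      X <- cbind(temperatures^2, temperatures, 1)
      cf <- unname(qr.solve(X, y))
      flag_degenerate <- FALSE
    }
    # derivative 2 a T + b keeps one sign over t_range <=> monotone
    d1 <- 2 * cf[1] * t_range[1] + cf[2]
    d2 <- 2 * cf[1] * t_range[2] + cf[2]
    tibble(channel = channel_names[j], a = cf[1], b = cf[2], c = cf[3],
           monotone = !flag_degenerate && (d1 * d2 > 0),
           degenerate = flag_degenerate)
  })
  coefs <- dplyr::bind_rows(co)
  if (any(coefs$degenerate)) warn("degenerate (constant) channel flagged in calibration")
  structure(
    list(coefficients = coefs, t_range = as.numeric(t_range),
         scale = list(i_min = unname(i_min), i_max = unname(i_max),
                      anchors = anchors),
         channel_names = channel_names),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %d channels, valid [%g, %g] K\n",
              nrow(x$coefficients), x$t_range[1], x$t_range[2]))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) x$coefficients

#' @rdname fit_calibration
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(
    n_channels = nrow(x$coefficients),
    n_monotone = sum(x$coefficients$monotone),
    t_min = x$t_range[1], t_max = x$t_range[2],
    i_min = x$scale$i_min, i_max = x$scale$i_max
  )
}

#' Scale raw band intensities to the 16-bit grayscale of a calibration
#'
#' Applies the frozen affine anchors of `cal` (calibration-set extremes to 0
#' and 65,535; one global pair or one pair per channel, depending on how the
#' calibration was fitted). Out-of-range inputs map outside `[0, 65535]` and
#' are the caller's responsibility to clip.
#'
#' @param cal A `calibration_model`.
#' @param intensities Numeric raw intensities: a matrix with one column per
#'   channel, or (for per-channel anchors) a vector with `channel` given.
#' @param channel Channel index when `intensities` is a single channel's
#'   vector and the anchors are per-channel.
#' @return Scaled grayscale counts.
#' @export
scale_counts <- function(cal, intensities, channel = NULL) {
  i_min <- cal$scale$i_min; i_max <- cal$scale$i_max
  if (length(i_min) == 1L) {
    return((intensities - i_min) / (i_max - i_min) * 65535)
  }
  if (!is.null(channel)) {
    return((intensities - i_min[channel]) / (i_max[channel] - i_min[channel]) * 65535)
  }
  if (is.null(dim(intensities)) || ncol(intensities) != length(i_min)) {
    abort("per-channel anchors need a matrix with one column per channel (or `channel`)")
  }
  sweep(sweep(intensities, 2, i_min, "-"), 2, (i_max - i_min) / 65535, "/")
}

cal_predict <- function(cal, t, channel) {
  cf <- cal$coefficients[channel, ]
  cf$a * t^2 + cf$b * t + cf$c
}

#' Render a temperature field into a multi-channel fluorescent image
#'
#' Per pixel and channel, evaluates the calibration quadratic
#' `a T^2 + b T + c` and (by default) digitizes it: counts are clipped to
#' `[0, 65535]` and rounded to integers with round-half-even, emulating a
#' 16-bit camera. With `quantize = FALSE` the image is the exact quadratic
#' map (no clipping), so pointwise inversion recovers the field identically;
#' the least-squares fit may then overshoot the digital range by its residual
#' (a fraction of a count).
#'
#' @param field A [temperature_field()].
#' @param cal A `calibration_model`.
#' @param quantize Round to integer counts (default `TRUE`).
#' @param clip How to treat field values outside `cal$t_range`: `"error"`
#'   (default) names the offending pixel; `"clip"` extrapolates the quadratic
#'   and clips counts to the 16-bit range, recording the clipped fraction in
#'   `meta$clip_fraction` (used for extrapolation studies).
#' @return A [fluorescent_image()] with one channel per calibration channel.
#' @export
render_image <- function(field, cal, quantize = TRUE, clip = c("error", "clip")) {
  stopifnot(inherits(field, "temperature_field"), inherits(cal, "calibration_model"))
  clip <- match.arg(clip)
  tv <- field$values
  out_of_range <- tv < cal$t_range[1] | tv > cal$t_range[2]
  if (any(out_of_range) && clip == "error") {
    bad <- which(out_of_range, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "field value %.3f K at pixel (%d, %d) outside calibration range [%g, %g] K",
      tv[bad[1], bad[2]], bad[1], bad[2], cal$t_range[1], cal$t_range[2]
    ))
  }
  nch <- nrow(cal$coefficients)
  ch <- array(0, c(dim(tv), nch))
  clipped <- 0L
  for (j in seq_len(nch)) {
    counts <- cal_predict(cal, tv, j)
    if (quantize || clip == "clip") {
      clipped <- clipped + sum(counts < 0 | counts > 65535)
      counts <- pmin(pmax(counts, 0), 65535)
    }
    if (quantize) counts <- round(counts)  # round-half-even
    ch[, , j] <- counts
  }
  fluorescent_image(ch, cal$channel_names, meta = list(
    source = field$meta, calibration_t_range = cal$t_range,
    quantized = quantize,
    clip_fraction = clipped / (length(tv) * nch)
  ))
}

#' Render a field through the physical emission/filter model
#'
#' Unlike [render_image()], which uses the fitted calibration quadratics as
#' the forward map, this renders through the physics: per pixel, the
#' quantum-dot spectrum at that temperature is integrated over the filter
#' bank and scaled with the calibration's frozen grayscale anchors. The
#' quadratic calibration is then only an *approximation* of this map —
#' exactly the situation of experimental imaging, where reconstruction error
#' includes calibration-model mismatch. Band intensities are evaluated on a
#' fine temperature grid and interpolated linearly per pixel.
#'
#' @param field A [temperature_field()].
#' @param model A [qd_spectrum_model()].
#' @param bank A [filter_bank()].
#' @param cal A `calibration_model` supplying the frozen scale anchors and
#'   channel names.
#' @param quantize Clip to `[0, 65535]` and round to integers (default TRUE).
#' @param n_grid Temperature grid size for the band-integral interpolation.
#' @return A [fluorescent_image()].
#' @export
render_physical <- function(field, model, bank, cal, quantize = TRUE,
                            n_grid = 512L) {
  stopifnot(inherits(field, "temperature_field"), inherits(cal, "calibration_model"))
  tv <- field$values
  lo <- min(tv); hi <- max(tv)
  grid <- if (hi > lo) seq(lo, hi, length.out = n_grid) else c(lo, lo + 1e-6)
  bi <- band_intensity_table(model, grid, bank)
  nch <- ncol(bi)
  ch <- array(0, c(dim(tv), nch))
  for (j in seq_len(nch)) {
    counts <- scale_counts(cal, stats::approx(grid, bi[, j], xout = as.numeric(tv))$y,
                           channel = j)
    if (quantize) counts <- round(pmin(pmax(counts, 0), 65535))
    ch[, , j] <- counts
  }
  fluorescent_image(ch, bank$bands$name, meta = list(
    source = field$meta, forward = "physical", quantized = quantize
  ))
}

#' Add camera noise in the count domain
#'
#' Adds i.i.d. Gaussian noise of `sigma_counts` grayscale counts to every
#' pixel of every channel, then re-clips (and re-quantizes if the image is
#' quantized) — the read-noise model for camera frames, as opposed to the
#' temperature-domain noise of [add_temperature_noise()]. Because emission
#' quenches with temperature, fixed count noise translates into *larger*
#' temperature errors where the scene is hot.
#'
#' @param image A [fluorescent_image()].
#' @param sigma_counts Noise standard deviation in counts (>= 0).
#' @param seed Integer seed.
#' @param mask Optional logical matrix: noise only applied inside the mask
#'   (background stays exactly at its floor).
#' @return A new [fluorescent_image()].
#' @export
add_count_noise <- function(image, sigma_counts, seed, mask = NULL) {
  stopifnot(inherits(image, "fluorescent_image"))
  if (sigma_counts < 0) abort("`sigma_counts` must be non-negative")
  if (sigma_counts == 0) return(image)
  ch <- image$channels
  noise <- with_seed(seed, rnorm(length(ch), 0, sigma_counts))
  noise <- array(noise, dim(ch))
  if (!is.null(mask)) noise <- noise * array(mask, dim(ch))
  ch <- ch + noise
  ch <- pmin(pmax(ch, 0), 65535)
  if (isTRUE(image$meta$quantized)) ch <- round(ch)
  out <- image
  out$channels <- ch
  out$meta$count_noise <- list(sigma_counts = sigma_counts, seed = seed)
  out
}

# Invert one channel's quadratic for a vector of counts: closed-form root
# selection within (a slightly extended) t_range. Returns NA where no real
# root lands in range.
invert_channel <- function(cal, counts, channel, slack = 0.5) {
  cf <- cal$coefficients[channel, ]
  lo <- cal$t_range[1] - slack; hi <- cal$t_range[2] + slack
  if (abs(cf$a) < .Machine$double.eps * max(1, abs(cf$b))) {
    if (cf$b == 0) return(rep(NA_real_, length(counts)))
    return(pmin(pmax((counts - cf$c) / cf$b, lo), hi))
  }
  disc <- cf$b^2 - 4 * cf$a * (cf$c - counts)
  disc[disc < 0] <- NA
  r1 <- (-cf$b + sqrt(disc)) / (2 * cf$a)
  r2 <- (-cf$b - sqrt(disc)) / (2 * cf$a)
  in1 <- !is.na(r1) & r1 >= lo & r1 <= hi
  in2 <- !is.na(r2) & r2 >= lo & r2 <= hi
  out <- ifelse(in1, r1, ifelse(in2, r2, NA_real_))
  # both in range (can happen near the vertex): pick the root on the branch
  # where the channel was flagged monotone, i.e. nearest the range centre
  both <- in1 & in2
  if (any(both)) {
    mid <- mean(cal$t_range)
    out[both] <- ifelse(abs(r1[both] - mid) <= abs(r2[both] - mid), r1[both], r2[both])
  }
  out
}

#' Invert an image to temperature pixel by pixel
#'
#' The pointwise oracle/baseline: each monotone channel's quadratic is
#' inverted in closed form (root selection within the validity range) and the
#' per-channel temperature estimates are combined by least squares (their
#' mean). Values are clamped to `cal$t_range`.
#'
#' @param image A [fluorescent_image()].
#' @param cal The `calibration_model` the image was rendered with.
#' @param channels Optional integer/character subset of channels to use;
#'   defaults to all monotone-flagged channels.
#' @return A [temperature_field()] of recovered temperatures.
#' @export
pointwise_invert <- function(image, cal, channels = NULL) {
  stopifnot(inherits(image, "fluorescent_image"), inherits(cal, "calibration_model"))
  if (is.null(channels)) {
    channels <- which(cal$coefficients$monotone)
    if (length(channels) == 0L) {
      abort("no monotone channel available; pass `channels` explicitly")
    }
  } else if (is.character(channels)) {
    channels <- match(channels, cal$channel_names)
  }
  d <- dim(image$channels)
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (j in channels) {
    est <- invert_channel(cal, as.numeric(image$channels[, , j]), j)
    ok <- !is.na(est)
    acc[ok] <- acc[ok] + est[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  if (any(cnt == 0)) abort("some pixels could not be inverted on any selected channel")
  est <- acc / cnt
  est <- pmin(pmax(est, cal$t_range[1]), cal$t_range[2])
  temperature_field(est, pitch_um = 1, meta = list(
    generator = "pointwise_invert", channels_used = cal$channel_names[channels]
  ))
}

#' Bin camera pixels
#'
#' Replaces each `factor x factor` block by its mean (re-quantized with
#' round-half-even), improving signal-to-noise at the cost of resolution; the
#' device pipeline uses factor 4. A trailing remainder that does not fill a
#' block is cropped (with a warning).
#'
#' @param image A [fluorescent_image()].
#' @param factor Positive integer binning factor.
#' @param quantize Re-quantize binned counts (default follows the image meta).
#' @return A binned [fluorescent_image()].
#' @export
bin_pixels <- function(image, factor = 4L, quantize = NULL) {
  stopifnot(inherits(image, "fluorescent_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) abort("`factor` must be a positive integer")
  if (factor == 1L) return(image)
  d <- dim(image$channels)
  nr <- (d[1] %/% factor) * factor
  nc <- (d[2] %/% factor) * factor
  if (nr < d[1] || nc < d[2]) {
    warn(sprintf("cropping %d row(s), %d column(s) not filling a %dx%d block",
                 d[1] - nr, d[2] - nc, factor, factor))
  }
  if (is.null(quantize)) quantize <- isTRUE(image$meta$quantized)
  out <- array(0, c(nr %/% factor, nc %/% factor, d[3]))
  for (j in seq_len(d[3])) {
    x <- image$channels[seq_len(nr), seq_len(nc), j]
    # block mean via two successive within-group means
    xr <- rowsum(x, rep(seq_len(nr %/% factor), each = factor)) / factor
    xc <- t(rowsum(t(xr), rep(seq_len(nc %/% factor), each = factor)) / factor)
    if (quantize) xc <- round(xc)
    out[, , j] <- xc
  }
  fluorescent_image(out, image$channel_names, meta = c(
    image$meta, list(binned_by = factor)
  ))
}
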