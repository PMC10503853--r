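#' Parametric quantum-dot emission model
#'
#' A Gaussian-line surrogate for the temperature-dependent emission of
#' CdSe/ZnS quantum dots: the peak red-shifts linearly with temperature, the
#' line broadens linearly, and the integrated intensity quenches by a fixed
#' *fraction per kelvin* (exponential in temperature, `exp(-q (T - T_ref))`),
#' so emission — and with it the temperature sensitivity dI/dT — fades as
#' the probe heats, the behaviour observed in device calibration data.
#' Users with measured spectra can bypass this model via
#' [read_spectral_table()].
#'
#' @param peak_nm_ref Emission peak at the reference temperature (nm).
#' @param peak_shift_nm_per_k Linear red-shift coefficient (nm/K).
#' @param fwhm_nm_ref Full width at half maximum at the reference (nm).
#' @param fwhm_broadening_nm_per_k Linear FWHM broadening (nm/K).
#' @param quench_per_k Fractional loss of integrated intensity per K.
#' @param t_ref Reference temperature (K).
#' @param t_valid Temperature interval over which the model is declared valid.
#' @return A `qd_spectrum_model` object.
#' @examples
#' m <- qd_spectrum_model()
#' s <- emission_spectrum(m, 298)
#' s$wavelength_nm[which.max(s$intensity)]
#' @export
qd_spectrum_model <- function(peak_nm_ref = 620, peak_shift_nm_per_k = 0.1,
                              fwhm_nm_ref = 30, fwhm_broadening_nm_per_k = 0.05,
                              quench_per_k = 0.01, t_ref = 298,
                              t_valid = c(280, 400)) {
  m <- list(
    peak_nm_ref = peak_nm_ref, peak_shift_nm_per_k = peak_shift_nm_per_k,
    fwhm_nm_ref = fwhm_nm_ref, fwhm_broadening_nm_per_k = fwhm_broadening_nm_per_k,
    quench_per_k = quench_per_k, t_ref = t_ref, t_valid = as.numeric(t_valid)
  )
  fw_lo <- fwhm_nm_ref + fwhm_broadening_nm_per_k * (t_valid - t_ref)
  if (any(fw_lo <= 0)) abort("FWHM must stay positive over t_valid")
  structure(m, class = "qd_spectrum_model")
}

#' Evaluate the emission spectrum at one temperature
#'
#' @param model A [qd_spectrum_model()].
#' @param t Temperature in K (must lie in `model$t_valid`).
#' @param wavelengths_nm Strictly increasing wavelength grid (nm).
#' @return A tibble with columns `wavelength_nm` and `intensity`
#'   (per-nm spectral density; nonnegative).
#' @export
emission_spectrum <- function(model, t, wavelengths_nm = seq(480, 780, by = 0.5)) {
  stopifnot(inherits(model, "qd_spectrum_model"))
  if (t < model$t_valid[1] || t > model$t_valid[2]) {
    abort(sprintf("temperature %.2f K outside model validity [%g, %g] K",
                  t, model$t_valid[1], model$t_valid[2]))
  }
  if (any(diff(wavelengths_nm) <= 0)) abort("wavelength grid must be strictly increasing")
  dt <- t - model$t_ref
  peak <- model$peak_nm_ref + model$peak_shift_nm_per_k * dt
  fwhm <- model$fwhm_nm_ref + model$fwhm_broadening_nm_per_k * dt
  area <- exp(-model$quench_per_k * dt)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  inten <- area / (sigma * sqrt(2 * pi)) * exp(-(wavelengths_nm - peak)^2 / (2 * sigma^2))
  tibble(wavelength_nm = wavelengths_nm, intensity = inten)
}

#' Spectral filter bank
#'
#' A set of band-pass / long-pass filters with optional logistic edge roll-off.
#' `edge_softness_nm = 0` gives ideal sharp cut-offs; positive values give the
#' gradual transitions of real interference filters (neighbouring pass-bands
#' then overlap).
#'
#' @param bands A data frame (or tibble) with columns `name`, `kind`
#'   (`"band-pass"` or `"long-pass"`), `center_nm` (cut-on wavelength for
#'   long-pass), `fwhm_nm` (ignored for long-pass), `edge_softness_nm`.
#' @return A `filter_bank` object.
#' @export
filter_bank <- function(bands) {
  bands <- as_tibble(bands)
  need <- c("name", "kind", "center_nm", "fwhm_nm", "edge_softness_nm")
  if (!all(need %in% names(bands))) {
    abort(paste("`bands` must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(bands$kind %in% c("band-pass", "long-pass"))) {
    abort("kind must be 'band-pass' or 'long-pass'")
  }
  structure(list(bands = bands), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands\n", nrow(x$bands)))
  print(x$bands)
  invisible(x)
}

#' Five sharp spectral bands for the synthetic benchmark
#'
#' Five contiguous ideal band-pass filters (15 nm wide, centred 590-650 nm)
#' with perfectly sharp edges, tiling the quantum-dot emission line.
#'
#' @return A [filter_bank()].
#' @export
filter_bank_sharp5 <- function() {
  centers <- c(590, 605, 620, 635, 650)
  filter_bank(tibble(
    name = paste0("band", seq_along(centers), "_", centers, "nm"),
    kind = "band-pass", center_nm = centers, fwhm_nm = 15, edge_softness_nm = 0
  ))
}

#' Six-filter bank of the imaging device
#'
#' The filter-wheel complement used on the microfluidic-chip scenes: a 550 nm
#' long-pass plus five band-passes (650/40, 660/10, 650/10, 640/10, 620/10,
#' quoted as centre +/- half-width FWHM). Soft logistic edges give the
#' overlapping pass-bands characteristic of real interference filters.
#'
#' @param edge_softness_nm Logistic roll-off scale in nm (default 2).
#' @return A [filter_bank()].
#' @export
filter_bank_device6 <- function(edge_softness_nm = 2) {
  filter_bank(tibble(
    name = c("lp550", "bp650w40", "bp660w10", "bp650w10", "bp640w10", "bp620w10"),
    kind = c("long-pass", rep("band-pass", 5)),
    center_nm = c(550, 650, 660, 650, 640, 620),
    fwhm_nm = c(NA, 40, 10, 10, 10, 10),
    edge_softness_nm = edge_softness_nm
  ))
}

# Transmission of one band at the given wavelengths, in [0, 1].
band_transmission <- function(band, wavelengths_nm) {
  s <- band$edge_softness_nm
  if (band$kind == "long-pass") {
    if (s <= 0) return(as.numeric(wavelengths_nm >= band$center_nm))
    return(stats::plogis((wavelengths_nm - band$center_nm) / s))
  }
  lo <- band$center_nm - band$fwhm_nm / 2
  hi <- band$center_nm + band$fwhm_nm / 2
  # sharp pass-bands are half-open [lo, hi) so banks that tile a support
  # never double-count a shared cut-off wavelength
  if (s <= 0) return(as.numeric(wavelengths_nm >= lo & wavelengths_nm < hi))
  stats::plogis((wavelengths_nm - lo) / s) * stats::plogis((hi - wavelengths_nm) / s)
}

#' Integrate a spectrum over a filter bank
#'
#' Per band, the trapezoidal integral of spectrum x transmission over the
#' spectrum's wavelength support. An empty spectral overlap yields zero
#' intensity with a warning (not an error).
#'
#' @param spectrum A tibble with `wavelength_nm` and `intensity` (e.g. from
#'   [emission_spectrum()]).
#' @param bank A [filter_bank()].
#' @return Named numeric vector of raw band intensities (one per band).
#' @export
band_integrate <- function(spectrum, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  wl <- spectrum$wavelength_nm
  iy <- spectrum$intensity
  out <- vapply(seq_len(nrow(bank$bands)), function(b) {
    tr <- band_transmission(bank$bands[b, ], wl)
    trapz_integral(wl, iy * tr)
  }, numeric(1))
  names(out) <- bank$bands$name
  if (any(out == 0)) {
    warn("one or more bands have zero overlap with the spectrum")
  }
  out
}

trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Band intensities across a set of temperatures
#'
#' Convenience wrapper: evaluates the emission model at each temperature and
#' integrates it over the bank, returning the raw (unscaled) intensity matrix
#' used for calibration fitting.
#'
#' @param model A [qd_spectrum_model()].
#' @param temperatures Numeric vector of temperatures (K).
#' @param bank A [filter_bank()].
#' @param wavelengths_nm Wavelength grid.
#' @return Matrix `length(temperatures) x n_bands` with band-name columns.
#' @export
band_intensity_table <- function(model, temperatures, bank,
                                 wavelengths_nm = seq(480, 780, by = 0.5)) {
  rows <- lapply(temperatures, function(t) {
    band_integrate(emission_spectrum(model, t, wavelengths_nm), bank)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a measured spectral table
#'
#' Loads a CSV with a `wavelength_nm` column followed by one intensity column
#' per temperature; column names after the first must parse as temperatures in
#' K (a leading "T" is allowed, e.g. `T298`).
#'
#' @param path CSV file path.
#' @return A list with `wavelength_nm`, `temperatures` and `intensity`
#'   (matrix wavelengths x temperatures).
#' @export
read_spectral_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") abort("first column must be 'wavelength_nm'")
  temps <- as.numeric(sub("^[Tt]", "", names(df)[-1]))
  if (any(is.na(temps))) abort("temperature columns must parse as numbers")
  list(
    wavelength_nm = df[[1]],
    temperatures = temps,
    intensity = as.matrix(df[, -1, drop = FALSE])
  )
}
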