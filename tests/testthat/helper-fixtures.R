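# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fix_qd <- function() fixture("qd", function() qd_spectrum_model())

fix_bank5 <- function() fixture("bank5", function() filter_bank_sharp5())

fix_cal5 <- function() fixture("cal5", function() {
  temps <- seq(298, 308, by = 0.5)
  fit_calibration(temps, band_intensity_table(fix_qd(), temps, fix_bank5()),
                  t_range = c(298, 308))
})

fix_pipe_field <- function() fixture("pipe_field", function() {
  spec <- field_spec("pipe_cross_section", shape = c(24, 24),
                     t_range = c(298, 308), r_inner_px = 5, r_outer_px = 10,
                     t_inner = 308, t_outer = 298)
  generate_pipe_field(spec)
})

fix_image <- function() fixture("image", function() {
  render_image(fix_pipe_field(), fix_cal5(), quantize = TRUE)
})

# A tiny random multichannel image on the count scale, deterministic.
rand_image <- function(nr = 8, nc = 9, ch = 3, seed = 1) {
  set.seed(seed)
  fluorescent_image(array(runif(nr * nc * ch, 0, 65535), c(nr, nc, ch)))
}

rand_field <- function(nr = 8, nc = 9, seed = 2, lo = 298, hi = 308) {
  set.seed(seed)
  temperature_field(matrix(runif(nr * nc, lo, hi), nr, nc))
}
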