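---
title: "Patch-recurrent fluorescence thermometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-recurrent fluorescence thermometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fluorotherm)
```

## The problem

Fluorescence thermometry infers temperature from the temperature-dependent
emission of a fluorescent probe — here CdSe/ZnS quantum dots, whose emission
line red-shifts, broadens and quenches as the probe warms. Imaging that
emission through a set of spectral filters gives a multi-channel grayscale
image in which every pixel's channel vector encodes the local temperature.
Classical practice inverts that encoding pixel by pixel (a polynomial fit of
temperature against channel intensities), which caps accuracy near the
per-pixel noise level. The premise of the patch-recurrent approach is that
temperature fields in real devices obey steady heat diffusion and are
therefore spatially smooth, so a model that reads a *run of neighbouring
pixels* can average out per-pixel noise without blurring real structure —
recovering temperatures more accurate than any single pixel supports.

`fluorotherm` packages the whole study pipeline: a synthetic forward model
(ground-truth fields, quantum-dot photophysics, filter banks, 16-bit camera
rendering), the family of recurrent inverse models, classical baselines, and
the evaluation harness (reconstruction error, extrapolation, error-gradient
analysis, chip range sweeps).

## Forward model

### Temperature fields

Two generator families, both exact solutions of the steady heat equation:

* **Annulus (pipe cross-section)** — the closed-form conduction profile
  through a pipe wall, `T(r) = T_i + (T_o − T_i)·ln(r/r_i)/ln(r_o/r_i)`,
  constant inside `r_i` and outside `r_o`. An optional sinusoidal Dirichlet
  modulation (default amplitude 1 K, period 16 px, decaying over ~3 rows)
  on the top/bottom boundary rows recreates periodic edge features, which
  are the hardest pixels to reconstruct.
* **Finite-difference plates** — the 5-point-stencil discrete Laplace
  equation on a rectangle with per-edge Dirichlet or insulated (mirror)
  boundaries and optional interior fixed-temperature heater lines, solved
  directly as a sparse linear system (`Matrix`); the maximum interior
  residual is checked against a tolerance (default 1e−6 K) after solving.
  This family also provides the microfluidic-chip surrogate: all four edges
  at a shell temperature, two vertical heater lines inside.

Pixel pitch defaults to 1 µm so gradient maps read directly in K/µm
(100 µm for chip scenes); grids are row-major, `[row, col]`, 1-based.

Sensor noise is modelled as pixelwise i.i.d. Gaussian noise of standard
deviation 0.1 K added to the *temperature* map before any optics, matching
the ordering of the modelled acquisition pipeline (noise on T, then rendering).

### Photophysics and rendering

Measured quantum-dot spectra are replaced by a parametric Gaussian-line
surrogate: peak 620 nm at the 298 K reference, red-shift 0.1 nm/K, FWHM
30 nm broadening at 0.05 nm/K, and quenching of the integrated intensity by
a fixed fraction per kelvin — `exp(−q·(T − T_ref))` with `q = 0.01 /K`, the
~1 %/K intensity sensitivity typical of quantum-dot thermometry.
Exponential (rather than linearized) quenching matters beyond small
windows: it keeps intensity positive over the 290–380 K chip envelope and
makes the temperature sensitivity `|dI/dT| ∝ I` *fall* as the probe heats,
which is what device calibration curves show and what drives the growth of
chip reconstruction error with scene temperature range. Users with measured
spectra can load them from CSV (`read_spectral_table()`) instead. Two filter banks are built in: five sharp
contiguous 15 nm band-passes (the synthetic benchmark) and the six-filter
device complement (550 nm long-pass plus 650/40, 660/10, 650/10, 640/10,
620/10 band-passes) with logistic roll-off edges (default scale 2 nm) that
produce genuinely overlapping pass-bands. Sharp pass-bands are treated as
half-open intervals so banks that tile a support never double-count a
shared cut-off wavelength.

Band intensities are trapezoidal integrals of spectrum × transmission.
Calibration follows the frozen-anchor protocol: extreme raw intensities
over the calibration set map affinely to grayscale 0 and 65,535, then each
channel gets a least-squares quadratic in temperature, with a monotonicity
flag (sign of `2aT + b` over the validity range) that pointwise inversion
consults. Two anchor conventions exist: *global* (one min/max across all
bands — the synthetic benchmark protocol, exact anchors) and *per-channel*
(each band's own extremes to 0/65,535 — the filter-wheel protocol, since
every filter image is a separate full-range camera exposure), optionally
with an exposure-headroom margin so scenes slightly outside the calibrated
operating points still register unclipped signal; chip calibrations default
to per-channel anchors with 15 % headroom. Rendering evaluates the quadratic per pixel;
**digitization** (clipping to `[0, 65535]` and round-half-even integer
quantization) is applied when `quantize = TRUE` (the default) or when
rendering out-of-range temperatures with `clip = "clip"`. An unquantized
render is deliberately the exact quadratic map — the least-squares fit can
overshoot the anchors by its residual (a fraction of a count), and treating
that overshoot as part of digitization keeps the render→invert round trip an
identity, which is the package's internal consistency oracle.

Pointwise inversion solves each monotone channel's quadratic in closed form
(root selection within the validity range) and combines channels by least
squares (their mean), clamping to the validity range. 4×4 pixel binning
(block means, re-quantized) mirrors the device's signal-to-noise binning.

### Chip scenes

A `chip_scene` bundles a solved heater field, a boustrophedon serpentine
channel mask (the only pixels holding quantum dots), and a simulated
thermocouple snapped to the nearest channel pixel. The scene's field is the
*clean* solution — the model-derived ground truth, in the role the
validated multiphysics model plays for a real device — while the rendered
image comes from a noisy copy, so reconstruction is genuinely scored
against information the image does not contain exactly. Rendering zeroes
everything outside the mask (background floor configurable, default 0 — the
masking step applied to camera frames; a real background level is unknown, so
zero is the assumption, not a measurement).

Chip images go through the **physical** forward map (`render_physical()`):
spectrum → band integrals → frozen anchors → counts. The analyst's quadratic
calibration, fitted from *only* the probe pixel across the heater series —
the single location where temperature and fluorescence are both known — is
then an approximation of that map, and its mismatch is part of the error
budget, exactly as in experimental work. (The synthetic benchmark instead
renders *from* the quadratics, as its protocol states, which is why its
render→invert round trip is exact.) Chip sensor noise lives in the *count*
domain (default 50 counts inside the mask, a read-noise scale chosen so the
near-ambient scene reconstructs at the few-hundredths-of-a-kelvin level):
temperature-domain noise would pass through inversion unchanged and make
every scene equally hard, whereas count noise interacts with the quenching
physics — hot scenes have dimmer, flatter channels, so fixed count noise
costs more kelvin. That interaction, not any tuned threshold, produces the
monotone growth of mask-aware RMSE with scene temperature span.

The default heater series uses excesses of 1–80 K over a 293 K ambient with
the shell warming at 35 % of the heater excess, producing scene spans from
about 0.7 K to about 52 K inside the declared 290–380 K envelope — chosen to
give a ladder of scene spans from near-isothermal to several tens of
kelvin, the regime in which error growth becomes visible. Chip patch pools keep only patches fully
inside the channel (`mask_only`): outside it there is no fluorescence, and
zero-signal patches carry no temperature information. Reconstruction on chip
scenes is likewise mask-restricted (`patch_mask`), with partial stitching
and scoring over covered channel pixels. The error–gradient association is
quantified as the Spearman rank correlation of (|error|, gradient norm)
pairs pooled across the whole heater series: the claim being tested is that
scenes with steeper thermal gradients reconstruct worse, which is a
between-scene statement; within one scene a pointwise reconstructor has no
gradient-localised error component.

## Inverse models

All three recurrent variants share one trunk: two stacked LSTM layers
(hidden sizes `hidden1` then `hidden2`; reference sizes 1024/612) and a
fully connected head with 0.2 dropout (training only) mapping each
position's `hidden2`-dim feature to one temperature. Gate parameterisation
is the standard 4-gate LSTM, `4·(n_in + H + 1)·H` parameters per layer
(8,226,869 total for the reference one-directional network on 5 channels).

* **FTLSTM** scans a 1×5 pixel sequence left→right; output is the 5
  corresponding temperatures.
* **BFTLSTM** runs two *headless* cores over the sequence and its reversal,
  re-aligns the reverse features by source position, fuses by elementwise
  addition, then applies the head. Fusion by addition (not concatenation)
  is a deliberate architectural choice: it keeps the head input at `hidden2` dimensions.
* **MFTLSTM** takes a 5×5 tile; each row and each column passes through a
  headless bidirectional core; row-scan and column-scan features are aligned
  by source pixel — the only arrangement in which "concatenate the row
  results, concatenate the column results, add pointwise" is dimensionally
  and semantically coherent — added, and mapped pixel-wise by the head,
  yielding a 5×5 temperature tile.

Design points the source text leaves open, decided here:

* Directional/orientational cores have **independent weights** by default
  (most expressive, consistent with "separate" cores); `tie_directions` /
  `tie_orientations` share them, which the symmetry diagnostics use
  (palindrome inputs → palindrome outputs; tile transposition commutes).
* The head is shared across positions (612 + 1 parameters), not one
  flattened 25·612→25 map; `flat_head = TRUE` switches to the flattened
  variant for comparison.
* The reverse scan is aligned **by source position** before fusion.

Training (the optimizer is an implementation choice; these are conventional
settings, all exposed): Adam on MSE over kelvin
targets, learning rate 1e−3 (the desk-scale trials below use 1e−2 then a
2e−3 polish), batch 256, early stopping on validation RMSE with patience 10.
Targets are standardized internally by the train-set mean/sd (stored in the
model, inverted on output) so optimization is independent of the kelvin
offset. Train/validation splits are always at the **whole-image level**:
stride-1 patches overlap so heavily that patch-level splits would leak the
validation answers into training.

Baselines: the multivariate polynomial fit (all `choose(C+2,2)` monomials of
total degree ≤ 2 in the channel intensities, least squares, minimum-norm on
rank-deficient designs — which these designs are, since the channels live on
a one-dimensional temperature curve) and a random forest (`ranger`; 200
trees, unlimited depth, √C feature subsampling, fixed seed).

## Patches and stitching

Model inputs are dense stride-1 windows — every 1×5 horizontal run, every
5×5 tile — normalized to `[0, 1]` by the 16-bit full scale; no padding, so
windows lie fully inside the image (edge pixels are still covered by
windows that touch them). Reconstruction stitches per-patch predictions by
per-pixel averaging over all covering patches (coverage counts retained;
uncovered pixels are an error). Dense extraction both maximizes training
data from limited images (the rationale for short 5-pixel runs) and smooths
stitching seams. Optional target centering (subtract the window midpoint)
exists but is off by default; the internal train-time standardization
subsumes it.

## What the generator does and does not emulate

The generator reproduces: heat-equation-smooth fields; 0.1 K temperature
noise ahead of rendering; five sharp vs six overlapping spectral bands;
frozen 0/65,535 anchors with quadratic calibration; 16-bit quantization;
serpentine masking and single-probe calibration; heater series with rising
spans. It does **not** emulate: camera shot/read noise in the intensity
domain (an optional toggle exists, default off), optics (PSF, vignetting),
photobleaching, flow in the channel, or the true (unpublished) quantum-dot
spectra — so passing tests demonstrate the *method's* behaviour under the
stated statistical structure, not performance on any particular instrument.

One generator condition deserves emphasis. The benchmark's premise —
recurrent reconstruction RMSE *below* the 0.1 K injected noise — is only
physically possible when per-pixel temperature steps are small against that
noise (otherwise any averaging
blurs real structure faster than it removes noise; a 10 K swing across a
48 px image is already in that hostile regime, where even an oracle 3×3
smoother makes pointwise inversion worse). The defaults therefore draw each
scene's wall-temperature span from 2–6 K with scene midpoints covering the
full 298–308 K window: individual fields are smoothness-dominated while the
dataset spans the whole range. This regime is fixed once as the
benchmark's study condition, not a tuning knob.

## Numerical choices

* Finite-difference solves are direct sparse solves; the residual check
  (not iteration count) is the convergence contract. Insulated edges use
  mirror ghosts, which simply drop out of the stencil.
* Round-half-even quantization (R's `round`), matching camera ADC practice.
* Quadratic inversion picks the root inside the (slightly slack-extended)
  validity range; if both roots land inside — possible near the vertex of a
  non-monotone channel — the root nearer the range centre wins.
* Gradient maps: central differences interior, one-sided at borders,
  divided by pitch.
* Spearman rank correlation for the error-gradient association (the
  association is monotone, not linear, so a rank statistic is the honest
  summary); a constant error or gradient map is reported as
  undefined rather than NaN.
* All randomness flows through explicit integer seeds; library code saves
  and restores the session RNG state, and child seeds are derived from the
  master seed (always below 2³¹).

## Desk-scale problem sizes

The reference architecture (1024/612 hidden, millions of parameters,
dense patches from large image sets) is far beyond what a single-CPU R
session can train in minutes, so the package's experiments and tests run a
scaled-down replica chosen once: 40 images of 48×48 px, hidden sizes 32/16,
8,000 training sequences / 3,500 training tiles, a 40-epoch 1e−2 Adam phase
plus a 15-epoch 2e−3 polish (batch 256 for sequence models, 96 for the tile
model — the tile model sees fewer samples per epoch, so smaller batches keep
its optimizer step count comparable). `benchmark_ordering_trial()` packages
one such trial end to end. At this scale the qualitative results of the
full-size study reproduce — reconstruction RMSE ordering multi-directional ≤
bidirectional ≤ one-directional < polynomial fit, multi-directional
validation RMSE below the 0.1 K noise, extrapolation degradation, chip-span
error growth — while absolute RMSEs (0.07–0.10 K here) remain above what
full-scale training of the reference architecture would deliver: fewer
parameters, less data, fewer epochs. Matching any particular instrument's
absolute accuracy is out of scope — that depends on the real probe spectra
and device thermal model.

## Known limitations

* Pure-R training: correct (gradient-checked against numerical
  differentiation) but slow; the reference architecture is constructable
  and runs forward passes, yet training it to convergence is impractical
  here.
* The quadratic calibration is a good local model over 10 K but a mediocre
  one over 90 K; that mismatch is real physics (it drives the chip
  range-sweep error growth) but also means chip-scale absolute accuracy is
  bounded by the calibration family, not the networks.
* Sequence models only scan horizontally; vertically anisotropic structure
  is handled well only by the multi-directional variant.
* The FD chip surrogate has Dirichlet shells, not convective boundaries;
  fields near the chip edge are stiffer than a conjugate-heat-transfer
  solution would give.
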