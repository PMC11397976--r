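---
title: "Fluorescence-based canopy segmentation and index imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence-based canopy segmentation and index imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyscope)
```

## The measurement problem

Multispectral top-view imaging in controlled-environment agriculture produces,
per sample, a stack of co-registered 8-bit grayscale frames: one per
illumination waveband (blue, green, red, near-infrared) plus a chlorophyll
fluorescence frame (`cfi`) captured under blue excitation through a >650 nm
long-pass filter. Pixel intensity is the proxy of reflectance; on the `cfi`
frame only chlorophyll-bearing tissue re-emits, so plants are bright and
everything else — substrate, pot, bench — is dark. That optical contrast is
what this package exploits: the fluorescence frame is segmented into plant and
background, and every downstream quantity (projected canopy area, per-pixel
normalized-difference indices and their statistics) is computed only on the
plant foreground.

## Segmentation model

The fluorescence intensity histogram of such a frame is bimodal: a dark
background mode and a bright plant mode. The canopy mask is obtained by

1. optionally median-filtering the frame (3×3) to suppress isolated hot
   pixels (off by default; the size filter in step 4 handles most artifacts),
2. finding the *valley threshold*: the argmin of the smoothed histogram over
   an intensity interval `[lo, hi]` that brackets the valley between the two
   modes,
3. binarizing with the strict rule *foreground ⇔ intensity > t*, and
4. *despeckling*: removing connected components smaller than
   `min_component_px` pixels.

The bounds `[lo, hi]` can be set manually (they always take precedence) or
derived automatically as the positions of the two leftmost local maxima of
the smoothed histogram whose topographic prominence is at least
`min_prominence_frac` (default 0.05) of the tallest smoothed bin. When fewer
than two prominent peaks exist — a blank scene, or a canopy filling the whole
frame — automatic detection refuses with an error rather than guessing, and
the user must supply manual bounds.

### Numerical conventions

Several choices in step 2–4 are underdetermined by the physics and are fixed
project-wide for determinism and auditability (the `threshold_result` records
the method, bounds, peaks and smoothed counts used):

* **Smoothing.** Centered moving average, default window 5 bins, edges padded
  by replicating the boundary bin. The argmin is taken on the *smoothed*
  counts; raw fluorescence histograms routinely contain empty bins anywhere
  in the valley, and an argmin on raw counts would lock onto the first of
  them.
* **Tie-break.** Equal minima resolve to the lowest intensity. Together with
  the strict `>` at the threshold (the threshold bin itself is background)
  this biases toward slightly larger plant masks and makes the
  threshold/mask pair fully deterministic.
* **Connectivity.** Despeckling defaults to 8-connectivity, the permissive
  convention under which a diagonal chain of pixels is one object;
  4-connectivity is available where diagonal bridges should not rescue
  speckles.
* **Pixel grid.** Row-major, origin top-left, `(row, col)` indexing.

## Index imaging

A normalized-difference index over bands `a`, `b` is
`(R_a − R_b) / (R_a + R_b)`, evaluated per pixel on the plant foreground
only. Built-ins are NDVI (`a = nir`, `b = red`), which rises with chlorophyll
("greenness"), and NDAI (`a = red`, `b = green`) for anthocyanin
pigmentation. The NDAI band order and sign convention in the literature vary;
here the convention is the one under which anthocyanin-rich tissue (high red,
low green reflectance) scores positive, and both bands of any index are fully
configurable, so users can match whichever published convention they need.

Pixels where both bands read zero have no defined ratio; they are flagged
invalid and excluded from every statistic, never assigned 0 — an undefined
pixel must not dilute a canopy mean. All defined values lie in `[−1, 1]` by
construction.

Canopy statistics are the mean and the **population** standard deviation over
valid pixels (the canopy's pixels are the entire population of interest, not
a sample from it), plus a histogram with 200 fixed bins of width 0.01 on
`[−1, 1]`, right edge inclusive only in the final bin so that a value of
exactly 1 lands in `[0.99, 1.00]`. Projected canopy area is
`foreground pixel count × cm_per_pixel²`. False-color renderings map
`[−1, 1]` linearly onto a perceptually uniform palette (default viridis,
dark at −1) with background black, and a color-bar legend is written
alongside every rendering.

## Gray-card exposure calibration

Cross-band intensity comparisons are only meaningful if each band images a
50%-reflectance gray card at the same mid-scale level. Calibration drives the
mean card intensity to 127 (the 8-bit midpoint) by fixed-point iteration of
the linear-sensor update `e ← e · 127 / mean(card)`, with tolerance ±1
intensity level and at most 10 proposals. A saturated reading (mean 255)
carries no usable scale information, so the exposure is halved — with a
warning — until the sensor leaves saturation, and only then do linear
proposals resume; the `iterations` field counts linear proposals, keeping it
a meaningful measure of model convergence regardless of how deep into
saturation the starting exposure was. For an exactly linear sensor the
update lands within quantization of the fixed point after one proposal (two
when the starting reading is so small that its rounding error matters); for
a mild gamma nonlinearity (`mean ∝ e^0.9`) the log-scale error contracts by
a factor of 10 per proposal, so convergence within 10 proposals is
guaranteed in practice. Capture backends are any user function
`exposure_ms → image`: a real camera driver, the included
`simulated_camera()` (linear or gamma, used by the validation suite), or
`folder_capture()`, which replays an archived exposure series from disk.

## Batch pipeline

`run_batch()` walks the immediate sub-folders of a root directory in
lexicographic order and, per sample: loads the configured bands, segments,
measures area, computes every configured index, and writes `mask.png`,
`<index>.png` (+ legend) and `<index>_hist.csv`, appending one row to
`results.csv`. A folder that fails (missing fluorescence frame, mismatched
dimensions, unreadable file) produces a row whose `error` column carries the
message; it never aborts the batch. Reals are written to the CSV at 6
significant digits; the data frame returned in R keeps full precision.

The configuration file is YAML — the natural configuration format in the R
ecosystem — with keys mirroring the function arguments
(`cm_per_pixel`, `bands`, `segmentation`, `indices`, `colormap`,
`exposures`). Calibration results can be persisted into the same file so an
analysis run records its acquisition state. Scheduling and upload are
deliberately out of scope: the tool processes whatever folders exist when it
runs.

## The synthetic scene generator

Real deposited plant images are not required for validation: the generator
builds scenes with *exact* ground truth that reproduce the statistical
structure the segmentation assumes — a dark background and bright plant in
the fluorescence channel (bimodal histogram), constant per-region
reflectance per band, optional additive Gaussian sensor noise (applied
independently per band, then rounded, then clipped to `[0, 255]`, in that
fixed order), and small bright background speckles placed by rejection
sampling with a one-pixel margin so they can never merge with the plant and
the ground-truth mask stays exact. Ground truth (mask, pixel count, area,
noiseless index value per sub-region) is computed before noise and speckles
are applied. A senescence variant gives the plant a sub-ellipse with its own
band intensities, producing a canopy with two exact index levels — the
two-peaked index histogram characteristic of a senescing older leaf.

Default conditions: 96×96 px frames, an elliptical plant of about 2000 px,
fluorescence contrast 180 (plant) vs 10 (background), plant `nir = 180`,
`red = 36` so the true NDVI is exactly `2/3`, scale 0.05 cm/px, noise σ = 5
in the noisy variant — a mode separation (170 levels) and noise level typical
of a well-exposed monochrome sensor. The validation suite runs the full
pipeline on these scenes: noiseless scenes must be recovered *exactly*
(mask pixel-for-pixel, area, index mean to 1e−9, std 0); noisy scenes must
reach IoU ≥ 0.99 over 20 seeds and keep the foreground NDVI mean within the
first-order error-propagation bound `5·σ_prop/√N`, with
`σ_prop = 2σ√(A²+B²)/(A+B)²`, for at least 95 of 100 seeds. Problem sizes
(96×96, 20/100 seeds, 1000 random histograms for the threshold oracle) were
chosen so the whole suite completes in well under a minute while keeping the
Monte-Carlo fractions stable.

What the generator does *not* emulate — and hence what passing these tests
does not show about real data: leaf texture and within-leaf reflectance
gradients, specular highlights, soil or algae with nonzero fluorescence,
mis-registration between bands, vignetting and other spatially varying
illumination, and multi-layer canopies with occlusion (a top view sees only
the uppermost leaf layer). On real scenes those effects make the histogram
valley shallower and the constant-reflectance assumption approximate; the
manual bounds, smoothing window and despeckle size exist precisely to absorb
them.

## Known limitations

* 8-bit, single-channel inputs only; 16-bit or color files are rejected as
  acquisition errors rather than converted.
* Segmentation is intensity-based by design; scenes whose background
  fluoresces (moss, algae) violate its premise.
* Index values are relative reflectance ratios; no inversion to pigment
  concentrations is attempted.
* Exposure calibration normalizes the spatial mean per band; it is not a
  per-pixel flat-field correction.
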