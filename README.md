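# canopyscope

Automated analysis of multispectral plant canopy images for
controlled-environment phenotyping (greenhouses, growth chambers, vertical
farms). Given per-sample folders of co-registered 8-bit grayscale frames —
one per illumination waveband plus a chlorophyll-fluorescence frame (`cfi`,
captured under blue excitation through a >650 nm long-pass filter) —
`canopyscope`:

* **segments** the plant from the background on the fluorescence frame,
  where chlorophyll-bearing tissue is bright and everything else dark: the
  threshold is the valley of the (smoothed) intensity histogram between the
  background mode and the plant mode, found automatically within manual or
  auto-detected bounds, followed by size-based despeckling of small
  connected components;
* **quantifies** projected canopy area as
  `foreground pixels × cm_per_pixel²`;
* **computes** per-pixel normalized-difference index images on the canopy
  only, `index = (R_a − R_b) / (R_a + R_b)` with intensity `R` as the
  reflectance proxy — built-ins NDVI `(a = nir, b = red)` and NDAI
  `(a = red, b = green)`, arbitrary band pairs configurable — with canopy
  mean, population standard deviation, a 200-bin histogram on `[−1, 1]`,
  and false-color PNG renderings;
* **batch-processes** a directory of sample folders to `results.csv`,
  skipping (and recording) corrupt folders instead of aborting;
* **calibrates** per-band exposure against a 50%-reflectance gray card so
  every band images mid-gray at intensity 127, by fixed-point iteration of
  the linear-sensor update `e ← e · 127 / mean(card)`;
* **generates** synthetic multispectral scenes with exact ground truth
  (mask, area, index values), so the entire pipeline is verifiable without
  camera hardware.

## Worked example

Two synthetic pots — one healthy (true NDVI exactly 2/3), one with a
senescent low-NDVI patch — analyzed end to end:

```r
library(canopyscope)

root <- file.path(tempdir(), "greenhouse")
write_scene(generate_scene(scene_spec(seed = 11)), file.path(root, "potA"))
write_scene(generate_senescent_scene(scene_spec(seed = 12),
  patch = list(center = c(48, 48), semi_axes = c(12, 9),
               intensity = c(nir = 100, red = 100))), file.path(root, "potB"))

cfg <- pipeline_config(cm_per_pixel = 0.05,
                       segmentation = segmentation_config(lo = 40, hi = 160))
res <- run_batch(root, cfg)
res[, c("set_id", "threshold", "n_foreground_px", "canopy_area_cm2",
        "ndvi_mean", "ndvi_std")]
#>   set_id threshold n_foreground_px canopy_area_cm2 ndvi_mean  ndvi_std
#> 1   potA        40            2065          5.1625 0.6666667 0.0000000
#> 2   potB        40            2065          5.1625 0.5598063 0.2445835
```

Reading the rows: the valley threshold landed at intensity 40, between the
background fluorescence mode (10) and the plant mode (180); both canopies
cover 2065 pixels = 5.16 cm² at 0.05 cm/px. Pot A recovers its true NDVI of
2/3 exactly with zero spread; pot B's senescent patch pulls the canopy mean
down to 0.560 and widens the spread, and its NDVI histogram
(`analysis/potB/ndvi_hist.csv`) has exactly two occupied bins — one per
tissue region. Per-sample artifacts (`mask.png`, `ndvi.png` false color +
legend, histogram CSVs) land under `analysis/`, and

```r
summarize_results(file.path(root, "analysis", "results.csv"))
#> samples analyzed: 2 (of 2 rows)
#> canopy_area_cm2: mean 5.1625, range [5.1625, 5.1625] (n=2)
#> ndvi_mean: mean 0.613236, range [0.559806, 0.666667] (n=2)
#> ndai_mean: mean -0.502592, range [-0.538462, -0.466723] (n=2)
```

Exposure calibration against a simulated linear camera converges in one
proposal:

```r
calibrate_band(simulated_camera(gain = 2.5), card_region = c(1, 24, 1, 32),
               start_ms = 10)
#> <calibration_record 'red': 50.8 ms, card mean 127.00 (target 127), converged in 1 iterations>
```

A thin command-line front-end wraps the same functions:

```sh
exec/canopyscope synth --suite default --seed 42 --out scenes
exec/canopyscope analyze scenes --config cfg.yaml --out results
exec/canopyscope summarize results/results.csv
```

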