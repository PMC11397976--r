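two_band_set <- function(a, b, band_a = "nir", band_b = "red") {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- storage.mode(b) <- "integer"
  imgs <- list(waveband_image(matrix(100L, nrow(a), ncol(a)), "cfi"),
               waveband_image(a, band_a), waveband_image(b, band_b))
  names(imgs) <- c("cfi", band_a, band_b)
  multispectral_image_set(imgs, "t", 1)
}

test_that("normalized-difference values follow the defining formula", {
  defn <- index_definition("ndvi", "nir", "red")
  full <- binary_mask(matrix(TRUE, 1, 4))
  set <- two_band_set(matrix(c(200L, 80L, 5L, 0L), 1, 4),
                      matrix(c(50L, 80L, 0L, 0L), 1, 4))
  img <- compute_index(set, full, defn)
  expect_equal(img$values[1, 1], 0.6)       # (200-50)/250
  expect_equal(img$values[1, 2], 0)         # a == b
  expect_equal(img$values[1, 3], 1)         # b == 0
  expect_false(img$valid[1, 4])             # 0/0 is undefined, not 0
  expect_true(is.na(img$values[1, 4]))

  # background pixels are never valid
  none <- binary_mask(matrix(FALSE, 1, 4))
  expect_false(any(compute_index(set, none, defn)$valid))

  expect_error(compute_index(set, full, index_definition("x", "nir", "blue")),
               "blue")
})

test_that("swapping the band pair negates every valid value", {
  set.seed(3)
  a <- matrix(sample(0:255, 100, TRUE), 10, 10)
  b <- matrix(sample(0:255, 100, TRUE), 10, 10)
  set <- two_band_set(a, b)
  mask <- binary_mask(matrix(sample(c(TRUE, FALSE), 100, TRUE), 10, 10))
  fwd <- compute_index(set, mask, index_definition("i", "nir", "red"))
  rev <- compute_index(set, mask, index_definition("i", "red", "nir"))
  expect_identical(fwd$valid, rev$valid)
  expect_equal(fwd$values[fwd$valid], -rev$values[rev$valid])
  expect_true(all(abs(fwd$values[fwd$valid]) <= 1))
})

test_that("statistics use the population standard deviation and fixed bins", {
  # intensities chosen so the valid values are exactly {0.2, 0.4, 0.6}
  set <- two_band_set(matrix(c(60L, 70L, 80L), 1, 3),
                      matrix(c(40L, 30L, 20L), 1, 3))
  img <- compute_index(set, binary_mask(matrix(TRUE, 1, 3)),
                       index_definition("ndvi", "nir", "red"))
  st <- index_stats(img)
  expect_equal(st$mean, 0.4)
  expect_equal(st$std, sqrt(0.08 / 3))   # population sd, about 0.16330
  expect_equal(st$n_pixels, 3)
  expect_equal(sum(st$histogram$count), 3)
  expect_equal(sum(st$histogram$fraction), 1)

  # a single pixel has zero spread
  one <- compute_index(two_band_set(matrix(60L), matrix(40L)),
                       binary_mask(matrix(TRUE, 1, 1)),
                       index_definition("ndvi", "nir", "red"))
  expect_equal(index_stats(one)$std, 0)

  # value 1.0 lands in the final bin [0.99, 1.00]
  top <- compute_index(two_band_set(matrix(5L), matrix(0L)),
                       binary_mask(matrix(TRUE, 1, 1)),
                       index_definition("ndvi", "nir", "red"))
  hst <- index_stats(top)$histogram
  expect_equal(hst$count[200], 1)
  expect_equal(hst$bin_left[200], 0.99)

  # no valid pixels: undefined markers, never zero
  blank <- compute_index(set, binary_mask(matrix(FALSE, 1, 3)),
                         index_definition("ndvi", "nir", "red"))
  st0 <- index_stats(blank)
  expect_equal(st0$n_pixels, 0)
  expect_true(is.na(st0$mean) && is.na(st0$std))
})

test_that("statistics are invariant to background intensity changes", {
  set.seed(17)
  g <- generate_scene(scene_spec(seed = 100))
  mask <- g$truth$mask
  defn <- default_indices()$ndvi
  base <- index_stats(compute_index(g$set, mask, defn))
  for (i in 1:10) {
    perturbed <- g$set
    for (b in c("nir", "red")) {
      px <- perturbed$images[[b]]$pixels
      bg <- which(!mask$pixels)
      px[sample(bg, 200)] <- sample(0:255, 200, TRUE)
      perturbed$images[[b]] <- waveband_image(px, b)
    }
    st <- index_stats(compute_index(perturbed, mask, defn))
    expect_identical(st$mean, base$mean)
    expect_identical(st$std, base$std)
    expect_identical(st$histogram$count, base$histogram$count)
  }
})

test_that("canopy area converts pixel counts by the squared scale", {
  expect_equal(canopy_area(binary_mask(matrix(FALSE, 10, 10)), 0.05), 0)
  px <- matrix(FALSE, 40, 40)
  px[1:30, 1:40] <- TRUE   # 1200 true pixels
  expect_equal(canopy_area(binary_mask(px), 0.05), 3.0)
  seven <- matrix(FALSE, 3, 3); seven[1:7] <- TRUE
  expect_equal(canopy_area(binary_mask(seven), 1), 7)
  expect_error(canopy_area(binary_mask(px), 0), "positive")
})

test_that("false-color rendering anchors the colormap and blacks out background", {
  dir <- withr::local_tempdir()
  set <- two_band_set(matrix(c(5L, 0L, 100L), 1, 3),
                      matrix(c(0L, 5L, 100L), 1, 3))
  img <- compute_index(set, binary_mask(matrix(c(TRUE, TRUE, FALSE), 1, 3)),
                       index_definition("ndvi", "nir", "red"))
  out <- file.path(dir, "ndvi.png")
  render_false_color(img, "viridis", out)
  arr <- png::readPNG(out)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "Viridis")) / 255
  expect_equal(as.numeric(arr[1, 1, ]),
               as.numeric(round(pal[, 256] * 255) / 255))   # +1 -> top end
  expect_equal(as.numeric(arr[1, 2, ]),
               as.numeric(round(pal[, 1] * 255) / 255))     # -1 -> bottom end
  expect_equal(as.numeric(arr[1, 3, ]), c(0, 0, 0))                     # bg
  expect_true(file.exists(file.path(dir, "ndvi_legend.png")))

  all_bg <- compute_index(set, binary_mask(matrix(FALSE, 1, 3)),
                          index_definition("ndvi", "nir", "red"))
  render_false_color(all_bg, "viridis", out, legend = FALSE)
  expect_true(all(png::readPNG(out) == 0))

  expect_error(render_false_color(img, "not-a-map", out), "unknown colormap")
})

test_that("index histogram CSV has the documented schema", {
  dir <- withr::local_tempdir()
  g <- generate_scene(scene_spec(seed = 4))
  st <- index_stats(compute_index(g$set, g$truth$mask,
                                  default_indices()$ndvi))
  p <- file.path(dir, "h.csv")
  write_histogram_csv(st, p)
  df <- utils::read.csv(p)
  expect_identical(names(df), c("bin_left", "bin_right", "count", "fraction"))
  expect_equal(nrow(df), 200)
  expect_equal(sum(df$count), st$n_pixels)
})
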