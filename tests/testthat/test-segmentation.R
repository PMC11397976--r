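test_that("histogram smoothing matches the hand-computed moving average", {
  counts <- integer(256)
  counts[(100:104) + 1] <- c(5, 1, 9, 1, 5)
  h <- intensity_histogram(counts)

  expect_identical(smooth_histogram(h, 1L), as.numeric(counts))

  sm <- smooth_histogram(h, 3L)
  expect_equal(sm[(101:103) + 1], c(5, 11 / 3, 5))
  expect_equal(sm[(99:100) + 1], c(5 / 3, 2))

  const <- intensity_histogram(rep(4L, 256))
  for (w in c(1L, 3L, 7L, 21L)) {
    expect_equal(smooth_histogram(const, w), rep(4, 256))
  }

  expect_error(smooth_histogram(h, 2L), "odd")
  expect_error(smooth_histogram(h, 0L), "odd")
})

test_that("valley threshold is the bounded argmin with tie-break low", {
  # V-shaped valley with distractor peaks outside the manual bounds
  counts <- integer(256)
  for (i in 60:180) counts[i + 1] <- abs(i - 117) + 3
  counts[c(20, 220) + 1] <- c(900, 700)
  tr <- find_valley_threshold(intensity_histogram(counts), 60, 180, 1L)
  expect_equal(tr$threshold, 117)
  expect_equal(tr$method, "bounded_valley")
  expect_length(tr$peaks, 0)

  # uniform counts inside the bounds: tie broken toward the lowest intensity
  tr2 <- find_valley_threshold(intensity_histogram(rep(3L, 256)), 50, 90, 1L)
  expect_equal(tr2$threshold, 50)

  # narrow-bounds case, expected value frozen from the brute-force oracle
  counts3 <- integer(256)
  counts3[(100:104) + 1] <- c(5, 1, 9, 1, 5)
  expect_equal(oracle_valley(counts3, 100, 104, 3), 100)
  tr3 <- find_valley_threshold(intensity_histogram(counts3), 100, 104, 3L)
  expect_equal(tr3$threshold, 100)

  expect_error(find_valley_threshold(intensity_histogram(counts), 90, 60),
               "lo <= hi")
})

test_that("valley threshold equals the exhaustive oracle on random histograms", {
  set.seed(71)
  for (i in 1:200) {
    counts <- random_histogram()
    lo <- sample(0:200, 1)
    hi <- lo + sample.int(256 - lo, 1) - 1L
    w <- sample(c(1L, 3L, 5L, 9L), 1)
    got <- find_valley_threshold(intensity_histogram(counts), lo, hi, w)
    expect_identical(got$threshold, as.integer(oracle_valley(counts, lo, hi,
                                                             w)))
  }
})

test_that("auto bounds pick the two leftmost prominent peaks", {
  two_modes <- integer(256)
  two_modes[12 + 1] <- 500; two_modes[(11:13) + 1] <- c(250, 500, 250)
  two_modes[200 + 1] <- 300; two_modes[(199:201) + 1] <- c(150, 300, 150)
  ab <- auto_bounds(intensity_histogram(two_modes), window = 1L)
  expect_equal(ab$lo, 12)
  expect_equal(ab$hi, 200)

  three_modes <- two_modes
  three_modes[(89:91) + 1] <- c(200, 400, 200)
  three_modes[(219:221) + 1] <- c(100, 200, 100)
  ab3 <- auto_bounds(intensity_histogram(three_modes), window = 1L)
  expect_equal(c(ab3$lo, ab3$hi), c(12, 90))
  expect_true(all(c(12, 90, 200, 220) %in% ab3$peaks))

  unimodal <- integer(256)
  unimodal[(100:110) + 1] <- c(1, 5, 20, 80, 200, 260, 200, 80, 20, 5, 1)
  expect_error(auto_bounds(intensity_histogram(unimodal), window = 1L),
               "not bimodal")
})

test_that("thresholding is strict-greater and monotone in the threshold", {
  img <- waveband_image(matrix(c(10L, 200L), 1, 2), "cfi")
  expect_identical(threshold_mask(img, 255)$pixels, matrix(FALSE, 1, 2))
  expect_identical(threshold_mask(img, 100)$pixels,
                   matrix(c(FALSE, TRUE), 1, 2))
  expect_identical(threshold_mask(img, 10)$pixels,
                   matrix(c(FALSE, TRUE), 1, 2))  # boundary bin is background
  pos <- waveband_image(matrix(sample(1:255, 25, TRUE), 5, 5), "cfi")
  expect_true(all(threshold_mask(pos, 0)$pixels))

  set.seed(31)
  for (i in 1:20) {
    r <- random_image(12, 12)
    t1 <- sample(0:254, 1); t2 <- sample(t1:255, 1)
    m1 <- threshold_mask(r, t1)$pixels
    m2 <- threshold_mask(r, t2)$pixels
    expect_true(all(m1[m2]))   # mask(t2) subset of mask(t1)
  }
})

test_that("component labeling agrees with flood fill and EBImage", {
  set.seed(47)
  for (i in 1:12) {
    px <- matrix(stats::runif(15 * 15) < 0.4, 15, 15)
    for (conn in c(4L, 8L)) {
      lab <- canopyscope:::label_components(px, conn)
      ref <- oracle_components(px, conn)
      # same partition (label ids may differ)
      expect_equal(max(lab), max(ref))
      expect_true(all((lab > 0) == px))
      key <- paste(lab[px], ref[px])
      expect_equal(length(unique(key)), max(ref))
    }
    # EBImage as an independent library cross-check (4-connectivity)
    eb <- EBImage::bwlabel(px * 1)
    expect_equal(max(canopyscope:::label_components(px, 4L)), max(eb))
  }
})

test_that("despeckling removes small components and is idempotent", {
  px <- matrix(FALSE, 8, 8)
  px[2:4, 2:5] <- TRUE            # 12-px blob
  px[7, 1] <- TRUE; px[8, 1] <- TRUE   # 2-px speckle
  px[1, 8] <- TRUE; px[2, 8] <- TRUE   # 2-px speckle
  out <- despeckle_mask(binary_mask(px), despeckle_params(5L, 8L))
  expect_equal(sum(out$pixels), 12)
  expect_true(all(out$pixels[2:4, 2:5]))

  # 6-px diagonal chain: one component under 8-connectivity, six singletons
  # under 4-connectivity
  diagpx <- matrix(FALSE, 8, 8)
  for (k in 1:6) diagpx[k, k] <- TRUE
  expect_equal(sum(despeckle_mask(binary_mask(diagpx),
                                  despeckle_params(5L, 8L))$pixels), 6)
  expect_equal(sum(despeckle_mask(binary_mask(diagpx),
                                  despeckle_params(5L, 4L))$pixels), 0)

  empty <- binary_mask(matrix(FALSE, 5, 5))
  expect_identical(despeckle_mask(empty)$pixels, empty$pixels)

  set.seed(13)
  for (i in 1:15) {
    m <- binary_mask(matrix(stats::runif(14 * 14) < 0.45, 14, 14))
    p <- despeckle_params(sample(1:6, 1), sample(c(4L, 8L), 1))
    once <- despeckle_mask(m, p)
    expect_true(all(m$pixels[once$pixels]))               # subset of input
    expect_identical(despeckle_mask(once, p)$pixels, once$pixels)  # idempotent
  }
})

test_that("segment recovers ground truth on synthetic scenes", {
  manual <- segmentation_config(lo = 40, hi = 160)

  clean <- generate_scene(scene_spec(seed = 7))
  seg <- segment(clean$set, manual)
  expect_identical(seg$mask$pixels, clean$truth$mask$pixels)
  expect_gt(seg$threshold$threshold, 10)
  expect_lt(seg$threshold$threshold, 180)

  speckled <- generate_scene(scene_spec(
    speckles = list(n = 3L, size = 2L, intensity = 200L), seed = 8))
  seg2 <- segment(speckled$set,
                  segmentation_config(lo = 40, hi = 160,
                                      min_component_px = 5L))
  expect_identical(seg2$mask$pixels, speckled$truth$mask$pixels)
  # without despeckling the speckles would survive
  raw <- threshold_mask(speckled$set$images$cfi, seg2$threshold$threshold)
  expect_equal(sum(raw$pixels) - sum(seg2$mask$pixels), 6)

  blank <- generate_scene(scene_spec(plant = matrix(FALSE, 96, 96), seed = 9))
  seg3 <- segment(blank$set, manual)
  expect_equal(sum(seg3$mask$pixels), 0)

  # auto bounds route reports its peaks
  sega <- segment(clean$set, segmentation_config())
  expect_equal(sega$threshold$method, "auto_peaks")
  expect_length(sega$threshold$peaks, 2)
  expect_identical(sega$mask$pixels, clean$truth$mask$pixels)
})

test_that("median prefilter removes single-pixel outliers", {
  px <- matrix(10L, 12, 12)
  px[c(1, 40, 77)] <- 255L   # isolated hot pixels, one in a corner
  filtered <- canopyscope:::median_prefilter(waveband_image(px, "cfi"))
  expect_identical(filtered$pixels, matrix(10L, 12, 12))

  const <- waveband_image(matrix(44L, 9, 9), "cfi")
  expect_identical(canopyscope:::median_prefilter(const)$pixels, const$pixels)
})
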