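#' Parametric description of a synthetic multispectral scene
#'
#' A synthetic scene emulates the statistical structure the segmentation
#' relies on: a dark background and a bright plant region in the
#' fluorescence channel (a bimodal intensity histogram), constant
#' per-region reflectance in every band, optional additive Gaussian sensor
#' noise, and small bright speckle artifacts on the background. Exact ground
#' truth (mask, pixel count, area, noiseless index values) is computed before
#' noise and speckles are applied.
#'
#' The defaults describe the canonical test scene: a 96x96 frame with an
#' elliptical plant whose NDVI is exactly `(180 - 36)/(180 + 36) = 2/3`,
#' positive NDAI, a fluorescence contrast of 180 vs 10, and a ground-sampling
#' distance of 0.05 cm/px.
#'
#' @param width,height Frame size in pixels.
#' @param plant Plant shape: a list of ellipses, each
#'   `list(center = c(row, col), semi_axes = c(a_row, a_col))`, or an explicit
#'   logical matrix. An empty list gives a blank (plantless) scene.
#' @param plant_intensity,background_intensity Named per-band mean
#'   intensities (0--255) for the two regions. The `cfi` means must differ,
#'   otherwise the scene is not segmentable.
#' @param patch Optional senescence patch: `list(center, semi_axes,
#'   intensity)` where `intensity` is a named per-band vector overriding the
#'   plant values inside the patch ellipse; the patch must lie inside the
#'   plant.
#' @param noise_sd Additive Gaussian noise standard deviation, applied
#'   independently per band, then rounded, then clipped to `[0, 255]` (in
#'   that order).
#' @param speckles `list(n, size, intensity)`: `n` background artifacts of
#'   `size` pixels (horizontal runs) at the given `cfi` intensity, placed by
#'   rejection sampling so they never touch the plant or each other.
#' @param cm_per_pixel Positive ground-sampling distance.
#' @param seed Integer seed making generation fully deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 96L, height = 96L,
                       plant = list(list(center = c(48, 48),
                                         semi_axes = c(30, 22))),
                       plant_intensity = c(cfi = 180, nir = 180, red = 36,
                                           green = 120, blue = 40),
                       background_intensity = c(cfi = 10, nir = 60, red = 60,
                                                green = 60, blue = 60),
                       patch = NULL,
                       noise_sd = 0,
                       speckles = list(n = 0L, size = 2L, intensity = 200L),
                       cm_per_pixel = 0.05, seed = 1L) {
  bands <- names(plant_intensity)
  if (!setequal(bands, names(background_intensity))) {
    stop("plant and background intensities must cover the same bands",
         call. = FALSE)
  }
  if (!"cfi" %in% bands) stop("a 'cfi' band is required", call. = FALSE)
  all_means <- c(plant_intensity, background_intensity,
                 if (!is.null(patch)) patch$intensity)
  if (any(all_means < 0 | all_means > 255)) {
    stop("band means must lie in [0, 255]", call. = FALSE)
  }
  if (plant_intensity[["cfi"]] == background_intensity[["cfi"]]) {
    stop("non-segmentable scene: plant and background fluorescence means are equal",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 plant = plant, plant_intensity = plant_intensity,
                 background_intensity = background_intensity, patch = patch,
                 noise_sd = noise_sd, speckles = speckles,
                 cm_per_pixel = cm_per_pixel, seed = as.integer(seed)),
            class = "scene_spec")
}

ellipse_mask <- function(width, height, center, semi_axes) {
  if (center[1] - semi_axes[1] < 1 || center[1] + semi_axes[1] > height ||
      center[2] - semi_axes[2] < 1 || center[2] + semi_axes[2] > width) {
    stop("plant shape exceeds the canvas", call. = FALSE)
  }
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - center[1]) / semi_axes[1])^2 + ((c - center[2]) / semi_axes[2])^2 <= 1
}

plant_mask_from_spec <- function(spec) {
  if (is.matrix(spec$plant)) {
    if (!identical(dim(spec$plant), c(spec$height, spec$width))) {
      stop("explicit plant mask must match the canvas size", call. = FALSE)
    }
    return(spec$plant)
  }
  m <- matrix(FALSE, spec$height, spec$width)
  for (e in spec$plant) {
    m <- m | ellipse_mask(spec$width, spec$height, e$center, e$semi_axes)
  }
  m
}

nd_value <- function(a, b) if (a + b > 0) (a - b) / (a + b) else NA_real_

region_expected_indices <- function(intensity) {
  out <- list()
  for (defn in default_indices()) {
    if (all(c(defn$band_a, defn$band_b) %in% names(intensity))) {
      out[[defn$name]] <- nd_value(intensity[[defn$band_a]],
                                   intensity[[defn$band_b]])
    }
  }
  out
}

# Place n speckles (horizontal runs of `size` px) on the background by
# rejection sampling; a one-pixel margin keeps them 8-disconnected from the
# plant and from each other so ground-truth masks stay exact.
place_speckles <- function(plant, n, size) {
  h <- nrow(plant); w <- ncol(plant)
  blocked <- plant
  out <- vector("list", n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in 1:1000) {
      r <- sample.int(h, 1L)
      c0 <- sample.int(w - size + 1L, 1L)
      rr <- max(1L, r - 1L):min(h, r + 1L)
      cc <- max(1L, c0 - 1L):min(w, c0 + size)
      if (!any(blocked[rr, cc])) {
        out[[k]] <- cbind(row = r, col = c0:(c0 + size - 1L))
        blocked[rr, cc] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place speckles away from the plant; scene too crowded",
           call. = FALSE)
    }
  }
  out
}

#' Generate a synthetic multispectral scene with exact ground truth
#'
#' Deterministic given the spec's seed. For a noiseless spec every plant
#' pixel carries exactly the configured band intensities, so the full
#' analysis pipeline must recover the mask, area and index values exactly.
#'
#' @param spec A [scene_spec()].
#' @return List with `set` (a [multispectral_image_set()]) and `truth`
#'   (class `ground_truth`): `mask`, `n_plant_px`, `area_cm2`
#'   (`= n_plant_px * cm_per_pixel^2`), and `expected_index`, a mapping
#'   index name -> noiseless value per sub-region (`main`, and `patch` when
#'   a senescence patch is present) together with per-region pixel counts.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  plant <- plant_mask_from_spec(spec)
  patch_px <- NULL
  if (!is.null(spec$patch)) {
    patch_px <- ellipse_mask(spec$width, spec$height, spec$patch$center,
                             spec$patch$semi_axes)
    if (any(patch_px & !plant)) {
      stop("senescence patch lies outside the plant", call. = FALSE)
    }
  }
  bands <- sort(names(spec$plant_intensity))
  images <- list()
  for (b in bands) {
    px <- matrix(spec$background_intensity[[b]], spec$height, spec$width)
    px[plant] <- spec$plant_intensity[[b]]
    if (!is.null(patch_px) && b %in% names(spec$patch$intensity)) {
      px[patch_px] <- spec$patch$intensity[[b]]
    }
    if (spec$noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
    }
    if (b == "cfi" && spec$speckles$n > 0) {
      spots <- place_speckles(plant, spec$speckles$n, spec$speckles$size)
      for (s in spots) px[s] <- spec$speckles$intensity
    }
    px <- pmin(pmax(round(px), 0), 255)   # round, then clip
    images[[b]] <- waveband_image(px, b)
  }
  n_main <- if (is.null(patch_px)) sum(plant) else sum(plant & !patch_px)
  regions <- list(main = list(n_px = n_main,
                              index = region_expected_indices(
                                as.list(spec$plant_intensity))))
  if (!is.null(patch_px)) {
    patch_int <- as.list(spec$plant_intensity)
    patch_int[names(spec$patch$intensity)] <- spec$patch$intensity
    regions$patch <- list(n_px = sum(patch_px),
                          index = region_expected_indices(patch_int))
  }
  truth <- structure(list(mask = binary_mask(plant),
                          n_plant_px = sum(plant),
                          area_cm2 = sum(plant) * spec$cm_per_pixel^2,
                          expected_index = regions),
                     class = "ground_truth")
  set <- multispectral_image_set(images, set_id = "synthetic",
                                 cm_per_pixel = spec$cm_per_pixel)
  list(set = set, truth = truth)
}

#' Generate a scene with a senescent sub-region
#'
#' Convenience wrapper around [generate_scene()] that adds a senescence
#' patch — a sub-ellipse of the plant with its own band intensities, hence
#' its own expected index values. The resulting canopy has two sub-regions
#' of distinct reflectance, which must surface as a two-peaked index
#' histogram.
#'
#' @param spec A [scene_spec()] without a patch.
#' @param patch `list(center, semi_axes, intensity)`; must lie inside the
#'   plant shape.
#' @return As [generate_scene()]; `truth$expected_index` lists both `main`
#'   and `patch` regions.
#' @export
generate_senescent_scene <- function(spec, patch) {
  stopifnot(inherits(spec, "scene_spec"))
  spec$patch <- patch
  if (any(c(patch$intensity) < 0 | c(patch$intensity) > 255)) {
    stop("band means must lie in [0, 255]", call. = FALSE)
  }
  generate_scene(spec)
}

#' The default named fixture suite
#'
#' Five scenes covering the behaviors the pipeline must handle: `clean`
#' (noiseless), `noisy` (sigma = 5 on every band), `speckled` (three 2-px
#' bright background artifacts), `senescent` (a low-NDVI patch inside the
#' plant) and `blank` (no plant).
#'
#' @param seed Base seed; each scene derives its own offset seed.
#' @return Named list of `generate_scene()` results.
#' @export
scene_suite <- function(seed = 42L) {
  blank <- matrix(FALSE, 96, 96)
  list(
    clean = generate_scene(scene_spec(seed = seed)),
    noisy = generate_scene(scene_spec(noise_sd = 5, seed = seed + 1L)),
    speckled = generate_scene(scene_spec(
      speckles = list(n = 3L, size = 2L, intensity = 200L), seed = seed + 2L)),
    senescent = generate_senescent_scene(
      scene_spec(seed = seed + 3L),
      patch = list(center = c(48, 48), semi_axes = c(12, 9),
                   intensity = c(nir = 100, red = 100))),
    blank = generate_scene(scene_spec(plant = blank, seed = seed + 4L))
  )
}

#' Write a generated scene to disk
#'
#' Writes one `<band>.png` per band plus `mask.png` (the ground-truth mask)
#' and `ground_truth.json` (pixel counts, area, expected index values, scale).
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output folder (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(scene$set$images)) {
    write_waveband_image(scene$set$images[[b]], file.path(dir,
                                                          paste0(b, ".png")))
  }
  write_mask(scene$truth$mask, file.path(dir, "mask.png"))
  gt <- list(mask = "mask.png",
             n_plant_px = scene$truth$n_plant_px,
             area_cm2 = scene$truth$area_cm2,
             cm_per_pixel = scene$set$cm_per_pixel,
             expected_index = scene$truth$expected_index)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
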