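#' Construct a single-waveband image
#'
#' A waveband image is one co-registered 8-bit grayscale frame taken under a
#' single illumination waveband. Pixel intensity (0--255) is the proxy of
#' reflectance used by all downstream index math; for the `cfi` band it is the
#' chlorophyll-fluorescence signal (captured under blue excitation through a
#' >650 nm long-pass filter) that drives segmentation.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`, row-major with
#'   origin at the top-left; both dimensions must be at least 1.
#' @param waveband Band label, conventionally one of `"blue"`, `"green"`,
#'   `"red"`, `"nir"`, `"cfi"`; arbitrary labels are allowed for custom bands.
#' @param exposure_ms Optional positive exposure time in milliseconds.
#' @return An object of class `waveband_image` with fields `pixels`,
#'   `waveband`, `exposure_ms`.
#' @export
waveband_image <- function(pixels, waveband, exposure_ms = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image dimensions must both be >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    stop("pixel intensities must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (!is.character(waveband) || length(waveband) != 1L || !nzchar(waveband)) {
    stop("waveband must be a non-empty label", call. = FALSE)
  }
  if (!is.null(exposure_ms) && (!is.numeric(exposure_ms) || exposure_ms <= 0)) {
    stop("exposure_ms must be positive", call. = FALSE)
  }
  structure(list(pixels = pixels, waveband = waveband,
                 exposure_ms = exposure_ms),
            class = "waveband_image")
}

#' @export
print.waveband_image <- function(x, ...) {
  cat(sprintf("<waveband_image '%s' %dx%d, intensities %d..%d>\n",
              x$waveband, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Bundle co-registered waveband images into a multispectral set
#'
#' The per-sample unit of analysis: one frame per waveband, all sharing
#' identical dimensions, plus the ground-sampling scale. The chlorophyll
#' fluorescence frame (`cfi`) is mandatory because it is the only band on
#' which plants and background are reliably separable by intensity.
#'
#' @param images Named list of [waveband_image()] objects; names are the band
#'   labels and must include `"cfi"`.
#' @param set_id Identifier for the sample (e.g. the folder name).
#' @param cm_per_pixel Positive ground-sampling distance in cm per pixel.
#' @param timestamp Optional acquisition timestamp (text).
#' @return An object of class `msi_set`.
#' @export
multispectral_image_set <- function(images, set_id, cm_per_pixel,
                                    timestamp = NULL) {
  if (!is.list(images) || length(images) == 0L || is.null(names(images))) {
    stop("images must be a named list of waveband_image objects", call. = FALSE)
  }
  ok <- vapply(images, inherits, logical(1), "waveband_image")
  if (!all(ok)) stop("all images must be waveband_image objects", call. = FALSE)
  if (!"cfi" %in% names(images)) {
    stop("no fluorescence image: the set must contain the 'cfi' band",
         call. = FALSE)
  }
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("dimension mismatch: all bands must share identical dimensions",
         call. = FALSE)
  }
  if (!is.numeric(cm_per_pixel) || length(cm_per_pixel) != 1L ||
      cm_per_pixel <= 0) {
    stop("cm_per_pixel must be a positive real", call. = FALSE)
  }
  structure(list(images = images, set_id = as.character(set_id),
                 cm_per_pixel = cm_per_pixel, timestamp = timestamp),
            class = "msi_set")
}

#' @export
print.msi_set <- function(x, ...) {
  d <- dim(x$images[[1]]$pixels)
  cat(sprintf("<msi_set '%s': bands [%s], %dx%d, %.4g cm/px>\n", x$set_id,
              paste(names(x$images), collapse = ", "), d[1], d[2],
              x$cm_per_pixel))
  invisible(x)
}

#' Construct a binary plant mask
#'
#' @param pixels Logical matrix; `TRUE` marks plant foreground.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels) || !is.logical(pixels) || anyNA(pixels)) {
    stop("mask pixels must be a logical matrix without NAs", call. = FALSE)
  }
  structure(list(pixels = pixels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Intensity histogram of an 8-bit image
#'
#' @param counts Integer vector of 256 nonnegative counts; element `i` is the
#'   number of pixels with intensity `i - 1`.
#' @return An object of class `intensity_histogram`.
#' @export
intensity_histogram <- function(counts) {
  if (length(counts) != 256L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be 256 nonnegative integers", call. = FALSE)
  }
  counts <- as.numeric(counts)   # counts can exceed .Machine$integer.max
  structure(list(counts = counts), class = "intensity_histogram")
}

#' Tally the intensity histogram of a waveband image
#'
#' @param image A [waveband_image()].
#' @return An [intensity_histogram()]; `counts[v + 1]` is the number of pixels
#'   with intensity exactly `v`, and the counts sum to the pixel count.
#' @export
compute_histogram <- function(image) {
  stopifnot(inherits(image, "waveband_image"))
  intensity_histogram(tabulate(as.vector(image$pixels) + 1L, nbins = 256L))
}

# -- file I/O ------------------------------------------------------------

# PNG IHDR layout: 8-byte signature, 4-byte length, "IHDR", width, height,
# then bit depth (byte 25) and color type (byte 26). Checked before decoding
# so 16-bit or color files are rejected rather than silently rescaled.
png_header_info <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L ||
      !identical(hdr[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))) {
    stop(sprintf("'%s' is not a PNG file", path), call. = FALSE)
  }
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

#' Read one 8-bit grayscale waveband frame from PNG or TIFF
#'
#' The imaging instrument is monochrome and 8-bit, so anything else signals an
#' acquisition error: 16-bit files are rejected (never rescaled) and
#' multi-channel (color) files are rejected (never converted to luminance).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param waveband Band label to attach to the frame.
#' @return A [waveband_image()].
#' @export
read_waveband_image <- function(path, waveband) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    info <- png_header_info(path)
    if (info$color_type != 0L) {
      stop(sprintf("'%s' is not single-channel grayscale (color type %d)",
                   path, info$color_type), call. = FALSE)
    }
    if (info$bit_depth != 8L) {
      stop(sprintf("'%s' is %d-bit; only 8-bit images are supported",
                   path, info$bit_depth), call. = FALSE)
    }
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits != 8L) {
      stop(sprintf("'%s' is %d-bit; only 8-bit images are supported",
                   path, bits), call. = FALSE)
    }
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    stop(sprintf("'%s' is not single-channel grayscale (%d channels)",
                 path, dim(arr)[3]), call. = FALSE)
  }
  px <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  waveband_image(px, waveband)
}

#' Load a sample folder into a multispectral image set
#'
#' Reads one grayscale frame per configured waveband from a sample folder,
#' matching files by the configured band -> filename map (default
#' `<band>.png`).
#'
#' @param folder_path Folder holding the per-band image files.
#' @param config A [pipeline_config()] (its `bands` map and `cm_per_pixel`
#'   are used).
#' @return A [multispectral_image_set()] whose `set_id` is the folder name.
#' @export
load_image_set <- function(folder_path, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(folder_path)) {
    stop(sprintf("sample folder '%s' does not exist", folder_path),
         call. = FALSE)
  }
  bands <- config$bands
  cfi_path <- file.path(folder_path, bands[["cfi"]])
  if (!file.exists(cfi_path)) {
    stop(sprintf("no fluorescence image: '%s' is missing", cfi_path),
         call. = FALSE)
  }
  images <- lapply(names(bands), function(b) {
    read_waveband_image(file.path(folder_path, bands[[b]]), b)
  })
  names(images) <- names(bands)
  multispectral_image_set(images, set_id = basename(folder_path),
                          cm_per_pixel = config$cm_per_pixel)
}

#' Write a waveband image as 8-bit grayscale PNG
#'
#' @param image A [waveband_image()].
#' @param path Output path; reading the file back reproduces the pixels
#'   bit-exactly.
#' @return The path, invisibly.
#' @export
write_waveband_image <- function(image, path) {
  stopifnot(inherits(image, "waveband_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask A [binary_mask()].
#' @param path Output path; foreground is written as 255, background as 0.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  ok <- tryCatch({
    png::writePNG(mask$pixels * 1, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write mask to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a 0/255 mask PNG back into a binary mask
#'
#' @param path Path to a mask PNG written by [write_mask()].
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  img <- read_waveband_image(path, "mask")
  binary_mask(img$pixels == 255L)
}
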