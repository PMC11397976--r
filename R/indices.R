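#' Define a normalized-difference index
#'
#' A normalized-difference index over two wavebands is
#' `(R_a - R_b) / (R_a + R_b)`, where `R` is pixel intensity (the reflectance
#' proxy). The built-in definitions are NDVI (`a = nir`, `b = red`), which
#' tracks chlorophyll/"greenness", and NDAI (`a = red`, `b = green`), which
#' tracks anthocyanin pigmentation; both band pair and sign convention are
#' fully configurable.
#'
#' @param name Index name (used in file and column names).
#' @param band_a Numerator-positive band label.
#' @param band_b The other band label; must differ from `band_a`.
#' @return An object of class `index_definition`.
#' @export
index_definition <- function(name, band_a, band_b) {
  if (!nzchar(name)) stop("index name must be non-empty", call. = FALSE)
  if (identical(band_a, band_b)) {
    stop("band_a and band_b must differ", call. = FALSE)
  }
  structure(list(name = name, band_a = band_a, band_b = band_b),
            class = "index_definition")
}

#' Built-in index definitions
#'
#' @return Named list with `ndvi = (nir, red)` and `ndai = (red, green)`.
#' @export
default_indices <- function() {
  list(ndvi = index_definition("ndvi", "nir", "red"),
       ndai = index_definition("ndai", "red", "green"))
}

#' Compute a masked per-pixel index image
#'
#' Evaluates `(a - b) / (a + b)` at every plant-foreground pixel. Pixels where
#' both bands read 0 have no defined value; they are flagged invalid and
#' excluded from all statistics rather than being assigned 0, so index means
#' are never diluted by undefined pixels. Background pixels are always
#' invalid.
#'
#' @param set A [multispectral_image_set()] containing both bands.
#' @param mask A [binary_mask()] with the set's dimensions.
#' @param defn An [index_definition()].
#' @return An object of class `index_image` with `values` (numeric matrix,
#'   `NA` where invalid), `valid` (logical matrix) and `index_name`. Every
#'   valid value lies in `[-1, 1]`.
#' @export
compute_index <- function(set, mask, defn) {
  stopifnot(inherits(set, "msi_set"), inherits(mask, "binary_mask"),
            inherits(defn, "index_definition"))
  for (b in c(defn$band_a, defn$band_b)) {
    if (!b %in% names(set$images)) {
      stop(sprintf("band '%s' required by index '%s' is missing from the set",
                   b, defn$name), call. = FALSE)
    }
  }
  if (!identical(dim(mask$pixels), dim(set$images[[1]]$pixels))) {
    stop("mask dimensions do not match the image set", call. = FALSE)
  }
  a <- set$images[[defn$band_a]]$pixels * 1.0
  b <- set$images[[defn$band_b]]$pixels * 1.0
  s <- a + b
  valid <- mask$pixels & s > 0
  values <- matrix(NA_real_, nrow(a), ncol(a))
  values[valid] <- (a[valid] - b[valid]) / s[valid]
  structure(list(values = values, valid = valid, index_name = defn$name),
            class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("<index_image '%s' %dx%d, %d valid px%s>\n", x$index_name,
              nrow(x$values), ncol(x$values), n,
              if (n) sprintf(", range %.3f..%.3f",
                             min(x$values[x$valid]), max(x$values[x$valid]))
              else ""))
  invisible(x)
}

#' Canopy statistics of an index image
#'
#' Mean and population standard deviation over valid pixels (the canopy
#' pixels are the full population of interest, not a sample), plus a
#' fixed-bin histogram: 200 bins of width 0.01 covering `[-1, 1]`, with the
#' right edge inclusive only for the final bin, so a value of exactly 1 falls
#' in `[0.99, 1.00]`.
#'
#' @param img An [index_image()].
#' @return An object of class `canopy_stats` with `index_name`, `mean`,
#'   `std`, `n_pixels` and a `histogram` data frame with columns `bin_left`,
#'   `bin_right`, `count`, `fraction`. When no pixel is valid, `mean` and
#'   `std` are `NA` (undefined), never 0.
#' @export
index_stats <- function(img) {
  stopifnot(inherits(img, "index_image"))
  v <- img$values[img$valid]
  n <- length(v)
  edges_left <- -1 + (0:199) * 0.01
  if (n == 0L) {
    counts <- integer(200)
    m <- s <- NA_real_
    frac <- rep(0, 200)
  } else {
    bin <- pmin(floor((v + 1) / 0.01), 199) + 1L
    counts <- tabulate(bin, nbins = 200L)
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    frac <- counts / n
  }
  structure(list(index_name = img$index_name, mean = m, std = s,
                 n_pixels = n,
                 histogram = data.frame(bin_left = edges_left,
                                        bin_right = edges_left + 0.01,
                                        count = counts, fraction = frac)),
            class = "canopy_stats")
}

#' @export
print.canopy_stats <- function(x, ...) {
  cat(sprintf("<canopy_stats '%s': mean=%s, std=%s, n=%d px>\n", x$index_name,
              format(x$mean, digits = 6), format(x$std, digits = 6),
              x$n_pixels))
  invisible(x)
}

#' Projected canopy area in square centimeters
#'
#' @param mask A [binary_mask()].
#' @param cm_per_pixel Positive ground-sampling distance in cm per pixel.
#' @return Foreground pixel count times `cm_per_pixel^2`, in cm^2.
#' @export
canopy_area <- function(mask, cm_per_pixel) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(cm_per_pixel) || length(cm_per_pixel) != 1L ||
      cm_per_pixel <= 0) {
    stop("cm_per_pixel must be a positive real", call. = FALSE)
  }
  sum(mask$pixels) * cm_per_pixel^2
}

#' Write an index histogram to CSV
#'
#' Columns: `bin_left, bin_right, count, fraction`.
#'
#' @param stats A [index_stats()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_histogram_csv <- function(stats, path) {
  stopifnot(inherits(stats, "canopy_stats"))
  utils::write.csv(stats$histogram, path, row.names = FALSE)
  invisible(path)
}

index_colormap <- function(colormap_name, n = 256L) {
  pals <- grDevices::hcl.pals()
  hit <- pals[tolower(pals) == tolower(colormap_name)]
  if (length(hit) != 1L) {
    stop(sprintf("unknown colormap '%s'; available maps: %s", colormap_name,
                 paste(pals, collapse = ", ")), call. = FALSE)
  }
  grDevices::hcl.colors(n, palette = hit)  # sequential maps run dark -> light
}

#' Render a false-color index image to PNG
#'
#' Valid pixel values are mapped linearly from `[-1, 1]` onto the named
#' colormap (-1 and +1 hit the two colormap endpoints); invalid and
#' background pixels are black. A color-bar legend PNG is written alongside
#' (`<path basename>_legend.png`).
#'
#' @param img An [index_image()].
#' @param colormap_name A palette name from [grDevices::hcl.pals()]
#'   (case-insensitive), default `"viridis"`.
#' @param path Output PNG path.
#' @param legend Write the color-bar legend PNG (default `TRUE`).
#' @return The path, invisibly.
#' @export
render_false_color <- function(img, colormap_name = "viridis", path,
                               legend = TRUE) {
  stopifnot(inherits(img, "index_image"))
  pal <- index_colormap(colormap_name)
  rgb <- grDevices::col2rgb(pal) / 255
  nr <- nrow(img$values); nc <- ncol(img$values)
  arr <- array(0, dim = c(nr, nc, 3L))
  if (any(img$valid)) {
    idx <- as.integer(round((img$values[img$valid] + 1) / 2 * 255)) + 1L
    for (ch in 1:3) {
      plane <- matrix(0, nr, nc)
      plane[img$valid] <- rgb[ch, idx]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, target = path)
  if (legend) {
    legend_path <- file.path(dirname(path),
                             paste0(tools::file_path_sans_ext(basename(path)),
                                    "_legend.png"))
    grDevices::png(legend_path, width = 120, height = 360)
    op <- graphics::par(mar = c(2, 1, 2, 3))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    graphics::image(x = 1, y = seq(-1, 1, length.out = 256),
                    z = matrix(1:256, 1), col = pal, axes = FALSE,
                    xlab = "", ylab = "", main = img$index_name)
    graphics::axis(4, at = seq(-1, 1, 0.5), las = 1)
  }
  invisible(path)
}
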