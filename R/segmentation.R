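#' Despeckle parameters
#'
#' @param min_component_px Positive integer; connected components strictly
#'   smaller than this are removed from the mask. Default 50 px, sized for
#'   typical dust/water-droplet artifacts at the default scene scale.
#' @param connectivity Pixel adjacency, 4 (edge neighbors) or 8 (edge +
#'   diagonal neighbors).
#' @param median_prefilter If `TRUE`, apply a 3x3 median filter to the
#'   fluorescence image before thresholding (grayscale despeckling at
#'   intensity-extraction time, in addition to mask-time size filtering).
#' @return An object of class `despeckle_params`.
#' @export
despeckle_params <- function(min_component_px = 50L, connectivity = 8L,
                             median_prefilter = FALSE) {
  if (!is.numeric(min_component_px) || min_component_px < 1 ||
      min_component_px != round(min_component_px)) {
    stop("min_component_px must be a positive integer", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  structure(list(min_component_px = as.integer(min_component_px),
                 connectivity = as.integer(connectivity),
                 median_prefilter = isTRUE(median_prefilter)),
            class = "despeckle_params")
}

threshold_result <- function(threshold, lo, hi, smoothed_counts,
                             peaks = integer(0),
                             method = c("bounded_valley", "auto_peaks")) {
  method <- match.arg(method)
  stopifnot(lo <= threshold, threshold <= hi, all(smoothed_counts >= 0))
  structure(list(threshold = as.integer(threshold),
                 bounds = c(lo = as.integer(lo), hi = as.integer(hi)),
                 smoothed_counts = smoothed_counts,
                 peaks = as.integer(peaks), method = method),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: t=%d in [%d, %d], method=%s%s>\n",
              x$threshold, x$bounds[["lo"]], x$bounds[["hi"]], x$method,
              if (length(x$peaks)) paste0(", peaks at ",
                                          paste(x$peaks, collapse = "/"))
              else ""))
  invisible(x)
}

hist_counts <- function(hist) {
  if (inherits(hist, "intensity_histogram")) hist$counts
  else if (is.numeric(hist) && length(hist) == 256L) as.numeric(hist)
  else stop("expected an intensity_histogram or 256 counts", call. = FALSE)
}

#' Moving-average smoothing of an intensity histogram
#'
#' Centered moving average of odd width; the edges are padded by replicating
#' the boundary bins so the output keeps all 256 bins. Smoothing stabilizes
#' the valley search against empty-bin jitter in raw sensor histograms.
#'
#' @param hist An [intensity_histogram()] (or a bare vector of 256 counts).
#' @param window Odd positive integer width; `window = 1` returns the counts
#'   unchanged.
#' @return Numeric vector of 256 smoothed counts.
#' @export
smooth_histogram <- function(hist, window = 5L) {
  counts <- hist_counts(hist)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 != 1) {
    stop("smoothing window must be an odd positive integer", call. = FALSE)
  }
  if (window == 1L) return(counts)
  pad <- (window - 1L) / 2L
  x <- c(rep(counts[1L], pad), counts, rep(counts[256L], pad))
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  as.numeric(sm[(pad + 1L):(pad + 256L)])
}

#' Valley threshold between manual bounds
#'
#' Finds the intensity that best separates the dark background mode from the
#' bright plant mode of a chlorophyll-fluorescence histogram: the argmin of
#' the smoothed histogram over the inclusive intensity range `[lo, hi]`.
#' Ties are broken toward the lowest intensity, which biases toward larger
#' plant masks.
#'
#' @param hist An [intensity_histogram()].
#' @param lo,hi Integer intensity bounds, `0 <= lo <= hi <= 255`. Typically
#'   set manually to bracket the histogram valley, or derived automatically
#'   with [auto_bounds()].
#' @param window Odd smoothing window passed to [smooth_histogram()].
#' @return A `threshold_result` with fields `threshold`, `bounds`,
#'   `smoothed_counts`, `peaks` (empty for manual bounds) and `method`
#'   (`"bounded_valley"`).
#' @export
find_valley_threshold <- function(hist, lo, hi, window = 5L) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi || lo < 0 || hi > 255) {
    stop("threshold bounds must satisfy 0 <= lo <= hi <= 255", call. = FALSE)
  }
  lo <- as.integer(lo); hi <- as.integer(hi)
  sm <- smooth_histogram(hist, window)
  seg <- sm[(lo:hi) + 1L]
  t <- lo + (which.min(seg) - 1L)   # which.min takes the first (lowest) tie
  threshold_result(t, lo, hi, sm, method = "bounded_valley")
}

# Local maxima of a smoothed histogram. Plateaus are collapsed to their
# leftmost bin; boundary runs count as peaks when they exceed their single
# neighbor (a background mode piled up at intensity 0 is a real peak).
local_maxima <- function(y) {
  r <- rle(y)
  n <- length(r$values)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  is_peak <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == n || r$values[i + 1L] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  starts[is_peak]
}

# Topographic prominence of peak at bin p (1-based): height above the higher
# of the two lowest saddles separating it from taller terrain (or the signal
# edge on either side).
peak_prominence <- function(y, p) {
  h <- y[p]
  side_min <- function(idx) {
    if (length(idx) == 0L) return(h)
    higher <- which(y[idx] > h)
    if (length(higher) > 0L) {
      # keep only bins between p and the nearest higher bin
      idx <- if (idx[1L] < p) idx[idx > idx[higher[length(higher)]]]
             else idx[idx < idx[higher[1L]]]
    }
    if (length(idx) == 0L) h else min(y[idx])
  }
  left <- side_min(seq_len(p - 1L))
  right <- side_min(if (p < length(y)) (p + 1L):length(y) else integer(0))
  h - max(left, right)
}

#' Automatic valley-search bounds from the two leftmost histogram peaks
#'
#' Scans the smoothed fluorescence histogram for local maxima whose
#' topographic prominence is at least `min_prominence_frac` of the tallest
#' smoothed bin, and returns the two leftmost qualifying peaks — the
#' background mode and the plant mode — as the valley-search bounds.
#'
#' @param hist An [intensity_histogram()].
#' @param window Odd smoothing window.
#' @param min_prominence_frac Fraction of the maximum smoothed count a local
#'   maximum must rise above its saddles to qualify; default 0.05 rejects
#'   noise wiggles without suppressing a faint plant mode.
#' @return List with `lo` and `hi` (the two peak intensities, `lo < hi`) and
#'   `peaks` (all qualifying peak intensities, left to right).
#' @export
auto_bounds <- function(hist, window = 5L, min_prominence_frac = 0.05) {
  if (!is.numeric(min_prominence_frac) || min_prominence_frac <= 0 ||
      min_prominence_frac >= 1) {
    stop("min_prominence_frac must be in (0, 1)", call. = FALSE)
  }
  sm <- smooth_histogram(hist, window)
  if (all(sm == 0)) stop("histogram is empty", call. = FALSE)
  cand <- local_maxima(sm)
  prom <- vapply(cand, function(p) peak_prominence(sm, p), numeric(1))
  keep <- cand[prom >= min_prominence_frac * max(sm)]
  if (length(keep) < 2L) {
    stop(paste("histogram not bimodal: fewer than two prominent peaks found;",
               "supply manual threshold bounds (lo, hi)"), call. = FALSE)
  }
  peaks <- as.integer(keep - 1L)   # bin index -> intensity
  list(lo = peaks[1L], hi = peaks[2L], peaks = peaks)
}

#' Binarize an image at an intensity threshold
#'
#' @param image A [waveband_image()] (normally the fluorescence frame).
#' @param t Threshold intensity in `[0, 255]`; a pixel is foreground iff its
#'   intensity is strictly greater than `t` (the threshold bin itself is
#'   background).
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(image, t) {
  stopifnot(inherits(image, "waveband_image"))
  if (!is.numeric(t) || t < 0 || t > 255) {
    stop("threshold must be in [0, 255]", call. = FALSE)
  }
  binary_mask(image$pixels > t)
}

# Connected-component labels for a logical matrix. Adjacency edges are built
# by vectorized shifts and components come from igraph; isolated foreground
# pixels are their own components.
label_components <- function(px, connectivity = 8L) {
  nr <- nrow(px); nc <- ncol(px)
  lin <- which(px)
  labels <- matrix(0L, nr, nc)
  if (length(lin) == 0L) return(labels)
  rank <- integer(nr * nc)
  rank[lin] <- seq_along(lin)
  shift_edges <- function(dr, dc) {
    rows <- seq_len(nr - dr)
    cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    if (length(rows) == 0L || length(cols) == 0L) return(NULL)
    both <- px[rows, cols, drop = FALSE] &
      px[rows + dr, cols + dc, drop = FALSE]
    w <- which(both)
    if (length(w) == 0L) return(NULL)
    sr <- ((w - 1L) %% length(rows)) + 1L
    sc <- ((w - 1L) %/% length(rows)) + 1L
    i1 <- (cols[sc] - 1L) * nr + rows[sr]
    cbind(i1, i1 + dr + dc * nr)
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) shift_edges(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(rank[edges[, 1]], rank[edges[, 2]]))
  }
  labels[lin] <- igraph::components(g)$membership
  labels
}

#' Remove small connected components from a mask
#'
#' Size-based despeckling: any foreground component (under the configured
#' connectivity) with fewer than `min_component_px` pixels is set to
#' background. The result is always a subset of the input and the operation
#' is idempotent.
#'
#' @param mask A [binary_mask()].
#' @param params A [despeckle_params()].
#' @return The despeckled [binary_mask()].
#' @export
despeckle_mask <- function(mask, params = despeckle_params()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(params, "despeckle_params"))
  px <- mask$pixels
  if (!any(px)) return(mask)
  labels <- label_components(px, params$connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- labels > 0L & sizes[pmax(labels, 1L)] >= params$min_component_px
  binary_mask(keep)
}

# 3x3 median filter on an 8-bit frame (EBImage, radius 1).
median_prefilter <- function(image) {
  f <- EBImage::medianFilter(image$pixels / 255, size = 1L)
  waveband_image(matrix(as.integer(round(f * 255)), nrow(f), ncol(f)),
                 image$waveband, image$exposure_ms)
}

#' Segmentation configuration
#'
#' @param lo,hi Optional manual bounds for the valley search. When both are
#'   given they take precedence over automatic peak detection.
#' @param auto_bounds Use [auto_bounds()] when manual bounds are absent.
#' @param smooth_window Odd histogram smoothing window (default 5 bins).
#' @param min_prominence_frac Peak prominence fraction for [auto_bounds()].
#' @param min_component_px,connectivity,median_prefilter See
#'   [despeckle_params()].
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(lo = NULL, hi = NULL, auto_bounds = TRUE,
                                smooth_window = 5L,
                                min_prominence_frac = 0.05,
                                min_component_px = 50L, connectivity = 8L,
                                median_prefilter = FALSE) {
  if (xor(is.null(lo), is.null(hi))) {
    stop("manual bounds require both lo and hi", call. = FALSE)
  }
  if (!is.null(lo) && (lo > hi || lo < 0 || hi > 255)) {
    stop("manual bounds must satisfy 0 <= lo <= hi <= 255", call. = FALSE)
  }
  if (is.null(lo) && !isTRUE(auto_bounds)) {
    stop("either manual bounds (lo, hi) or auto_bounds = TRUE is required",
         call. = FALSE)
  }
  structure(list(lo = lo, hi = hi, auto_bounds = isTRUE(auto_bounds),
                 smooth_window = as.integer(smooth_window),
                 min_prominence_frac = min_prominence_frac,
                 despeckle = despeckle_params(min_component_px, connectivity,
                                              median_prefilter)),
            class = "segmentation_config")
}

#' Segment the plant canopy from a multispectral image set
#'
#' Full fluorescence-based segmentation: optional 3x3 median prefilter,
#' intensity histogram, valley threshold between manual or automatically
#' detected bounds, strict-greater binarization, then size-based
#' despeckling.
#'
#' @param set A [multispectral_image_set()] containing the `cfi` band.
#' @param config A [segmentation_config()].
#' @return List with `mask` (the final [binary_mask()]) and `threshold`
#'   (the `threshold_result` diagnostics; `method` is `"bounded_valley"` for
#'   manual bounds and `"auto_peaks"` with the detected peaks otherwise).
#' @export
segment <- function(set, config = segmentation_config()) {
  stopifnot(inherits(set, "msi_set"), inherits(config, "segmentation_config"))
  img <- set$images[["cfi"]]
  if (config$despeckle$median_prefilter) img <- median_prefilter(img)
  h <- compute_histogram(img)
  if (!is.null(config$lo)) {
    tr <- find_valley_threshold(h, config$lo, config$hi, config$smooth_window)
  } else {
    ab <- auto_bounds(h, config$smooth_window, config$min_prominence_frac)
    tr <- find_valley_threshold(h, ab$lo, ab$hi, config$smooth_window)
    tr$peaks <- ab$peaks
    tr$method <- "auto_peaks"
  }
  mask <- despeckle_mask(threshold_mask(img, tr$threshold), config$despeckle)
  list(mask = mask, threshold = tr)
}
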