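#' Propose a corrected exposure from a gray-card reading
#'
#' Under a linear sensor model, mean card intensity is proportional to
#' exposure time, so the exposure that images a 50%-reflectance gray card at
#' the 8-bit midpoint is `current_ms * target / measured_mean`.
#'
#' @param current_ms Current exposure in milliseconds (positive).
#' @param measured_mean Mean card intensity measured at `current_ms`; must be
#'   `> 0` (there is no way to scale up from complete darkness).
#' @param target Target mean intensity, default 127 (the 8-bit midpoint).
#' @param min_ms,max_ms Hardware exposure limits the proposal is clipped to.
#' @return The proposed exposure in milliseconds.
#' @export
propose_exposure <- function(current_ms, measured_mean, target = 127,
                             min_ms = 0.01, max_ms = 10000) {
  if (!is.numeric(current_ms) || current_ms <= 0) {
    stop("current_ms must be positive", call. = FALSE)
  }
  if (!is.numeric(measured_mean) || measured_mean <= 0) {
    stop("no signal: measured mean intensity is 0, cannot scale from darkness",
         call. = FALSE)
  }
  min(max(current_ms * target / measured_mean, min_ms), max_ms)
}

calibration_record <- function(waveband, exposure_ms, measured_mean,
                               target, converged, iterations) {
  structure(list(waveband = waveband, exposure_ms = exposure_ms,
                 measured_mean = measured_mean, target = target,
                 converged = converged, iterations = as.integer(iterations)),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(
    "<calibration_record '%s': %.4g ms, card mean %.2f (target %g), %s in %d iterations>\n",
    x$waveband, x$exposure_ms, x$measured_mean, x$target,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

region_mean <- function(image, card_region) {
  if (length(card_region) != 4L) {
    stop("card_region must be c(row_min, row_max, col_min, col_max)",
         call. = FALSE)
  }
  r <- as.integer(card_region)
  d <- dim(image$pixels)
  if (r[1] < 1L || r[3] < 1L || r[2] > d[1] || r[4] > d[2] ||
      r[1] > r[2] || r[3] > r[4]) {
    stop("card_region must lie within the frame", call. = FALSE)
  }
  mean(image$pixels[r[1]:r[2], r[3]:r[4]])
}

#' Calibrate one band's exposure against a gray card
#'
#' Iterates [propose_exposure()] on the mean intensity inside the card region
#' until the mean is within `tolerance` of `target` or `max_iter` proposals
#' have been made. A saturated card (mean 255) invalidates the linear model,
#' so the exposure is halved, with a warning, until the reading leaves
#' saturation before linear proposals resume; those recovery halvings are not
#' counted as model iterations.
#'
#' @param capture Function `exposure_ms -> waveband_image` — a camera backend
#'   or a simulator such as [simulated_camera()].
#' @param card_region Inclusive 1-based rectangle
#'   `c(row_min, row_max, col_min, col_max)` covering the gray card.
#' @param start_ms Starting exposure in milliseconds.
#' @param target Target mean intensity (default 127).
#' @param tolerance Convergence tolerance in intensity levels (default 1).
#' @param max_iter Maximum number of exposure proposals (default 10).
#' @param min_ms,max_ms Exposure limits passed to [propose_exposure()].
#' @return A `calibration_record` with the final exposure, measured card
#'   mean, convergence flag and iteration count.
#' @export
calibrate_band <- function(capture, card_region, start_ms = 10,
                           target = 127, tolerance = 1, max_iter = 10L,
                           min_ms = 0.01, max_ms = 10000) {
  stopifnot(is.function(capture))
  e <- start_ms
  iters <- 0L
  halvings <- 0L
  repeat {
    img <- capture(e)
    m <- region_mean(img, card_region)
    if (m <= 0) {
      stop("no signal: gray card reads 0, check illumination", call. = FALSE)
    }
    if (m >= 255) {
      if (e <= min_ms || halvings >= 40L) {
        return(calibration_record(img$waveband, e, m, target,
                                  converged = FALSE, iterations = iters))
      }
      warning(sprintf("gray card saturated at %.4g ms; halving exposure", e),
              call. = FALSE)
      e <- max(e / 2, min_ms)
      halvings <- halvings + 1L
      next
    }
    if (abs(m - target) <= tolerance) {
      return(calibration_record(img$waveband, e, m, target,
                                converged = TRUE, iterations = iters))
    }
    if (iters >= max_iter) {
      return(calibration_record(img$waveband, e, m, target,
                                converged = FALSE, iterations = iters))
    }
    e <- propose_exposure(e, m, target, min_ms, max_ms)
    iters <- iters + 1L
  }
}

#' Simulated camera backend for calibration
#'
#' Produces constant gray-card frames whose mean intensity follows
#' `round(clip(gain * exposure_ms^gamma))`, optionally with additive Gaussian
#' noise. `gamma = 1` is an exactly linear sensor; `gamma < 1` emulates mild
#' response nonlinearity.
#'
#' @param gain Sensor gain (intensity per ms at 1 ms, before rounding).
#' @param gamma Response exponent (default 1, linear).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0).
#' @param width,height Frame size in pixels.
#' @param waveband Band label stamped on the frames.
#' @return A capture function `exposure_ms -> waveband_image`.
#' @export
simulated_camera <- function(gain, gamma = 1, noise_sd = 0,
                             width = 32L, height = 24L, waveband = "red") {
  stopifnot(gain >= 0, gamma > 0, noise_sd >= 0)
  function(exposure_ms) {
    level <- gain * exposure_ms^gamma
    px <- matrix(level, height, width)
    if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)
    px <- pmin(pmax(round(px), 0), 255)
    waveband_image(px, waveband, exposure_ms = exposure_ms)
  }
}

#' Folder-replay capture backend
#'
#' Replays a pre-taken gray-card exposure series from disk: files named
#' `<band>_<exposure>ms.png` (e.g. `red_12.5ms.png`). A capture request
#' returns the file whose recorded exposure is closest to the requested one,
#' so the iterative calibration can be exercised against archived series.
#'
#' @param dir Folder containing the series.
#' @param waveband Band label to replay.
#' @return A capture function `exposure_ms -> waveband_image`.
#' @export
folder_capture <- function(dir, waveband) {
  pattern <- sprintf("^%s_([0-9.]+)ms\\.(png|tif|tiff)$", waveband)
  files <- list.files(dir, pattern = pattern)
  if (length(files) == 0L) {
    stop(sprintf("no '%s_<exposure>ms' images found in '%s'", waveband, dir),
         call. = FALSE)
  }
  exposures <- as.numeric(sub(pattern, "\\1", files))
  function(exposure_ms) {
    i <- which.min(abs(exposures - exposure_ms))
    img <- read_waveband_image(file.path(dir, files[i]), waveband)
    img$exposure_ms <- exposures[i]
    img
  }
}
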