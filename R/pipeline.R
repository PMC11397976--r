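#' Pipeline configuration
#'
#' Everything the batch analysis needs: the band -> filename map, the
#' segmentation settings, the index definitions, the ground-sampling scale
#' and the rendering colormap.
#'
#' @param cm_per_pixel Positive ground-sampling distance in cm per pixel.
#' @param bands Named character vector mapping band labels to filenames
#'   inside each sample folder; must include `cfi`.
#' @param segmentation A [segmentation_config()].
#' @param indices List of [index_definition()]s; at least one, and every
#'   referenced band must be in the band map.
#' @param colormap Palette name for false-color renderings.
#' @param exposures Optional named numeric vector of per-band exposures (ms),
#'   as recorded by calibration; carried for provenance.
#' @param log_level `"info"` (per-folder progress) or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cm_per_pixel,
                            bands = c(cfi = "cfi.png", nir = "nir.png",
                                      red = "red.png", green = "green.png",
                                      blue = "blue.png"),
                            segmentation = segmentation_config(),
                            indices = default_indices(),
                            colormap = "viridis",
                            exposures = NULL,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.numeric(cm_per_pixel) || cm_per_pixel <= 0) {
    stop("cm_per_pixel must be a positive real", call. = FALSE)
  }
  if (is.null(names(bands)) || !"cfi" %in% names(bands)) {
    stop("band map must name a 'cfi' file", call. = FALSE)
  }
  if (length(indices) == 0L) {
    stop("at least one index must be defined", call. = FALSE)
  }
  for (defn in indices) {
    stopifnot(inherits(defn, "index_definition"))
    miss <- setdiff(c(defn$band_a, defn$band_b), names(bands))
    if (length(miss)) {
      stop(sprintf("index '%s' references band(s) not in the band map: %s",
                   defn$name, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  names(indices) <- vapply(indices, `[[`, character(1), "name")
  index_colormap(colormap, 2L)   # fail fast on unknown maps
  structure(list(cm_per_pixel = cm_per_pixel, bands = bands,
                 segmentation = segmentation, indices = indices,
                 colormap = colormap, exposures = exposures,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Expected keys: `cm_per_pixel`; optional `bands` (label: filename map),
#' `segmentation` (`lo`, `hi`, `auto_bounds`, `smooth_window`,
#' `min_prominence_frac`, `min_component_px`, `connectivity`,
#' `median_prefilter`), `indices` (list of `{name, band_a, band_b}`),
#' `colormap`, `exposures`, `log_level`.
#'
#' @param path Path to the YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cm_per_pixel)) {
    stop(sprintf("config '%s' must set cm_per_pixel", path), call. = FALSE)
  }
  seg <- do.call(segmentation_config, as.list(y$segmentation))
  idx <- if (is.null(y$indices)) default_indices()
         else lapply(y$indices, function(d) {
           index_definition(d$name, d$band_a, d$band_b)
         })
  args <- list(cm_per_pixel = y$cm_per_pixel, segmentation = seg,
               indices = idx)
  if (!is.null(y$bands)) args$bands <- unlist(y$bands)
  if (!is.null(y$colormap)) args$colormap <- y$colormap
  if (!is.null(y$exposures)) args$exposures <- unlist(y$exposures)
  if (!is.null(y$log_level)) args$log_level <- y$log_level
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  seg <- config$segmentation
  y <- list(cm_per_pixel = config$cm_per_pixel,
            bands = as.list(config$bands),
            segmentation = list(
              lo = seg$lo, hi = seg$hi, auto_bounds = seg$auto_bounds,
              smooth_window = seg$smooth_window,
              min_prominence_frac = seg$min_prominence_frac,
              min_component_px = seg$despeckle$min_component_px,
              connectivity = seg$despeckle$connectivity,
              median_prefilter = seg$despeckle$median_prefilter),
            indices = lapply(unname(config$indices), function(d) {
              list(name = d$name, band_a = d$band_a, band_b = d$band_b)
            }),
            colormap = config$colormap,
            log_level = config$log_level)
  if (!is.null(config$exposures)) y$exposures <- as.list(config$exposures)
  y$segmentation <- Filter(Negate(is.null), y$segmentation)
  yaml::write_yaml(y, path)
  invisible(path)
}

sample_columns <- function(config) {
  idx_cols <- unlist(lapply(names(config$indices), function(nm) {
    paste0(nm, c("_mean", "_std", "_n"))
  }))
  c("set_id", "timestamp", "threshold", "n_foreground_px", "canopy_area_cm2",
    idx_cols, "error")
}

analyze_one <- function(folder, config, out_dir) {
  set <- load_image_set(folder, config)
  seg <- segment(set, config$segmentation)
  n_fg <- sum(seg$mask$pixels)
  area <- canopy_area(seg$mask, config$cm_per_pixel)
  sample_dir <- file.path(out_dir, set$set_id)
  dir.create(sample_dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(seg$mask, file.path(sample_dir, "mask.png"))
  row <- list(set_id = set$set_id, timestamp = NA_character_,
              threshold = seg$threshold$threshold, n_foreground_px = n_fg,
              canopy_area_cm2 = area)
  for (nm in names(config$indices)) {
    img <- compute_index(set, seg$mask, config$indices[[nm]])
    st <- index_stats(img)
    render_false_color(img, config$colormap,
                       file.path(sample_dir, paste0(nm, ".png")))
    write_histogram_csv(st, file.path(sample_dir, paste0(nm, "_hist.csv")))
    row[[paste0(nm, "_mean")]] <- st$mean
    row[[paste0(nm, "_std")]] <- st$std
    row[[paste0(nm, "_n")]] <- st$n_pixels
  }
  row$error <- ""
  row
}

#' Run the batch analysis over a directory of sample folders
#'
#' For each immediate sub-folder of `root` (in lexicographic order): load the
#' image set, segment, measure canopy area, compute every configured index
#' with statistics, and write per-sample artifacts (`mask.png`,
#' `<index>.png` false color + legend, `<index>_hist.csv`) plus one row of
#' `results.csv`. A failing folder is recorded in the CSV's `error` column
#' and skipped; it never aborts the batch.
#'
#' @param root Directory containing one sub-folder per sample.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (default `file.path(root, "analysis")`).
#' @return The results data frame, invisibly; `results.csv` is written to
#'   `out_dir`. Reals are reported at 6 significant digits, and
#'   `canopy_area_cm2 = n_foreground_px * cm_per_pixel^2` holds on every row.
#' @export
run_batch <- function(root, config, out_dir = file.path(root, "analysis")) {
  stopifnot(inherits(config, "pipeline_config"))
  folders <- sort(list.dirs(root, recursive = FALSE))
  folders <- folders[basename(folders) != basename(out_dir)]
  if (length(folders) == 0L) {
    stop(sprintf("no sample folders found under '%s'", root), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- sample_columns(config)
  rows <- lapply(folders, function(folder) {
    t0 <- Sys.time()
    row <- tryCatch(
      analyze_one(folder, config, out_dir),
      error = function(e) {
        list(set_id = basename(folder), error = conditionMessage(e))
      })
    row$timestamp <- format(t0, "%Y-%m-%dT%H:%M:%S")
    if (config$log_level == "info") {
      message(sprintf("[%s] %s (%.2fs)%s", row$timestamp, basename(folder),
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      if (nzchar(row$error %||% "")) paste0(" ERROR: ",
                                                            row$error)
                      else ""))
    }
    missing <- setdiff(cols, names(row))
    row[missing] <- NA
    as.data.frame(row[cols], stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  on_disk <- results
  for (col in names(on_disk)) {   # reals go to disk at 6 significant digits
    if (is.double(on_disk[[col]])) on_disk[[col]] <- signif(on_disk[[col]], 6)
  }
  utils::write.csv(on_disk, file.path(out_dir, "results.csv"),
                   row.names = FALSE, na = "")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a batch results file
#'
#' Prints per-batch means and ranges of canopy area and each index mean;
#' the input file is never modified.
#'
#' @param results_csv Path to a `results.csv` written by [run_batch()].
#' @return The report lines, invisibly.
#' @export
summarize_results <- function(results_csv) {
  df <- tryCatch(suppressWarnings(utils::read.csv(results_csv,
                                                  stringsAsFactors = FALSE)),
                 error = function(e) stop(sprintf("malformed CSV '%s': %s",
                                                  results_csv,
                                                  conditionMessage(e)),
                                          call. = FALSE))
  needed <- c("set_id", "canopy_area_cm2")
  if (!all(needed %in% names(df))) {
    stop(sprintf("malformed CSV '%s': missing columns", results_csv),
         call. = FALSE)
  }
  ok <- df[is.na(df$error) | df$error == "", , drop = FALSE]
  if (nrow(ok) == 0L) {
    lines <- "no samples"
  } else {
    fmt <- function(label, x) {
      x <- x[!is.na(x)]
      sprintf("%s: mean %.6g, range [%.6g, %.6g] (n=%d)", label, mean(x),
              min(x), max(x), length(x))
    }
    lines <- c(sprintf("samples analyzed: %d (of %d rows)", nrow(ok),
                       nrow(df)),
               fmt("canopy_area_cm2", ok$canopy_area_cm2))
    for (col in grep("_mean$", names(df), value = TRUE)) {
      lines <- c(lines, fmt(col, ok[[col]]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
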