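# Independent oracles, deliberately written with naive loops so they share no
# code path with the implementation they check.

# Moving average with replicated-edge padding, one bin at a time.
oracle_smooth <- function(counts, window) {
  half <- (window - 1) / 2
  out <- numeric(256)
  for (i in 1:256) {
    acc <- 0
    for (k in -half:half) {
      j <- min(max(i + k, 1), 256)
      acc <- acc + counts[j]
    }
    out[i] <- acc / window
  }
  out
}

# Exhaustive argmin scan of the independently smoothed histogram.
oracle_valley <- function(counts, lo, hi, window) {
  sm <- oracle_smooth(counts, window)
  best <- lo
  for (t in lo:hi) {
    if (sm[t + 1] < sm[best + 1]) best <- t
  }
  best
}

# Brute-force flood fill labeling.
oracle_components <- function(px, connectivity) {
  nr <- nrow(px); nc <- ncol(px)
  labels <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (px[r, c] && labels[r, c] == 0L) {
      lab <- lab + 1L
      queue <- list(c(r, c))
      labels[r, c] <- lab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in nbr) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              px[q[1], q[2]] && labels[q[1], q[2]] == 0L) {
            labels[q[1], q[2]] <- lab
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  labels
}

random_histogram <- function() {
  counts <- integer(256)
  n_nonzero <- sample(1:80, 1)
  bins <- sample(1:256, n_nonzero)
  counts[bins] <- sample(0:500, n_nonzero, replace = TRUE)
  counts
}

random_image <- function(nr = 16, nc = 16) {
  waveband_image(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc), "cfi")
}

mask_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}

test_config <- function(...) {
  pipeline_config(cm_per_pixel = 0.05,
                  bands = c(cfi = "cfi.png", nir = "nir.png", red = "red.png",
                            green = "green.png", blue = "blue.png"),
                  log_level = "quiet", ...)
}
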