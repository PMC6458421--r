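# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# a mid-sized scene with its saliency map and partition, shared across files
fixture_scene <- function() memo("scene", {
  generate_scene(random_scene_spec(seed = 3, width_px = 640, height_px = 480),
                 seed = 3, scene_id = 1L)
})

fixture_saliency <- function() memo("saliency", {
  compute_saliency_map(fixture_scene(), saliency_params())
})

fixture_partition <- function() memo("partition", {
  build_roi_partition(fixture_scene(), fixture_saliency())
})

fixture_geometry <- function() geometry()  # 640 x 480 px on 30.6 x 23.0 cm

# noiseless behaviour: detection must match the generator truth exactly;
# dots override the zeroed defaults
noiseless_params <- function(...) {
  args <- list(noise_sd_px = 0, blink_rate_hz = 0, drift_sd_px = 0,
               misfixation_prob = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(behaviour_params, args)
}

# RGB array with a filled disc
disc_image <- function(h, w, cx, cy, r, fg = 1, bg = 0) {
  x <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  y <- matrix(seq_len(h) - 0.5, h, w)
  m <- matrix(bg, h, w)
  m[(x - cx)^2 + (y - cy)^2 <= r^2] <- fg
  array(rep(m, 3), dim = c(h, w, 3))
}

grey_image <- function(h, w, level = 0.5) {
  array(level, dim = c(h, w, 3))
}

# constant-position gaze samples
flat_samples <- function(n_ms = 500, x = 320, y = 240, t0 = 0) {
  tibble::tibble(t_ms = t0 + seq_len(n_ms) - 1, x_px = x, y_px = y,
                 pupil = 1000)
}

# a hand-built trace: fixation, one raised-cosine saccade, fixation
saccade_samples <- function(amp_px = 150, dur_ms = 40, pre_ms = 300,
                            post_ms = 300, x0 = 200, y0 = 240) {
  t <- seq(0, pre_ms + dur_ms + post_ms - 1)
  x <- rep(x0, length(t))
  inside <- t >= pre_ms & t < pre_ms + dur_ms
  tau <- (t[inside] - pre_ms) / dur_ms
  x[inside] <- x0 + amp_px * (tau - sin(2 * pi * tau) / (2 * pi))
  x[t >= pre_ms + dur_ms] <- x0 + amp_px
  tibble::tibble(t_ms = t, x_px = x, y_px = y0, pupil = 1000)
}

# brute-force centre-surround conspicuity oracle on the intensity channel:
# block-average the image onto a coarse lattice, score each cell by its
# difference from the mean of the surrounding cells, return the argmax cell
brute_force_saliency_argmax <- function(image, cell_px, surround_cells = 2) {
  intens <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  nr <- nrow(intens) %/% cell_px
  nc <- ncol(intens) %/% cell_px
  lat <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      lat[i, j] <- mean(intens[((i - 1) * cell_px + 1):(i * cell_px),
                               ((j - 1) * cell_px + 1):(j * cell_px)])
    }
  }
  score <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      neigh <- c()
      for (di in -surround_cells:surround_cells) {
        for (dj in -surround_cells:surround_cells) {
          ii <- i + di; jj <- j + dj
          if ((di != 0 || dj != 0) && ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            neigh <- c(neigh, lat[ii, jj])
          }
        }
      }
      score[i, j] <- abs(lat[i, j] - mean(neigh))
    }
  }
  best <- unname(which(score == max(score), arr.ind = TRUE)[1, ])
  # centre of the winning cell, in image pixels (y, x)
  c(y = (best[1] - 0.5) * cell_px, x = (best[2] - 0.5) * cell_px)
}
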