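#' Parameters of the low-level saliency model
#'
#' The model scores each scene location by how strongly it differs from its
#' surround in three low-level features: colour, intensity and orientation.
#' Feature maps are computed at several analysis scales (fractions of the
#' original resolution), combined on a common coarse reference lattice,
#' averaged within and then across features, and the overall map is resized
#' back to the input resolution.
#'
#' Two backends are available. `"centre_surround"` (the default) scores each
#' feature map by the absolute difference between the map and a
#' Gaussian-smoothed surround, in the tradition of Itti & Koch-style models.
#' `"graph_activation"` treats the reference lattice as a fully connected
#' graph whose edge weights combine feature dissimilarity with a Gaussian
#' falloff in lattice distance, and takes the equilibrium (stationary)
#' distribution of the induced Markov chain as the activation map. Both are
#' qualitatively similar on the blob-like conspicuity structure the ROI
#' partition consumes; neither claims numerical fidelity to any specific
#' published binary.
#'
#' @param scales Analysis scales as fractions of the input resolution.
#' @param reference_scale Fraction of the input resolution defining the
#'   common lattice on which maps are combined; must not exceed the smallest
#'   analysis scale.
#' @param features Subset of `c("colour", "intensity", "orientation")`.
#' @param backend `"centre_surround"` or `"graph_activation"`.
#' @param surround_sigma_frac Centre-surround backend: surround Gaussian
#'   sigma as a fraction of the smaller image dimension at each scale.
#' @param graph_sigma_frac Graph backend: Gaussian distance bandwidth of the
#'   edge weights, as a fraction of the larger reference-lattice dimension.
#' @param graph_tol,graph_max_iter Power-iteration stopping tolerance
#'   (L1 change of the stationary vector) and iteration cap.
#'
#' @return An object of class `saliency_params`.
#' @export
saliency_params <- function(scales = c(0.5, 0.25, 0.125),
                            reference_scale = 0.027,
                            features = c("colour", "intensity", "orientation"),
                            backend = c("centre_surround", "graph_activation"),
                            surround_sigma_frac = 0.1,
                            graph_sigma_frac = 0.15,
                            graph_tol = 1e-9,
                            graph_max_iter = 10000L) {
  backend <- match.arg(backend)
  features <- match.arg(features, several.ok = TRUE)
  if (any(scales <= 0) || any(scales > 1)) {
    abort("analysis scales must lie in (0, 1]")
  }
  if (reference_scale <= 0 || reference_scale > min(scales)) {
    abort("reference_scale must be positive and no larger than the smallest analysis scale")
  }
  structure(
    list(scales = sort(scales, decreasing = TRUE),
         reference_scale = reference_scale,
         features = features, backend = backend,
         surround_sigma_frac = surround_sigma_frac,
         graph_sigma_frac = graph_sigma_frac,
         graph_tol = graph_tol,
         graph_max_iter = as.integer(graph_max_iter)),
    class = "saliency_params"
  )
}

#' Decompose an RGB image into low-level feature channels
#'
#' Produces the channels the saliency model is built from: an intensity
#' channel, two colour-opponency channels (red-green and blue-yellow, with
#' yellow taken as the mean of red and green), and four orientation-energy
#' channels obtained from quadrature Gabor pairs at 0, 45, 90 and 135
#' degrees of stripe orientation.
#'
#' @param image A height x width x 3 numeric array with values in `[0, 1]`,
#'   or a [generate_scene()] object.
#' @param wavelength Gabor carrier wavelength in pixels.
#'
#' @return A named list of numeric matrices: `intensity`, `rg`, `by`,
#'   `ori_0`, `ori_45`, `ori_90`, `ori_135`.
#' @export
compute_feature_channels <- function(image, wavelength = 7) {
  image <- as_rgb_array(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  intensity <- (r + g + b) / 3
  chans <- list(
    intensity = intensity,
    rg = r - g,
    by = b - (r + g) / 2
  )
  max_size <- 2 * ((min(dim(intensity)) - 1) %/% 2) + 1
  for (th in c(0, 45, 90, 135)) {
    gp <- gabor_pair(th, wavelength = wavelength, max_size = max_size)
    e <- conv_mat(intensity, gp$even)
    o <- conv_mat(intensity, gp$odd)
    chans[[paste0("ori_", th)]] <- sqrt(e^2 + o^2)
  }
  chans
}

as_rgb_array <- function(image) {
  if (inherits(image, "scene")) image <- image$image
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an RGB array (height x width x 3) or a scene")
  }
  image
}

#' Compute a saliency map for a scene
#'
#' See [saliency_params()] for the model. The returned map has the scene's
#' pixel dimensions, is non-negative, and is scaled so its maximum equals 1;
#' a zero-variance input yields the all-zero map (nothing differs from its
#' surround).
#'
#' @param image RGB array (height x width x 3, values in `[0, 1]`) or scene.
#' @param params A [saliency_params()] object.
#'
#' @return An object of class `saliency_map` with elements `values`
#'   (matrix), `backend` and `params`.
#' @examples
#' scn <- generate_scene(random_scene_spec(seed = 1, width_px = 160, height_px = 120), seed = 1)
#' sal <- compute_saliency_map(scn, saliency_params())
#' range(sal$values)
#' @export
compute_saliency_map <- function(image, params = saliency_params()) {
  stopifnot(inherits(params, "saliency_params"))
  image <- as_rgb_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  ref_h <- round(h * params$reference_scale)
  ref_w <- round(w * params$reference_scale)
  if (ref_h < 2 || ref_w < 2) {
    abort(sprintf(
      "image (%d x %d) is smaller than the reference-scale lattice allows; increase reference_scale",
      h, w))
  }

  feature_channels <- list(
    intensity = "intensity",
    colour = c("rg", "by"),
    orientation = c("ori_0", "ori_45", "ori_90", "ori_135")
  )

  per_feature <- lapply(params$features, function(feat) {
    maps <- list()
    for (s in params$scales) {
      sh <- max(2, round(h * s)); sw <- max(2, round(w * s))
      scaled <- array(0, dim = c(sh, sw, 3))
      for (k in 1:3) scaled[, , k] <- resize_mat(image[, , k], sh, sw)
      chans <- compute_feature_channels(scaled)
      for (nm in feature_channels[[feat]]) {
        m <- chans[[nm]]
        act <- switch(params$backend,
          centre_surround = centre_surround_activation(m, params),
          graph_activation = m
        )
        act <- resize_mat(act, ref_h, ref_w)
        if (params$backend == "graph_activation") {
          act <- graph_activation(act, params)
        }
        maps[[length(maps) + 1]] <- normalize_conspicuity(act)
      }
    }
    Reduce(`+`, maps) / length(maps)
  })

  overall <- Reduce(`+`, per_feature) / length(per_feature)
  overall <- resize_mat(overall, h, w)
  overall[overall < 0] <- 0
  mx <- max(overall)
  values <- if (mx > 1e-12) overall / mx else matrix(0, h, w)

  structure(
    list(values = values, backend = params$backend, params = params),
    class = "saliency_map"
  )
}

# |centre - surround| at the map's own scale
centre_surround_activation <- function(m, params) {
  sigma <- max(2, min(dim(m)) * params$surround_sigma_frac)
  abs(m - blur_mat(m, sigma))
}

# Equilibrium distribution of a Markov chain on the lattice whose transition
# mass from node j to node i is |v_i - v_j| * exp(-d_ij^2 / (2 sigma^2)).
graph_activation <- function(m, params) {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  # a (numerically) featureless map excites nothing; guard against
  # floating-point ripple introduced by resampling a constant channel
  if (diff(range(m)) <= 1e-10 * max(abs(m), 1)) return(matrix(0, nr, nc))
  v <- as.vector(m)
  ij <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d2 <- outer(ij[, 1], ij[, 1], `-`)^2 + outer(ij[, 2], ij[, 2], `-`)^2
  sigma <- params$graph_sigma_frac * max(nr, nc)
  W <- abs(outer(v, v, `-`)) * exp(-d2 / (2 * sigma^2))
  diag(W) <- 0
  cs <- colSums(W)
  if (all(cs <= 1e-15)) return(matrix(0, nr, nc))  # featureless map
  zero <- cs <= 1e-15
  W[, zero] <- 1 / n  # dangling nodes jump uniformly
  cs[zero] <- 1
  P <- sweep(W, 2, cs, `/`)
  p <- rep(1 / n, n)
  for (iter in seq_len(params$graph_max_iter)) {
    p_new <- as.vector(P %*% p)
    if (sum(abs(p_new - p)) < params$graph_tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  matrix(p, nr, nc)
}

# Rescale to [0, 1] and weight by global uniqueness: maps with one dominant
# peak keep their magnitude, near-uniform maps are suppressed. A cheap
# stand-in for iterative within-map normalization.
normalize_conspicuity <- function(m) {
  mn <- min(m); mx <- max(m)
  if (mx - mn < 1e-15) return(matrix(0, nrow(m), ncol(m)))
  m01 <- (m - mn) / (mx - mn)
  m01 * (1 - mean(m01))^2
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d px, backend %s, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$backend,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Relative saliency of a region of interest
#'
#' The mean saliency inside the region divided by the mean saliency of the
#' whole scene. Values above 1 indicate above-average physical saliency.
#'
#' @param map A [compute_saliency_map()] object or a plain numeric matrix.
#' @param roi_mask Logical matrix of the map's dimensions selecting the
#'   region.
#'
#' @return A single ratio.
#' @export
relative_roi_saliency <- function(map, roi_mask) {
  values <- if (inherits(map, "saliency_map")) map$values else map
  stopifnot(is.matrix(values), is.logical(roi_mask))
  if (!identical(dim(values), dim(roi_mask))) {
    abort("`roi_mask` must have the map's dimensions")
  }
  if (!any(roi_mask)) abort("relative saliency is undefined for an empty mask")
  scene_mean <- mean(values)
  if (scene_mean <= 0) abort("relative saliency is undefined for an all-zero map")
  mean(values[roi_mask]) / scene_mean
}

#' Heat-map display of a saliency map
#'
#' @param object A `saliency_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- expand.grid(y = seq_len(nrow(object$values)),
                    x = seq_len(ncol(object$values)))
  df$saliency <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("saliency (%s)", object$backend))
}

#' Write / read a saliency map as a 16-bit greyscale PNG
#'
#' Values are stored on their `[0, 1]` scale. A plain-text writer
#' ([write_saliency_text()]) is also provided for lossless exchange.
#'
#' @param map A `saliency_map` object.
#' @param path Output file path.
#' @return `write_saliency_png()` returns `path` invisibly;
#'   `read_saliency_png()` returns a numeric matrix.
#' @export
write_saliency_png <- function(map, path) {
  stopifnot(inherits(map, "saliency_map"))
  v <- pmin(pmax(map$values, 0), 1)
  write_png16_grey(v * 65535, path)
  invisible(path)
}

#' @rdname write_saliency_png
#' @export
read_saliency_png <- function(path) {
  png::readPNG(path)
}

#' @rdname write_saliency_png
#' @export
write_saliency_text <- function(map, path) {
  values <- if (inherits(map, "saliency_map")) map$values else map
  write.table(values, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
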