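#' Specify a synthetic scene
#'
#' A scene is a grey background of mean luminance `background`, optional
#' smooth luminance texture, a set of social shapes (bodies, with heads on
#' top) rendered in muted, low-contrast colours, and a set of distractor
#' patches rendered as high-contrast concentric rings. The distractors are
#' deliberately more conspicuous to the low-level saliency model than the
#' social regions, emulating stimulus sets in which non-social scene parts
#' out-rank the social regions in physical saliency.
#'
#' Shapes are parametric: `list(type = "ellipse", cx, cy, rx, ry,
#' angle = 0, colour = c(r, g, b))` or `list(type = "polygon", x, y,
#' colour = c(r, g, b))`, all in pixel coordinates. Every shape must lie
#' fully on screen.
#'
#' The default (no shapes, zero texture) is the degenerate uniform scene;
#' use [random_scene_spec()] for realistic layouts.
#'
#' @param width_px,height_px Scene size in pixels.
#' @param head_regions,body_regions Lists of shapes.
#' @param distractor_patches List of patch specs: `list(cx, cy, radius)`.
#' @param background Mean background luminance in `[0, 1]`.
#' @param texture_amplitude Amplitude of the smooth background luminance
#'   texture (0 = flat).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 640L, height_px = 480L,
                       head_regions = list(), body_regions = list(),
                       distractor_patches = list(),
                       background = 0.5, texture_amplitude = 0) {
  if (width_px < 8 || height_px < 8) abort("scene must be at least 8 x 8 px")
  spec <- structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         head_regions = head_regions, body_regions = body_regions,
         distractor_patches = distractor_patches,
         background = background, texture_amplitude = texture_amplitude),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  w <- spec$width_px; h <- spec$height_px
  check_shape <- function(s, what) {
    bb <- shape_bbox(s)
    if (bb["x0"] < 0 || bb["y0"] < 0 || bb["x1"] > w || bb["y1"] > h) {
      abort(sprintf("%s shape extends off-screen", what))
    }
  }
  for (s in spec$head_regions) check_shape(s, "head")
  for (s in spec$body_regions) check_shape(s, "body")
  for (p in spec$distractor_patches) {
    if (p$cx - p$radius < 0 || p$cx + p$radius > w ||
        p$cy - p$radius < 0 || p$cy + p$radius > h) {
      abort("distractor patch extends off-screen")
    }
  }
  invisible(spec)
}

shape_bbox <- function(s) {
  if (s$type == "ellipse") {
    r <- max(s$rx, s$ry)  # conservative for rotated ellipses
    c(x0 = s$cx - r, y0 = s$cy - r, x1 = s$cx + r, y1 = s$cy + r)
  } else {
    c(x0 = min(s$x), y0 = min(s$y), x1 = max(s$x), y1 = max(s$y))
  }
}

shape_mask <- function(s, h, w) {
  x <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  y <- matrix(seq_len(h) - 0.5, h, w)
  if (s$type == "ellipse") {
    ang <- (s$angle %||% 0) * pi / 180
    dx <- x - s$cx; dy <- y - s$cy
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    (u / s$rx)^2 + (v / s$ry)^2 <= 1
  } else if (s$type == "polygon") {
    point_in_polygon(as.vector(x), as.vector(y), s$x, s$y) |>
      matrix(h, w)
  } else {
    abort(sprintf("unknown shape type '%s'", s$type))
  }
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Draw a random scene layout
#'
#' One or two person figures (body ellipse with a head ellipse on top) in
#' muted colours plus several high-contrast ring distractors, positioned
#' without mutual overlap, over a lightly textured background. Head and
#' body coverages land in the low-percent range typical of social scene
#' photographs.
#'
#' @param seed Integer seed; the layout is a deterministic function of it.
#' @param width_px,height_px Scene size.
#' @param n_people,n_distractors Counts; sampled if `NULL` (1-2 people,
#'   2-4 distractors).
#' @param background Mean background luminance.
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(seed, width_px = 640L, height_px = 480L,
                              n_people = NULL, n_distractors = NULL,
                              background = 0.5) {
  withr::with_seed(seed, {
    w <- width_px; h <- height_px
    sc <- min(w, h) / 480
    n_people <- n_people %||% sample(1:2, 1)
    n_distractors <- n_distractors %||% sample(2:4, 1)
    heads <- list(); bodies <- list(); patches <- list()
    taken <- matrix(NA_real_, 0, 3)  # cx, cy, clearance radius
    place <- function(radius, margin) {
      best <- NULL; best_d <- -Inf
      for (try in 1:300) {
        cx <- runif(1, radius + margin, w - radius - margin)
        cy <- runif(1, radius + margin, h - radius - margin)
        d <- if (nrow(taken) == 0) Inf else {
          min(sqrt((taken[, 1] - cx)^2 + (taken[, 2] - cy)^2) - taken[, 3])
        }
        if (d > radius) return(c(cx, cy))
        if (d > best_d) { best_d <- d; best <- c(cx, cy) }
      }
      best  # crowded layout: tolerate some overlap rather than fail
    }
    for (i in seq_len(n_people)) {
      brx <- runif(1, 40, 60) * sc
      bry <- runif(1, 95, 125) * sc
      hrx <- runif(1, 26, 36) * sc
      hry <- 1.2 * hrx
      # head sits on top of the body, slightly overlapping its upper rim
      reach_up <- bry + 1.1 * hry
      pos <- place(reach_up, 4)
      taken <- rbind(taken, c(pos, max(brx, hrx) + 10 * sc))
      bodies[[i]] <- list(type = "ellipse", cx = pos[1], cy = pos[2],
                          rx = brx, ry = bry,
                          colour = 0.5 + runif(3, -0.12, 0.12))
      heads[[i]] <- list(type = "ellipse", cx = pos[1],
                         cy = pos[2] - bry - 0.1 * hry,
                         rx = hrx, ry = hry,
                         colour = c(0.63, 0.52, 0.44) + runif(3, -0.04, 0.04))
    }
    for (i in seq_len(n_distractors)) {
      r <- runif(1, 34, 52) * sc
      pos <- place(r, 4)
      taken <- rbind(taken, c(pos, r + 6 * sc))
      patches[[i]] <- list(cx = pos[1], cy = pos[2], radius = r)
    }
    scene_spec(w, h, head_regions = heads, body_regions = bodies,
               distractor_patches = patches, background = background,
               texture_amplitude = 0.03)
  })
}

#' Render a scene from its specification
#'
#' Deterministic under a fixed seed (the seed drives the background texture
#' and the distractor ring colours). Distractor patches are drawn as
#' concentric rings alternating between two saturated, opposed colours,
#' giving them higher local contrast — and higher relative saliency — than
#' the muted social shapes.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @param scene_id Optional identifier carried through the pipeline.
#' @return An object of class `scene`: RGB array `image`
#'   (height x width x 3), logical `head_mask` and `body_mask`, sizes and
#'   the spec.
#' @examples
#' scn <- generate_scene(random_scene_spec(seed = 3, 160, 120), seed = 3)
#' mean(scn$head_mask)
#' @export
generate_scene <- function(spec, seed, scene_id = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  h <- spec$height_px; w <- spec$width_px
  withr::with_seed(seed, {
    img <- array(spec$background, dim = c(h, w, 3))
    if (spec$texture_amplitude > 0) {
      noise <- matrix(rnorm(h * w), h, w)
      tex <- blur_mat(noise, max(2, min(h, w) / 40))
      tex <- tex / max(abs(tex), 1e-12) * spec$texture_amplitude
      for (k in 1:3) img[, , k] <- img[, , k] + tex
    }
    x <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
    y <- matrix(seq_len(h) - 0.5, h, w)
    for (p in spec$distractor_patches) {
      r <- sqrt((x - p$cx)^2 + (y - p$cy)^2)
      inside <- r <= p$radius
      ring <- (floor(r / (p$radius / 4)) %% 2) == 0
      c1 <- c(0.95, 0.85, 0.05) + runif(3, -0.05, 0.05)
      c2 <- c(0.05, 0.15, 0.9) + runif(3, -0.05, 0.05)
      for (k in 1:3) {
        ch <- img[, , k]
        ch[inside & ring] <- c1[k]
        ch[inside & !ring] <- c2[k]
        img[, , k] <- ch
      }
    }
    head_mask <- matrix(FALSE, h, w)
    body_mask <- matrix(FALSE, h, w)
    paint <- function(sh) {
      m <- shape_mask(sh, h, w)
      for (k in 1:3) {
        ch <- img[, , k]
        ch[m] <- sh$colour[k]
        img[, , k] <<- ch
      }
      m
    }
    for (sh in spec$body_regions) body_mask <- body_mask | paint(sh)
    for (sh in spec$head_regions) head_mask <- head_mask | paint(sh)
    img[img < 0] <- 0; img[img > 1] <- 1
    structure(
      list(image = img, head_mask = head_mask, body_mask = body_mask,
           width_px = w, height_px = h, spec = spec,
           scene_id = scene_id,
           head_fraction = mean(head_mask),
           body_fraction = mean(body_mask & !head_mask)),
      class = "scene"
    )
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s> %d x %d px, head %.1f%%, body %.1f%%\n",
              format(x$scene_id), x$width_px, x$height_px,
              100 * x$head_fraction, 100 * x$body_fraction))
  invisible(x)
}

#' @method autoplot scene
#' @export
autoplot.scene <- function(object, ...) {
  df <- expand.grid(y = seq_len(object$height_px), x = seq_len(object$width_px))
  df$fill <- grDevices::rgb(object$image[, , 1], object$image[, , 2],
                            object$image[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed()
}

#' Build a bank of random scenes
#'
#' @param n_scenes Number of scenes.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param ... Passed to [random_scene_spec()].
#' @return A list of [generate_scene()] objects with `scene_id` 1..n.
#' @export
build_scene_bank <- function(n_scenes, seed, ...) {
  lapply(seq_len(n_scenes), function(i) {
    s <- derive_seed(seed, 1000 + i)
    generate_scene(random_scene_spec(seed = s, ...), seed = s, scene_id = i)
  })
}

# deterministic 32-bit-safe child seeds
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

#' Write scene images and label masks as PNG
#'
#' The label mask uses 0 = background, 1 = head, 2 = body.
#'
#' @param scene A `scene`.
#' @param image_path,mask_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_scene_png <- function(scene, image_path, mask_path = NULL) {
  png::writePNG(scene$image, image_path)
  if (!is.null(mask_path)) {
    lab <- matrix(0L, scene$height_px, scene$width_px)
    lab[scene$body_mask] <- 2L
    lab[scene$head_mask] <- 1L
    png::writePNG(lab / 255, mask_path)
  }
  invisible(c(image_path, mask_path))
}

#' @rdname write_scene_png
#' @param path PNG path of a label mask written by [write_scene_png()].
#' @return `read_social_masks()` returns `list(head = , body = )` logical
#'   matrices.
#' @export
read_social_masks <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  list(head = lab == 1, body = lab == 2)
}
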