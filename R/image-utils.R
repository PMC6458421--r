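# Internal raster helpers. Throughout the package an image channel is a
# numeric matrix indexed [row = y, col = x]; EBImage stores [x, y], hence
# the transposes at the boundary.

resize_mat <- function(m, new_h, new_w) {
  if (nrow(m) == new_h && ncol(m) == new_w) return(m)
  img <- EBImage::Image(t(m))
  out <- EBImage::resize(img, w = new_w, h = new_h, filter = "bilinear")
  t(EBImage::imageData(out))
}

conv_mat <- function(m, kernel) {
  # kernel dims must be odd and no larger than the image
  img <- EBImage::Image(t(m))
  out <- EBImage::filter2(img, t(kernel), boundary = "replicate")
  t(EBImage::imageData(out))
}

gaussian_kernel <- function(sigma, max_size = Inf) {
  half <- ceiling(3 * sigma)
  size <- 2 * half + 1
  if (size > max_size) {
    half <- max((max_size - 1) %/% 2, 1)
    size <- 2 * half + 1
  }
  ax <- seq(-half, half)
  k1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

blur_mat <- function(m, sigma) {
  max_size <- 2 * ((min(dim(m)) - 1) %/% 2) + 1
  if (max_size < 3) return(m)
  conv_mat(m, gaussian_kernel(sigma, max_size = max_size))
}

# quadrature (even/odd) Gabor pair; theta in degrees is the orientation of
# the stripes the filter responds to (0 = horizontal stripes)
gabor_pair <- function(theta_deg, wavelength = 7, sigma = 0.56 * wavelength,
                       gamma = 0.5, max_size = Inf) {
  half <- ceiling(2.5 * sigma)
  size <- 2 * half + 1
  if (size > max_size) {
    half <- max((max_size - 1) %/% 2, 1)
    size <- 2 * half + 1
  }
  ax <- seq(-half, half)
  x <- matrix(ax, size, size, byrow = TRUE)
  y <- matrix(ax, size, size)
  th <- theta_deg * pi / 180
  xp <- x * sin(th) + y * cos(th)   # varies perpendicular to the stripes
  yp <- x * cos(th) - y * sin(th)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xp / wavelength)
  odd <- env * sin(2 * pi * xp / wavelength)
  even <- even - mean(even)  # zero DC response
  list(even = even, odd = odd)
}

# row/col (y, x) of the maximum of a matrix
mat_argmax <- function(m) {
  i <- which.max(m)
  c(row = (i - 1) %% nrow(m) + 1, col = (i - 1) %/% nrow(m) + 1)
}
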