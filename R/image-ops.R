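# Low-level grayscale image operations shared by the preprocessing,
# augmentation and difference-map stages. All operate on plain numeric
# matrices; padding is reflective unless noted.

# Reflect an index vector into [1, n] ("symmetric" boundary: 0 -> 1, -1 -> 2,
# n+1 -> n, ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Separable filtering with a 1-D kernel applied along rows then columns,
# reflective padding, output size unchanged.
sep_filter <- function(img, kernel) {
  k <- length(kernel)
  mv_assert(k %% 2L == 1L, "kernel length must be odd")
  half <- (k - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  # rows
  out <- matrix(0, n, m)
  for (t in seq_len(k)) {
    idx <- reflect_index(seq_len(n) + (t - 1L) - half, n)
    out <- out + kernel[t] * img[idx, , drop = FALSE]
  }
  res <- matrix(0, n, m)
  for (t in seq_len(k)) {
    idx <- reflect_index(seq_len(m) + (t - 1L) - half, m)
    res <- res + kernel[t] * out[, idx, drop = FALSE]
  }
  res
}

# Normalized Gaussian kernel of given sigma; radius defaults to ceil(3*sigma).
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 3x3 box blur with reflective padding.
box_blur3 <- function(img) sep_filter(img, rep(1 / 3, 3))

# Bilinear sampling of `img` at fractional (row, col) coordinates, with
# reflective handling of out-of-range coordinates.
bilinear_sample <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i0 <- reflect_index(as.integer(r0), n); i1 <- reflect_index(as.integer(r0) + 1L, n)
  j0 <- reflect_index(as.integer(c0), m); j1 <- reflect_index(as.integer(c0) + 1L, m)
  v00 <- img[cbind(i0, j0)]; v01 <- img[cbind(i0, j1)]
  v10 <- img[cbind(i1, j0)]; v11 <- img[cbind(i1, j1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Resize a grayscale image with bilinear interpolation
#'
#' Downscaling applies a Gaussian anti-aliasing pre-filter
#' (`sigma = (scale - 1) / 2`) so mean intensity is approximately
#' preserved for smooth images.
#'
#' @param img Numeric matrix.
#' @param size Output side length (the output is `size` x `size`).
#' @return Numeric `size` x `size` matrix.
#' @export
resize_image <- function(img, size) {
  img <- as_pixels(img)
  mv_assert(is_number(size) && size >= 1, "size must be >= 1")
  size <- as.integer(size)
  n <- nrow(img); m <- ncol(img)
  if (n == size && m == size) return(img)
  sr <- n / size; sc <- m / size
  if (max(sr, sc) > 1) {
    sigma <- (max(sr, sc) - 1) / 2
    if (sigma > 1e-8) img <- sep_filter(img, gaussian_kernel(sigma))
  }
  # pixel-center alignment
  rr <- (seq_len(size) - 0.5) * sr + 0.5
  cc <- (seq_len(size) - 0.5) * sc + 0.5
  grid_r <- matrix(rr, size, size)
  grid_c <- matrix(cc, size, size, byrow = TRUE)
  matrix(bilinear_sample(img, as.vector(grid_r), as.vector(grid_c)), size, size)
}

#' Rotate a square grayscale image about its center
#'
#' Bilinear interpolation with reflective padding. Angles that are exact
#' multiples of 90 degrees are applied by index permutation (no
#' interpolation error).
#'
#' @param img Numeric square matrix.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(img, angle) {
  img <- as_pixels(img)
  mv_assert(nrow(img) == ncol(img), "rotate_image requires a square image")
  a <- angle %% 360
  if (isTRUE(all.equal(a, 0))) return(img)
  if (isTRUE(all.equal(a %% 90, 0))) {
    q <- (round(a) %/% 90) %% 4
    out <- img
    for (i in seq_len(q)) out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
    return(out)
  }
  n <- nrow(img)
  ctr <- (n + 1) / 2
  th <- angle * pi / 180
  xs <- seq_len(n) - ctr
  gr <- matrix(xs, n, n)              # row offsets
  gc <- matrix(xs, n, n, byrow = TRUE) # col offsets
  # inverse mapping: sample source at R(-theta) * (r, c)
  src_r <- cos(th) * gr + sin(th) * gc + ctr
  src_c <- -sin(th) * gr + cos(th) * gc + ctr
  matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c)), n, n)
}

#' Horizontal / vertical reflections and the polar flip
#'
#' `flip_horizontal()` mirrors columns, `flip_vertical()` mirrors rows,
#' and `polar_flip()` composes the two — which equals an exact 180-degree
#' rotation and is its own inverse.
#'
#' @param img Numeric matrix.
#' @return Matrix of the same size.
#' @export
flip_horizontal <- function(img) {
  img <- as_pixels(img)
  img[, rev(seq_len(ncol(img))), drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(img) {
  img <- as_pixels(img)
  img[rev(seq_len(nrow(img))), , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
polar_flip <- function(img) flip_vertical(flip_horizontal(img))
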