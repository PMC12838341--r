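#' Preprocessing configuration
#'
#' Settings for the fixed image-preparation chain applied before model
#' training: grayscale conversion, contrast-limited adaptive histogram
#' equalization (CLAHE), unsharp-mask sharpening, resizing, and min-max
#' normalization (always applied, in that order; individual enhancement
#' stages can be disabled).
#'
#' @param clahe_clip_limit Histogram clip limit as a multiple of the mean
#'   tile bin height (> 0). Default 2.0, the conventional value.
#' @param clahe_tile_grid Integer vector `(rows, cols)` of CLAHE tiles,
#'   each >= 1. Default `c(8, 8)`.
#' @param sharpen_strength Unsharp-mask strength (>= 0). Default 1.
#' @param target_size Output side length in pixels (>= 16).
#' @param do_grayscale,do_clahe,do_sharpen Stage flags.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2.0, clahe_tile_grid = c(8L, 8L),
                              sharpen_strength = 1.0, target_size = 64L,
                              do_grayscale = TRUE, do_clahe = TRUE,
                              do_sharpen = TRUE) {
  mv_assert(is_number(clahe_clip_limit) && clahe_clip_limit > 0,
            "clahe_clip_limit must be > 0")
  mv_assert(length(clahe_tile_grid) == 2L && all(clahe_tile_grid >= 1),
            "clahe_tile_grid must be two integers >= 1")
  mv_assert(is_number(sharpen_strength) && sharpen_strength >= 0,
            "sharpen_strength must be >= 0")
  mv_assert(is_number(target_size) && target_size >= 16, "target_size must be >= 16")
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 sharpen_strength = sharpen_strength,
                 target_size = as.integer(target_size),
                 do_grayscale = isTRUE(do_grayscale),
                 do_clahe = isTRUE(do_clahe),
                 do_sharpen = isTRUE(do_sharpen)),
            class = "preprocess_config")
}

#' Convert an image to a single gray channel
#'
#' Three-channel inputs are combined with the Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); single-channel inputs pass through unchanged.
#'
#' @param image Numeric matrix (H x W) or array (H x W x C with C in
#'   \{1, 3\}).
#' @return Numeric H x W matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  mv_assert(is.array(image) && length(dim(image)) == 3L,
            "expected a matrix or an H x W x C array")
  ch <- dim(image)[3]
  if (ch == 1L) return(image[, , 1L])
  mv_assert(ch == 3L, sprintf("unsupported channel count: %d", ch))
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles; each tile's 256-bin
#' histogram is clipped at `clip_limit` times the mean bin height, the
#' excess is redistributed uniformly, and the clipped CDF defines the
#' tile's intensity mapping. Each pixel is remapped by bilinear
#' interpolation between the mappings of the four nearest tile centers.
#' Input and output are on \[0, 1\].
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param config A [preprocess_config()] (only the CLAHE fields are used).
#' @return Numeric matrix in \[0, 1\].
#' @export
apply_clahe <- function(image, config = preprocess_config()) {
  img <- as_pixels(image)
  mv_assert(all(is.finite(img)), "image must be finite")
  nbins <- 256L
  H <- nrow(img); W <- ncol(img)
  tr <- min(config$clahe_tile_grid[1], H)
  tc <- min(config$clahe_tile_grid[2], W)
  bins <- pmin(pmax(floor(clamp(img, 0, 1) * nbins), 0), nbins - 1L)  # 0-based

  # tile boundaries (nearly equal splits)
  rb <- floor(seq(0, H, length.out = tr + 1L))
  cb <- floor(seq(0, W, length.out = tc + 1L))
  luts <- array(0, dim = c(tr, tc, nbins))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (i in seq_len(tr)) {
    rows <- (rb[i] + 1L):rb[i + 1L]
    centers_r[i] <- mean(range(rows))
    for (j in seq_len(tc)) {
      cols <- (cb[j] + 1L):cb[j + 1L]
      if (i == 1L) centers_c[j] <- mean(range(cols))
      tile_bins <- bins[rows, cols]
      npix <- length(tile_bins)
      h <- tabulate(as.vector(tile_bins) + 1L, nbins)
      clip_abs <- max(1, config$clahe_clip_limit * npix / nbins)
      excess <- sum(pmax(h - clip_abs, 0))
      h <- pmin(h, clip_abs) + excess / nbins
      luts[i, j, ] <- cumsum(h) / npix   # mapping into (0, 1]
    }
  }

  # bilinear interpolation between tile mappings
  pr <- matrix(seq_len(H), H, W)
  pc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ti <- findInterval(seq_len(H), centers_r)          # per-row lower tile
  tj <- findInterval(seq_len(W), centers_c)
  i0 <- pmax(ti, 1L); i1 <- pmin(ti + 1L, tr); i0 <- pmin(i0, tr)
  j0 <- pmax(tj, 1L); j1 <- pmin(tj + 1L, tc); j0 <- pmin(j0, tc)
  wr <- ifelse(i1 > i0, (seq_len(H) - centers_r[i0]) / (centers_r[i1] - centers_r[i0]), 0)
  wc <- ifelse(j1 > j0, (seq_len(W) - centers_c[j0]) / (centers_c[j1] - centers_c[j0]), 0)
  wr <- clamp(wr, 0, 1); wc <- clamp(wc, 0, 1)

  I0 <- matrix(i0[pr], H, W); I1 <- matrix(i1[pr], H, W)
  J0 <- matrix(j0[pc], H, W); J1 <- matrix(j1[pc], H, W)
  WR <- matrix(wr[pr], H, W); WC <- matrix(wc[pc], H, W)
  B <- bins + 1L
  val <- function(I, J) matrix(luts[cbind(as.vector(I), as.vector(J), as.vector(B))], H, W)
  out <- (1 - WR) * ((1 - WC) * val(I0, J0) + WC * val(I0, J1)) +
    WR * ((1 - WC) * val(I1, J0) + WC * val(I1, J1))
  clamp(out, 0, 1)
}

#' Unsharp-mask sharpening
#'
#' `out = clip(image + strength * (image - blur(image)), 0, 1)` with a
#' fixed 3x3 box blur (reflective padding). Constant images are
#' unchanged for any strength.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param strength Non-negative sharpening strength.
#' @return Numeric matrix in \[0, 1\].
#' @export
sharpen <- function(image, strength = 1.0) {
  img <- as_pixels(image)
  mv_assert(is_number(strength) && strength >= 0, "strength must be >= 0")
  if (strength == 0) return(img)
  clamp(img + strength * (img - sep_filter(img, rep(1 / 3, 3))), 0, 1)
}

#' Min-max intensity normalization
#'
#' Maps values affinely so the minimum becomes 0 and the maximum 1. A
#' constant image maps to all zeros (documented degenerate rule).
#'
#' @param image Numeric matrix with finite values.
#' @return Numeric matrix in \[0, 1\].
#' @export
minmax_normalize <- function(image) {
  img <- as_pixels(image)
  mv_assert(all(is.finite(img)), "image contains non-finite values")
  rng <- range(img)
  if (rng[1] == rng[2]) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Full preprocessing pipeline
#'
#' Applies, in order: grayscale conversion, CLAHE, sharpening, resizing
#' to `target_size`, and min-max normalization. The returned
#' [cell_image()] records each applied stage in its provenance.
#'
#' @param image Numeric matrix or H x W x C array (or `cell_image`).
#' @param config A [preprocess_config()].
#' @param group,source_id Metadata carried into the result.
#' @return A [cell_image()] of shape `target_size` x `target_size` with
#'   values in \[0, 1\].
#' @export
preprocess_pipeline <- function(image, config = preprocess_config(),
                                group = NA_character_, source_id = "") {
  mv_assert(inherits(config, "preprocess_config"), "config must be a preprocess_config")
  if (inherits(image, "cell_image")) {
    if (is.na(group)) group <- image$group
    if (identical(source_id, "")) source_id <- image$source_id
    image <- image$pixels
  }
  stages <- character()
  if (config$do_grayscale || !is.matrix(image)) {
    image <- to_grayscale(image)
    stages <- c(stages, "grayscale")
  }
  if (config$do_clahe) {
    image <- apply_clahe(image, config)
    stages <- c(stages, "clahe")
  }
  if (config$do_sharpen) {
    image <- sharpen(image, config$sharpen_strength)
    stages <- c(stages, "sharpen")
  }
  image <- resize_image(image, config$target_size)
  stages <- c(stages, "resize")
  image <- minmax_normalize(image)
  stages <- c(stages, "normalize")
  cell_image(image, group = group, source_id = source_id, provenance = stages)
}

#' Preprocess every image of a dataset
#'
#' @param dataset A `synthetic_dataset` (or any list with `images`).
#' @param config A [preprocess_config()].
#' @return The dataset with every image replaced by its preprocessed
#'   version (parameters and labels untouched).
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  out <- dataset
  out$images <- lapply(dataset$images, preprocess_pipeline, config = config)
  out$size <- config$target_size
  out
}
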