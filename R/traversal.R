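#' Latent traversal of one dimension
#'
#' Sweeps a single latent coordinate linearly over \[-3, 3\] around a
#' baseline latent vector and decodes each point, visualizing what that
#' dimension encodes. The default baseline is the zero vector; group-mean
#' latents can be supplied to produce per-group panels.
#'
#' @param model A `vae_model` or `trained_vae`.
#' @param dim 0-based latent dimension index (matching the `z_i` naming).
#' @param n_steps Number of traversal values (>= 2); default 7 gives
#'   -3, -2, ..., +3.
#' @param baseline Length-L latent vector; default all zeros.
#' @param from,to Traversal endpoints; default -3 and 3.
#' @return An object of class `traversal_result`: list with `dimension`,
#'   `values`, `images` (list of decoded matrices), `baseline`.
#' @export
traverse <- function(model, dim, n_steps = 7L, baseline = NULL,
                     from = -3, to = 3) {
  if (inherits(model, "trained_vae")) model <- model$model
  mv_assert(inherits(model, "vae_model"), "model must be a vae_model")
  L <- model$config$latent_dim
  mv_assert(is_number(dim) && dim >= 0 && dim < L,
            sprintf("dim must be in [0, %d)", L))
  mv_assert(is_number(n_steps) && n_steps >= 2, "n_steps must be >= 2")
  if (is.null(baseline)) baseline <- numeric(L)
  mv_assert(length(baseline) == L, "baseline must have length L")
  values <- seq(from, to, length.out = as.integer(n_steps))
  Z <- matrix(rep(baseline, each = length(values)), length(values), L)
  Z[, dim + 1L] <- values
  dec <- decode(model, Z)
  images <- lapply(seq_len(nrow(Z)), function(i) dec[i, , ])
  structure(list(dimension = as.integer(dim), values = values,
                 images = images, baseline = baseline),
            class = "traversal_result")
}

#' Absolute pixel-wise difference map
#'
#' @param img_a,img_b Same-shaped numeric matrices.
#' @return Elementwise `|a - b|`.
#' @export
abs_difference_map <- function(img_a, img_b) {
  a <- as_pixels(img_a); b <- as_pixels(img_b)
  mv_assert(all(dim(a) == dim(b)), "images must have the same shape")
  abs(a - b)
}

#' Per-pixel structural similarity (SSIM) map
#'
#' Local SSIM with an 11 x 11 Gaussian window (sigma 1.5), stability
#' constants `K1 = 0.01`, `K2 = 0.03` and data range 1 — the canonical
#' reference parameters. Filtering uses reflective padding so the map
#' covers every pixel.
#'
#' @param img_a,img_b Same-shaped matrices with values in \[0, 1\].
#' @param window Window size (odd).
#' @param sigma Gaussian window sigma.
#' @param K1,K2 Stability constants.
#' @return Matrix of per-pixel SSIM values in \[-1, 1\] (1 = identical
#'   local structure).
#' @export
ssim_map <- function(img_a, img_b, window = 11L, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  a <- as_pixels(img_a); b <- as_pixels(img_b)
  mv_assert(all(dim(a) == dim(b)), "images must have the same shape")
  mv_assert(window %% 2L == 1L, "window must be odd")
  half <- (window - 1L) %/% 2L
  k <- gaussian_kernel(sigma, radius = half)
  C1 <- K1^2; C2 <- K2^2   # data range 1
  mu_a <- sep_filter(a, k); mu_b <- sep_filter(b, k)
  va <- sep_filter(a * a, k) - mu_a^2
  vb <- sep_filter(b * b, k) - mu_b^2
  cab <- sep_filter(a * b, k) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' SSIM dissimilarity map
#'
#' `(1 - SSIM) / 2`, rescaling the per-pixel SSIM into a \[0, 1\]
#' dissimilarity comparable across dimensions.
#'
#' @inheritParams ssim_map
#' @return Matrix in \[0, 1\]; 0 = locally identical.
#' @export
ssim_dissimilarity <- function(img_a, img_b, window = 11L, sigma = 1.5,
                               K1 = 0.01, K2 = 0.03) {
  (1 - ssim_map(img_a, img_b, window, sigma, K1, K2)) / 2
}

#' Threshold a dissimilarity map at a quantile
#'
#' The mask marks pixels at or above the given quantile of the map's
#' value distribution, highlighting the regions of highest variation.
#' When all values tie (a constant map) every pixel is masked.
#'
#' @param dissimilarity Numeric matrix.
#' @param quantile Quantile in (0, 1); default 0.95.
#' @return Logical matrix of the same shape.
#' @export
threshold_map <- function(dissimilarity, quantile = 0.95) {
  m <- as_pixels(dissimilarity)
  mv_assert(is_number(quantile) && quantile > 0 && quantile < 1,
            "quantile must be in (0, 1)")
  thr <- stats::quantile(m, quantile, names = FALSE, type = 7)
  m >= thr
}

#' Difference maps for the top- and bottom-ranked dimensions
#'
#' For each selected dimension the decoder is evaluated at the traversal
#' extremes (-3 and +3, other coordinates at the baseline) and the
#' absolute and SSIM dissimilarity maps plus the thresholded mask are
#' computed. On a successful run the top-ranked dimensions produce larger
#' mean dissimilarity than the bottom-ranked ones.
#'
#' @param model A `vae_model` or `trained_vae`.
#' @param table An [effect_size_table()] for this model's latents.
#' @param top_k,bottom_k How many dimensions from each end of the
#'   ranking; `top_k + bottom_k <= L`.
#' @param baseline Baseline latent vector (default zeros).
#' @param quantile Mask quantile, see [threshold_map()].
#' @return An object of class `difference_report`: list with `maps` (one
#'   `difference_map` per dimension: `dimension`, `rank`, `end`,
#'   `absolute`, `ssim_dissimilarity`, `mask`) and `summary` (data frame
#'   with `dimension`, `rank`, `end`, `mean_abs_diff`, `mean_dissim`,
#'   `mask_fraction`).
#' @export
difference_report <- function(model, table, top_k = 3L, bottom_k = 1L,
                              baseline = NULL, quantile = 0.95) {
  if (inherits(model, "trained_vae")) model <- model$model
  mv_assert(inherits(table, "effect_size_table"), "table must be an effect_size_table")
  L <- nrow(table)
  mv_assert(top_k >= 0 && bottom_k >= 0 && top_k + bottom_k <= L,
            "top_k + bottom_k must not exceed the latent dimension")
  dims_by_rank <- ranked_dimensions(table)
  sel <- unique(c(head(dims_by_rank, top_k),
                  if (bottom_k > 0) tail(dims_by_rank, bottom_k)))
  ends <- ifelse(sel %in% head(dims_by_rank, top_k), "top", "bottom")
  maps <- vector("list", length(sel))
  rows <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    d <- sel[i]
    tr <- traverse(model, d, n_steps = 2L, baseline = baseline)
    lo <- tr$images[[1]]; hi <- tr$images[[2]]
    am <- abs_difference_map(lo, hi)
    dm <- ssim_dissimilarity(lo, hi)
    mask <- threshold_map(dm, quantile)
    rnk <- table$rank[table$dimension == d]
    maps[[i]] <- structure(list(dimension = d, rank = rnk, end = ends[i],
                                absolute = am, ssim_dissimilarity = dm,
                                mask = mask),
                           class = "difference_map")
    rows[[i]] <- data.frame(dimension = d, rank = rnk, end = ends[i],
                            mean_abs_diff = mean(am), mean_dissim = mean(dm),
                            mask_fraction = mean(mask))
  }
  structure(list(maps = maps, summary = do.call(rbind, rows)),
            class = "difference_report")
}
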