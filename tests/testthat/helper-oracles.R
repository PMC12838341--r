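# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation.

# Two-pass Cohen's d with explicit loops (equal-weight pooled SD).
oracle_cohens_d <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- 0; for (x in a) va <- va + (x - ma)^2
  vb <- 0; for (x in b) vb <- vb + (x - mb)^2
  va <- va / (length(a) - 1); vb <- vb / (length(b) - 1)
  (mb - ma) / sqrt((va + vb) / 2)
}

# Scalar SSIM: mean over pixels of the local SSIM computed by explicit
# window loops with symmetric (reflect) padding and a Gaussian window
# built from dnorm. Slow but direct; for small images only.
oracle_ssim_mean <- function(a, b, window = 11L, sigma = 1.5,
                             K1 = 0.01, K2 = 0.03) {
  half <- (window - 1L) %/% 2L
  w1 <- dnorm(seq(-half, half), sd = sigma)
  w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  refl <- function(i, n) {
    p <- 2 * n - 2
    j <- (i - 1) %% p
    j <- ifelse(j < 0, j + p, j)
    ifelse(j >= n, p - j, j) + 1
  }
  n <- nrow(a); m <- ncol(a)
  C1 <- K1^2; C2 <- K2^2
  total <- 0
  for (r in seq_len(n)) {
    for (cc in seq_len(m)) {
      ri <- refl(r + seq(-half, half), n)
      ci <- refl(cc + seq(-half, half), m)
      pa <- a[ri, ci]; pb <- b[ri, ci]
      mua <- sum(W * pa); mub <- sum(W * pb)
      va <- sum(W * pa^2) - mua^2
      vb <- sum(W * pb^2) - mub^2
      cab <- sum(W * pa * pb) - mua * mub
      total <- total + ((2 * mua * mub + C1) * (2 * cab + C2)) /
        ((mua^2 + mub^2 + C1) * (va + vb + C2))
    }
  }
  total / (n * m)
}

# Direct (non-separable) 3x3 box blur at one pixel with reflect padding.
oracle_box3_at <- function(img, r, c) {
  refl <- function(i, n) {
    p <- 2 * n - 2
    j <- (i - 1) %% p
    j <- ifelse(j < 0, j + p, j)
    ifelse(j >= n, p - j, j) + 1
  }
  s <- 0
  for (dr in -1:1) for (dc in -1:1)
    s <- s + img[refl(r + dr, nrow(img)), refl(c + dc, ncol(img))]
  s / 9
}

# A small smooth test image (Gaussian blob) of given size.
smooth_blob <- function(size, sigma = size / 5) {
  ctr <- (size + 1) / 2
  xs <- seq_len(size) - ctr
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  0.1 + 0.8 * g / max(g)
}

# Tiny 16 px model config used across model/training tests.
tiny_config <- function(kind = "beta_vae", L = 3L, ...) {
  model_config(kind, latent_dim = L, image_size = 16L,
               encoder_widths = 32L, beta = 2, ...)
}

# Tiny in-memory dataset of rendered cells (no disk IO).
tiny_dataset <- function(n_per_group = 8L, size = 16L, seed = 5L) {
  g <- default_group_configs()
  ctrl <- group_config("control", means = c(radius = 5, ring_width = 1),
                       sds = c(radius = 0.5, ring_width = 0.3))
  trt <- group_config("treated", means = c(radius = 5, ring_width = 2),
                      sds = c(radius = 0.5, ring_width = 0.3))
  generate_dataset(ctrl, trt, n_per_group = n_per_group, size = size,
                   seed = seed)
}
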