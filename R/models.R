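#' Model configuration for the VAE family
#'
#' Describes one of the three generative models: `beta_vae` (KL term
#' weighted by `beta`), `beta_tcvae` (KL decomposed into mutual
#' information, total correlation and dimension-wise KL, weighted by
#' `alpha`, `beta`, `gamma`), and `me_vae` (three parallel encoders over
#' original / rotated / polar-flipped views whose posteriors are averaged
#' before decoding, trained with the `beta_vae` loss).
#'
#' @param kind One of `"beta_vae"`, `"beta_tcvae"`, `"me_vae"`.
#' @param latent_dim Latent dimensionality L (>= 1). Default 32, the
#'   configuration reported for all three models.
#' @param beta KL (or total-correlation) weight; default 6.
#' @param alpha Mutual-information weight (TCVAE only); default 1.
#' @param gamma Dimension-wise KL weight (TCVAE only); default 1.
#' @param image_size Input image side length in pixels.
#' @param encoder_widths Hidden-layer widths of the encoder MLP.
#' @param decoder_widths Hidden-layer widths of the decoder MLP (default
#'   the reverse of `encoder_widths`).
#' @param init Weight initialization: `"pca"` (default) warm-starts the
#'   outer layers and latent heads from the principal components of the
#'   training images (see [train_model()]), so the short training budget
#'   is spent refining an already-sensible linear autoencoder; `"random"`
#'   uses pure He initialization.
#' @param logvar_clamp Posterior log-variances are clamped to
#'   `[-logvar_clamp, logvar_clamp]` for numerical stability.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(kind = c("beta_vae", "beta_tcvae", "me_vae"),
                         latent_dim = 32L, beta = 6, alpha = 1, gamma = 1,
                         image_size = 64L, encoder_widths = 256L,
                         decoder_widths = rev(encoder_widths),
                         init = c("pca", "random"),
                         logvar_clamp = 8) {
  kind <- match.arg(kind)
  init <- match.arg(init)
  mv_assert(is_number(latent_dim) && latent_dim >= 1, "latent_dim must be >= 1")
  mv_assert(is_number(beta) && beta >= 0, "beta must be >= 0")
  mv_assert(is_number(alpha) && is_number(gamma), "alpha and gamma must be numbers")
  mv_assert(is_number(image_size) && image_size >= 16, "image_size must be >= 16")
  mv_assert(length(encoder_widths) >= 1 && all(encoder_widths >= 1),
            "encoder_widths must be a nonempty positive vector")
  mv_assert(length(decoder_widths) >= 1 && all(decoder_widths >= 1),
            "decoder_widths must be a nonempty positive vector")
  structure(list(kind = kind, latent_dim = as.integer(latent_dim),
                 beta = beta, alpha = alpha, gamma = gamma,
                 image_size = as.integer(image_size),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 n_encoders = if (kind == "me_vae") 3L else 1L,
                 init = init, logvar_clamp = logvar_clamp),
            class = "model_config")
}

#' Gaussian posterior parameters
#'
#' Container for per-sample posterior means and log-variances, either as
#' length-L vectors (single sample) or n x L matrices.
#'
#' @param mu,logvar Numeric vectors or matrices of identical shape.
#' @return An object of class `posterior_params` with matrix `mu` and
#'   `logvar` fields (vectors are promoted to one-row matrices).
#' @export
posterior_params <- function(mu, logvar) {
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  if (!is.matrix(logvar)) logvar <- matrix(logvar, nrow = 1)
  mv_assert(all(dim(mu) == dim(logvar)), "mu and logvar must have the same shape")
  mv_assert(all(is.finite(mu)) && all(is.finite(logvar)),
            "posterior parameters must be finite")
  structure(list(mu = mu, logvar = logvar), class = "posterior_params")
}

#' Initialize a VAE model
#'
#' He-initialized dense encoder/decoder stacks. The encoder maps the
#' flattened image through `encoder_widths` ReLU layers to affine `mu` and
#' `logvar` heads; the decoder mirrors it back to a sigmoid-bounded image.
#' ME-VAE models hold three weight-independent encoders.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `vae_model`.
#' @export
init_model <- function(config, seed = 1L) {
  mv_assert(inherits(config, "model_config"), "config must be a model_config")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  D <- config$image_size^2
  L <- config$latent_dim
  make_encoder <- function() {
    dims <- c(D, config$encoder_widths)
    hidden <- lapply(seq_len(length(dims) - 1L),
                     function(i) nn_linear_init(dims[i], dims[i + 1L]))
    last <- dims[length(dims)]
    list(hidden = hidden,
         mu = nn_linear_init(last, L, gain = 1),
         logvar = nn_linear_init(last, L, gain = 1))
  }
  dims <- c(L, config$decoder_widths)
  dec_hidden <- lapply(seq_len(length(dims) - 1L),
                       function(i) nn_linear_init(dims[i], dims[i + 1L]))
  decoder <- list(hidden = dec_hidden,
                  out = nn_linear_init(dims[length(dims)], D, gain = 1))
  encoders <- lapply(seq_len(config$n_encoders), function(i) make_encoder())
  structure(list(config = config, encoders = encoders, decoder = decoder),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model kind=%s L=%d image=%dpx encoders=%d>\n",
              x$config$kind, x$config$latent_dim, x$config$image_size,
              x$config$n_encoders))
  invisible(x)
}

# Internal: encoder forward with cache. X is (batch x D).
encoder_forward <- function(enc, X, clamp_lim) {
  acts <- mlp_forward(enc$hidden, X)
  h <- acts[[length(acts)]]
  mu <- sweep(h %*% enc$mu$W, 2, enc$mu$b, "+")
  pre_lv <- sweep(h %*% enc$logvar$W, 2, enc$logvar$b, "+")
  logvar <- clamp(pre_lv, -clamp_lim, clamp_lim)
  list(acts = acts, mu = mu, logvar = logvar, pre_lv = pre_lv)
}

# Internal: encoder backward. Returns grads shaped like enc.
encoder_backward <- function(enc, cache, dmu, dlv, clamp_lim) {
  dlv <- dlv * (abs(cache$pre_lv) < clamp_lim)   # clamp gate
  h <- cache$acts[[length(cache$acts)]]
  g_mu <- list(W = crossprod(h, dmu), b = colSums(dmu))
  g_lv <- list(W = crossprod(h, dlv), b = colSums(dlv))
  dh <- tcrossprod(dmu, enc$mu$W) + tcrossprod(dlv, enc$logvar$W)
  bp <- mlp_backward(enc$hidden, cache$acts, dh)
  list(grads = list(hidden = bp$grads, mu = g_mu, logvar = g_lv), dX = bp$dX)
}

# Internal: decoder forward with cache. Z is (batch x L).
decoder_forward <- function(dec, Z) {
  acts <- mlp_forward(dec$hidden, Z)
  h <- acts[[length(acts)]]
  pre <- sweep(h %*% dec$out$W, 2, dec$out$b, "+")
  list(acts = acts, out = sigmoid(pre))
}

# Internal: decoder backward given gradient at the sigmoid output.
decoder_backward <- function(dec, cache, dout) {
  dpre <- dout * cache$out * (1 - cache$out)
  h <- cache$acts[[length(cache$acts)]]
  g_out <- list(W = crossprod(h, dpre), b = colSums(dpre))
  dh <- tcrossprod(dpre, dec$out$W)
  bp <- mlp_backward(dec$hidden, cache$acts, dh)
  list(grads = list(hidden = bp$grads, out = g_out), dZ = bp$dX)
}

#' Encode images to posterior parameters
#'
#' Deterministic given the model weights. For an ME-VAE the three
#' encoders are applied to the deterministic view triplet (original,
#' 0-degree rotation, polar flip) and their posteriors averaged.
#'
#' @param model A [init_model()] / trained `vae_model`.
#' @param images A `cell_image`, numeric matrix, list of either, or a
#'   flattened (batch x D) matrix (`flat = TRUE`).
#' @param flat Set `TRUE` when `images` is already a (batch x D) matrix.
#' @return A [posterior_params()] with one row per image.
#' @export
encode <- function(model, images, flat = FALSE) {
  mv_assert(inherits(model, "vae_model"), "model must be a vae_model")
  X <- images_to_batch(images, model$config$image_size, flat = flat)
  clamp_lim <- model$config$logvar_clamp
  if (model$config$kind == "me_vae") {
    size <- model$config$image_size
    views <- me_vae_views_flat(X, size)
    caches <- lapply(1:3, function(i)
      encoder_forward(model$encoders[[i]], views[[i]], clamp_lim))
    mu <- (caches[[1]]$mu + caches[[2]]$mu + caches[[3]]$mu) / 3
    lv <- (caches[[1]]$logvar + caches[[2]]$logvar + caches[[3]]$logvar) / 3
    return(posterior_params(mu, lv))
  }
  cache <- encoder_forward(model$encoders[[1]], X, clamp_lim)
  posterior_params(cache$mu, cache$logvar)
}

# Internal: deterministic ME-VAE views of a flat batch — original,
# rotation by 0 degrees (= original), polar flip.
me_vae_views_flat <- function(X, size) {
  flip <- t(apply(X, 1, function(row) as.vector(polar_flip(matrix(row, size, size)))))
  if (nrow(X) == 1L) flip <- matrix(flip, nrow = 1L)
  list(X, X, flip)
}

#' Decode latent vectors to images
#'
#' @param model A `vae_model`.
#' @param z Length-L vector or (batch x L) matrix.
#' @return A single image matrix (vector input) or an array
#'   `(batch, H, W)` (matrix input); pixel values lie in (0, 1).
#' @export
decode <- function(model, z) {
  mv_assert(inherits(model, "vae_model"), "model must be a vae_model")
  single <- !is.matrix(z)
  if (single) z <- matrix(z, nrow = 1)
  mv_assert(ncol(z) == model$config$latent_dim,
            sprintf("z must have length/width %d", model$config$latent_dim))
  out <- decoder_forward(model$decoder, z)$out
  s <- model$config$image_size
  if (single) return(matrix(out[1, ], s, s))
  arr <- array(0, dim = c(nrow(out), s, s))
  for (i in seq_len(nrow(out))) arr[i, , ] <- matrix(out[i, ], s, s)
  arr
}

#' Reparameterization sampling
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps` standard normal from R's
#' global random stream.
#'
#' @param p A [posterior_params()].
#' @return Matrix of samples, same shape as `p$mu`.
#' @export
reparameterize <- function(p) {
  mv_assert(inherits(p, "posterior_params"), "p must be posterior_params")
  eps <- matrix(rnorm(length(p$mu)), nrow(p$mu), ncol(p$mu))
  p$mu + exp(p$logvar / 2) * eps
}

#' KL divergence from the posterior to the standard normal prior
#'
#' Closed form per sample:
#' `sum_j 0.5 * (exp(logvar_j) + mu_j^2 - 1 - logvar_j)`.
#'
#' @param p A [posterior_params()].
#' @return Numeric vector, one non-negative KL value per row of `p`.
#' @export
kl_standard_normal <- function(p) {
  mv_assert(inherits(p, "posterior_params"), "p must be posterior_params")
  rowSums(0.5 * (exp(p$logvar) + p$mu^2 - 1 - p$logvar))
}

# Internal constructor for the per-batch loss record.
loss_breakdown <- function(kind, total, reconstruction, kl,
                           mi = NA_real_, tc = NA_real_, dimwise_kl = NA_real_) {
  structure(list(kind = kind, total = total, reconstruction = reconstruction,
                 kl = kl, mi = mi, tc = tc, dimwise_kl = dimwise_kl),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss %s total=%.4f rec=%.4f kl=%.4f", x$kind, x$total,
              x$reconstruction, x$kl))
  if (is.finite(x$mi)) cat(sprintf(" mi=%.4f tc=%.4f dimwise=%.4f", x$mi, x$tc,
                                   x$dimwise_kl))
  cat(">\n")
  invisible(x)
}

#' Beta-VAE loss
#'
#' `total = MSE + beta * KL`, where MSE is summed over pixels and
#' averaged over the batch, and KL (closed form against the standard
#' normal prior) is summed over dimensions and averaged over the batch.
#'
#' @param x,reconstruction (batch x D) matrices (or single images).
#' @param p A [posterior_params()] for the batch.
#' @param beta KL weight.
#' @return A `loss_breakdown`.
#' @export
beta_vae_loss <- function(x, reconstruction, p, beta = 6) {
  if (!is.matrix(x)) x <- matrix(as_pixels(x), nrow = 1)
  if (!is.matrix(reconstruction)) reconstruction <- matrix(as_pixels(reconstruction), nrow = 1)
  if (is.matrix(x) && !identical(dim(x), dim(reconstruction)))
    mv_stop("x and reconstruction shapes differ")
  rec <- mean(rowSums((x - reconstruction)^2))
  kl <- mean(kl_standard_normal(p))
  loss_breakdown("beta_vae", total = rec + beta * kl, reconstruction = rec,
                 kl = kl)
}

#' Beta-TCVAE loss with the MI / TC / dimension-wise KL decomposition
#'
#' The KL term is decomposed into mutual information
#' `E[log q(z|x) - log q(z)]`, total correlation
#' `E[log q(z) - sum_j log q(z_j)]`, and dimension-wise KL
#' `E[sum_j (log q(z_j) - log p(z_j))]`, estimated on the minibatch by
#' weighted sampling: the aggregate posterior at `z_i` is approximated by
#' the mixture over batch members with exact importance weights `1/N` for
#' the member that generated `z_i` and `(N-1)/(N(M-1))` for the others
#' (`N` = dataset size, `M` = batch size). With these weights each term
#' vanishes in expectation when every posterior equals the prior, and the
#' three terms always sum to `log q(z|x) - log p(z)` exactly.
#' `total = MSE + alpha * MI + beta * TC + gamma * dimwise`.
#'
#' @param p A [posterior_params()] for the batch (M >= 2 rows).
#' @param z (M x L) matrix of reparameterized samples, one per row of `p`.
#' @param alpha,beta,gamma Term weights (defaults 1, 6, 1).
#' @param dataset_size Total number of training images N (>= M).
#' @param x,reconstruction Optional (M x D) matrices; when supplied the
#'   reconstruction MSE enters the total, otherwise it is 0.
#' @return A `loss_breakdown` with `mi`, `tc` and `dimwise_kl` filled in
#'   and `kl` equal to their sum.
#' @export
tcvae_loss <- function(p, z, alpha = 1, beta = 6, gamma = 1, dataset_size,
                       x = NULL, reconstruction = NULL) {
  mv_assert(inherits(p, "posterior_params"), "p must be posterior_params")
  M <- nrow(p$mu); L <- ncol(p$mu)
  mv_assert(M >= 2, "tcvae_loss requires a batch of at least 2",
            "morphovae_degenerate_error")
  if (!is.matrix(z)) z <- matrix(z, nrow = M)
  mv_assert(all(dim(z) == dim(p$mu)), "z must match the posterior shape")
  mv_assert(is_number(dataset_size) && dataset_size >= M,
            "dataset_size must be >= batch size")
  est <- tc_decomposition(p$mu, p$logvar, z, dataset_size)
  rec <- if (!is.null(x) && !is.null(reconstruction))
    mean(rowSums((x - reconstruction)^2)) else 0
  loss_breakdown("beta_tcvae",
                 total = rec + alpha * est$mi + beta * est$tc + gamma * est$dimwise,
                 reconstruction = rec,
                 kl = est$mi + est$tc + est$dimwise,
                 mi = est$mi, tc = est$tc, dimwise_kl = est$dimwise)
}

# Internal: per-pair per-dimension Gaussian log densities
# a[i, j, d] = log N(z[i, d]; mu[j, d], exp(logvar[j, d])).
pairwise_logq <- function(mu, logvar, z) {
  M <- nrow(mu); L <- ncol(mu)
  a <- array(0, dim = c(M, M, L))
  for (d in seq_len(L)) {
    diff <- outer(z[, d], mu[, d], "-")
    v <- exp(logvar[, d])
    a[, , d] <- -0.5 * log(2 * pi) -
      0.5 * matrix(logvar[, d], M, M, byrow = TRUE) -
      sweep(diff^2, 2, 2 * v, "/")
  }
  a
}

# Internal: log importance weights for the minibatch mixture estimate of
# the aggregate posterior.
mws_logweights <- function(M, N) {
  W <- matrix(log((N - 1) / (N * (M - 1))), M, M)
  diag(W) <- log(1 / N)
  W
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Internal: the three decomposition terms (means over the batch).
tc_decomposition <- function(mu, logvar, z, N) {
  M <- nrow(mu); L <- ncol(mu)
  a <- pairwise_logq(mu, logvar, z)
  lw <- mws_logweights(M, N)
  a_joint <- apply(a, c(1, 2), sum)                 # log q(z_i | x_j)
  lqz <- logsumexp_rows(a_joint + lw)               # log qhat(z_i)
  lqzd <- sapply(seq_len(L), function(d) logsumexp_rows(a[, , d] + lw))
  if (M == 1L) lqzd <- matrix(lqzd, nrow = 1)
  lqzx <- diag(a_joint)                             # log q(z_i | x_i)
  lpz <- rowSums(-0.5 * (log(2 * pi) + z^2))
  lpzd_sum <- lpz
  list(mi = mean(lqzx - lqz),
       tc = mean(lqz - rowSums(lqzd)),
       dimwise = mean(rowSums(lqzd) - lpzd_sum))
}

#' Average three latent vectors into one
#'
#' Elementwise mean `(z1 + z2 + z3) / 3`, the ME-VAE aggregation rule.
#'
#' @param z1,z2,z3 Numeric vectors or matrices of identical shape.
#' @return Object of the same shape.
#' @export
aggregate_latents <- function(z1, z2, z3) {
  mv_assert(length(z1) == length(z2) && length(z2) == length(z3),
            "latent vectors must have equal length")
  (z1 + z2 + z3) / 3
}

#' ME-VAE forward pass
#'
#' Each of the three views is encoded by its own encoder; the posterior
#' parameters are averaged elementwise (the latent aggregation rule
#' applied to `mu` and `logvar`), a single `z` is sampled from the
#' aggregate, and the decoder reconstructs the original view. The loss is
#' the beta-VAE loss against the original view.
#'
#' @param model A `vae_model` of kind `"me_vae"`.
#' @param original,rotated,polar_view Same-shaped images or (batch x D)
#'   matrices (`flat = TRUE`).
#' @param flat Inputs are already flattened batches.
#' @param sample If `FALSE`, use `z = mu` (deterministic; no RNG use).
#' @return List with `reconstruction` (batch x D matrix), `posterior`
#'   (aggregated [posterior_params()]), `z`, and `loss` (a
#'   `loss_breakdown`).
#' @export
me_vae_forward <- function(model, original, rotated, polar_view, flat = FALSE,
                           sample = TRUE) {
  mv_assert(inherits(model, "vae_model") && model$config$kind == "me_vae",
            "model must be an me_vae vae_model")
  size <- model$config$image_size
  X1 <- images_to_batch(original, size, flat = flat)
  X2 <- images_to_batch(rotated, size, flat = flat)
  X3 <- images_to_batch(polar_view, size, flat = flat)
  mv_assert(all(dim(X1) == dim(X2)) && all(dim(X1) == dim(X3)),
            "the three views must have identical shapes")
  clamp_lim <- model$config$logvar_clamp
  c1 <- encoder_forward(model$encoders[[1]], X1, clamp_lim)
  c2 <- encoder_forward(model$encoders[[2]], X2, clamp_lim)
  c3 <- encoder_forward(model$encoders[[3]], X3, clamp_lim)
  mu <- aggregate_latents(c1$mu, c2$mu, c3$mu)
  lv <- aggregate_latents(c1$logvar, c2$logvar, c3$logvar)
  post <- posterior_params(mu, lv)
  z <- if (sample) reparameterize(post) else mu
  recon <- decoder_forward(model$decoder, z)$out
  loss <- beta_vae_loss(X1, recon, post, beta = model$config$beta)
  list(reconstruction = recon, posterior = post, z = z, loss = loss)
}

# Internal: coerce images (cell_image / matrix / list thereof / flat
# batch matrix) to a (batch x D) matrix, validating the size.
images_to_batch <- function(images, size, flat = FALSE) {
  D <- size * size
  if (flat) {
    mv_assert(is.matrix(images) && ncol(images) == D,
              sprintf("flat batch must have %d columns", D))
    return(images)
  }
  if (inherits(images, "cell_image") || (is.matrix(images) && nrow(images) == ncol(images))) {
    px <- as_pixels(images)
    mv_assert(nrow(px) == size && ncol(px) == size,
              sprintf("image must be %d x %d", size, size))
    return(matrix(as.vector(px), nrow = 1))
  }
  if (is.list(images)) {
    rows <- lapply(images, function(im) {
      px <- as_pixels(im)
      mv_assert(nrow(px) == size && ncol(px) == size,
                sprintf("image must be %d x %d", size, size))
      as.vector(px)
    })
    return(do.call(rbind, rows))
  }
  mv_stop("unsupported image input")
}
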