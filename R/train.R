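#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 1e-4, weight
#' decay 1e-5, batch size 16, 150 epochs. The desk-scale preset used in
#' the test suite shortens this to 20 epochs on 64 x 64 images.
#'
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay L2 weight decay folded into the gradients (>= 0).
#' @param batch_size Minibatch size (>= 2; the TCVAE estimator is
#'   undefined on singleton batches).
#' @param epochs Number of passes over the data (>= 0).
#' @param seed Integer seed controlling shuffling, initialization and
#'   sampling.
#' @param optimizer Only `"adam"` is supported.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         batch_size = 16L, epochs = 150L, seed = 1L,
                         optimizer = "adam") {
  mv_assert(is_number(learning_rate) && learning_rate > 0, "learning_rate must be > 0")
  mv_assert(is_number(weight_decay) && weight_decay >= 0, "weight_decay must be >= 0")
  mv_assert(is_number(batch_size) && batch_size >= 2, "batch_size must be >= 2")
  mv_assert(is_number(epochs) && epochs >= 0, "epochs must be >= 0")
  mv_assert(identical(optimizer, "adam"), "only the adam optimizer is supported")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer),
            class = "train_config")
}

#' Generate the ME-VAE view triplet for one image
#'
#' Returns the original image, a rotation by an angle drawn uniformly
#' from \[-180, 180\] degrees (bilinear interpolation, reflective
#' padding), and the polar flip (horizontal plus vertical reflection,
#' i.e. an exact 180-degree rotation). Uses R's global random stream.
#'
#' @param image `cell_image` or numeric square matrix.
#' @return List with elements `original`, `rotated`, `polar`.
#' @export
make_views <- function(image) {
  px <- as_pixels(image)
  mv_assert(nrow(px) == ncol(px), "make_views requires a square image")
  angle <- runif(1, -180, 180)
  list(original = px, rotated = rotate_image(px, angle), polar = polar_flip(px))
}

# Internal: PCA warm start. Builds a linear principal-component
# autoencoder inside the network so training starts from a sensible
# model instead of noise: the first encoder layer holds +/- pairs of
# whitened principal directions (so ReLU preserves the signed scores),
# the mu head reads the standardized top-L scores, the first decoder
# layer re-expands z into the +/- pairs, and the output layer maps them
# back through the component loadings with the output bias at the logit
# of the mean image. Layers without room (width < 2 components) are left
# at their random initialization.
pca_warmstart <- function(model, X) {
  cfg <- model$config
  H <- cfg$encoder_widths[1]
  Hd <- cfg$decoder_widths[length(cfg$decoder_widths)]
  L <- cfg$latent_dim
  n <- nrow(X); D <- ncol(X)
  k <- min(H %/% 2L, Hd %/% 2L, n - 1L, D)
  if (k < 1L) return(model)
  xm <- colMeans(X)
  sv <- svd(sweep(X, 2, xm), nu = 0, nv = k)
  sdev <- sv$d[seq_len(k)] / sqrt(n - 1)
  keep <- which(sdev >= max(0.05 * sdev[1], 1e-8))
  k <- length(keep)
  if (k < 1L) return(model)
  V <- sv$v[, keep, drop = FALSE]
  s <- sdev[keep]
  Vw <- sweep(V, 2, s, "/")            # whitened directions

  for (e in seq_along(model$encoders)) {
    enc <- model$encoders[[e]]
    W1 <- enc$hidden[[1]]$W
    W1[, seq_len(k)] <- Vw
    W1[, k + seq_len(k)] <- -Vw
    enc$hidden[[1]]$W <- W1
    enc$hidden[[1]]$b <- -as.vector(xm %*% W1)
    if (length(enc$hidden) == 1L) {     # heads read the hidden layer directly
      m <- min(L, k)
      Wmu <- matrix(0, H, L)
      Wmu[cbind(seq_len(m), seq_len(m))] <- 1
      Wmu[cbind(k + seq_len(m), seq_len(m))] <- -1
      enc$mu$W <- Wmu; enc$mu$b <- numeric(L)
      enc$logvar$W <- enc$logvar$W * 0.1
      enc$logvar$b <- rep(-2, L)        # moderately confident start
    }
    model$encoders[[e]] <- enc
  }

  mbar <- clamp(xm, 0.02, 0.98)
  dec <- model$decoder
  if (length(dec$hidden) == 1L) {
    m <- min(L, k)
    Wh <- matrix(0, L, Hd)
    Wh[cbind(seq_len(m), seq_len(m))] <- 1
    Wh[cbind(seq_len(m), k + seq_len(m))] <- -1
    dec$hidden[[1]]$W <- Wh; dec$hidden[[1]]$b <- numeric(Hd)
  }
  gain <- sweep(V, 2, s, "*") / (mbar * (1 - mbar))   # D x k loadings
  Wout <- dec$out$W
  Wout[seq_len(k), ] <- t(gain)
  Wout[k + seq_len(k), ] <- -t(gain)
  dec$out$W <- Wout
  dec$out$b <- log(mbar / (1 - mbar))
  model$decoder <- dec
  model
}

# Internal: collect trainable params of a model into one nested list.
model_params <- function(model) list(encoders = model$encoders, decoder = model$decoder)
set_model_params <- function(model, params) {
  model$encoders <- params$encoders
  model$decoder <- params$decoder
  model
}

# Internal: gradients of the TCVAE penalty (alpha*MI + beta*TC +
# gamma*dimwise, batch mean) with respect to z, and to mu/logvar in their
# role as mixture components. The z-path gradient must additionally be
# chained through the reparameterization by the caller.
tc_penalty_grads <- function(mu, logvar, z, N, alpha, beta, gamma) {
  M <- nrow(mu); L <- ncol(mu)
  a <- pairwise_logq(mu, logvar, z)
  lw <- mws_logweights(M, N)
  a_joint <- apply(a, c(1, 2), sum)
  lqz <- logsumexp_rows(a_joint + lw)
  wj <- exp(a_joint + lw - lqz)                      # M x M softmax weights
  dz <- matrix(0, M, L); dmu <- matrix(0, M, L); dlv <- matrix(0, M, L)
  for (d in seq_len(L)) {
    ad <- a[, , d]
    lqzd <- logsumexp_rows(ad + lw)
    wd <- exp(ad + lw - lqzd)
    cmat <- diag(alpha / M, M) + ((beta - alpha) / M) * wj +
      ((gamma - beta) / M) * wd
    delta <- outer(z[, d], mu[, d], "-")             # z_i - mu_j
    vinv <- matrix(1 / exp(logvar[, d]), M, M, byrow = TRUE)
    dz[, d] <- rowSums(cmat * (-delta * vinv)) + (gamma / M) * z[, d]
    dmu[, d] <- colSums(cmat * (delta * vinv))
    dlv[, d] <- colSums(cmat * (-0.5 + 0.5 * delta^2 * vinv))
  }
  list(dz = dz, dmu = dmu, dlv = dlv)
}

# Internal: one training step. Returns list(grads, loss).
train_step <- function(model, X, dataset_size) {
  cfg <- model$config
  B <- nrow(X)
  clamp_lim <- cfg$logvar_clamp
  kind <- cfg$kind

  if (kind == "me_vae") {
    size <- cfg$image_size
    X2 <- X; X3 <- X
    for (i in seq_len(B)) {
      m <- matrix(X[i, ], size, size)
      v <- make_views(m)
      X2[i, ] <- as.vector(v$rotated)
      X3[i, ] <- as.vector(v$polar)
    }
    c1 <- encoder_forward(model$encoders[[1]], X, clamp_lim)
    c2 <- encoder_forward(model$encoders[[2]], X2, clamp_lim)
    c3 <- encoder_forward(model$encoders[[3]], X3, clamp_lim)
    mu <- (c1$mu + c2$mu + c3$mu) / 3
    lv <- (c1$logvar + c2$logvar + c3$logvar) / 3
  } else {
    c1 <- encoder_forward(model$encoders[[1]], X, clamp_lim)
    mu <- c1$mu; lv <- c1$logvar
  }
  eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  sig_eps <- exp(lv / 2) * eps
  z <- mu + sig_eps
  dcache <- decoder_forward(model$decoder, z)
  Y <- dcache$out

  rec <- mean(rowSums((X - Y)^2))
  dY <- 2 * (Y - X) / B
  dec_bp <- decoder_backward(model$decoder, dcache, dY)
  dZ <- dec_bp$dZ

  if (kind == "beta_tcvae") {
    post <- posterior_params(mu, lv)
    est <- tc_decomposition(mu, lv, z, dataset_size)
    loss <- loss_breakdown("beta_tcvae",
                           total = rec + cfg$alpha * est$mi + cfg$beta * est$tc +
                             cfg$gamma * est$dimwise,
                           reconstruction = rec,
                           kl = est$mi + est$tc + est$dimwise,
                           mi = est$mi, tc = est$tc, dimwise_kl = est$dimwise)
    pg <- tc_penalty_grads(mu, lv, z, dataset_size, cfg$alpha, cfg$beta, cfg$gamma)
    dz_tot <- dZ + pg$dz
    dmu <- pg$dmu + dz_tot
    dlv <- pg$dlv + dz_tot * 0.5 * sig_eps
  } else {
    kl <- mean(rowSums(0.5 * (exp(lv) + mu^2 - 1 - lv)))
    loss <- loss_breakdown(kind, total = rec + cfg$beta * kl,
                           reconstruction = rec, kl = kl)
    dmu <- dZ + cfg$beta * mu / B
    dlv <- dZ * 0.5 * sig_eps + cfg$beta * 0.5 * (exp(lv) - 1) / B
  }

  if (kind == "me_vae") {
    e1 <- encoder_backward(model$encoders[[1]], c1, dmu / 3, dlv / 3, clamp_lim)
    e2 <- encoder_backward(model$encoders[[2]], c2, dmu / 3, dlv / 3, clamp_lim)
    e3 <- encoder_backward(model$encoders[[3]], c3, dmu / 3, dlv / 3, clamp_lim)
    grads <- list(encoders = list(e1$grads, e2$grads, e3$grads),
                  decoder = dec_bp$grads)
  } else {
    e1 <- encoder_backward(model$encoders[[1]], c1, dmu, dlv, clamp_lim)
    grads <- list(encoders = list(e1$grads), decoder = dec_bp$grads)
  }
  list(grads = grads, loss = loss)
}

#' Train a VAE model
#'
#' Seeded end-to-end: weight initialization, shuffling, view
#' augmentation and reparameterization sampling are all driven by
#' `train_config$seed`, so two runs with the same configuration produce
#' identical weights. The input dataset is not modified.
#'
#' @param dataset A (preprocessed) `synthetic_dataset`, or any list with
#'   an `images` element of same-sized square images in \[0, 1\].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return List of class `trained_vae` with elements `model` (the trained
#'   `vae_model`), `history` (data frame, one row per epoch with the mean
#'   loss components), `model_cfg` and `train_cfg`.
#' @export
train_model <- function(dataset, model_cfg, train_cfg = train_config()) {
  mv_assert(inherits(model_cfg, "model_config"), "model_cfg must be a model_config")
  mv_assert(inherits(train_cfg, "train_config"), "train_cfg must be a train_config")
  mv_assert(length(dataset$images) > 0, "dataset is empty",
            "morphovae_data_error")
  X <- images_to_batch(dataset$images, model_cfg$image_size)
  n <- nrow(X)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  model <- init_model(model_cfg, seed = train_cfg$seed)
  if (identical(model_cfg$init, "pca")) model <- pca_warmstart(model, X)
  set.seed(train_cfg$seed + 1L)

  params <- model_params(model)
  opt <- adam_init(params)
  t_step <- 0L
  hist_rows <- vector("list", train_cfg$epochs)

  for (epoch in seq_len(train_cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = train_cfg$batch_size)
    comp <- c(total = 0, reconstruction = 0, kl = 0, mi = 0, tc = 0, dimwise = 0)
    nb <- 0L
    for (s in starts) {
      batch <- idx[s:min(s + train_cfg$batch_size - 1L, n)]
      if (model_cfg$kind == "beta_tcvae" && length(batch) < 2L) next
      model <- set_model_params(model, params)
      step <- train_step(model, X[batch, , drop = FALSE], dataset_size = n)
      t_step <- t_step + 1L
      upd <- adam_step(params, step$grads, opt, t_step,
                       lr = train_cfg$learning_rate,
                       weight_decay = train_cfg$weight_decay)
      params <- upd$p; opt <- upd$s
      l <- step$loss
      comp <- comp + c(l$total, l$reconstruction, l$kl,
                       ifelse(is.na(l$mi), 0, l$mi),
                       ifelse(is.na(l$tc), 0, l$tc),
                       ifelse(is.na(l$dimwise_kl), 0, l$dimwise_kl))
      nb <- nb + 1L
    }
    hist_rows[[epoch]] <- data.frame(epoch = epoch, t(comp / max(nb, 1L)))
  }
  model <- set_model_params(model, params)
  history <- if (train_cfg$epochs > 0) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(), total = numeric(), reconstruction = numeric(),
               kl = numeric(), mi = numeric(), tc = numeric(), dimwise = numeric())
  structure(list(model = model, history = history, model_cfg = model_cfg,
                 train_cfg = train_cfg),
            class = "trained_vae")
}

#' Extract posterior-mean latent representations
#'
#' Row i of the result is the posterior mean `mu` of image i (no
#' sampling, so repeated calls are identical). For ME-VAE models the
#' deterministic view triplet (original, 0-degree rotation, polar flip)
#' is used and the three encoder means averaged.
#'
#' @param model A `vae_model` or `trained_vae`.
#' @param dataset Dataset whose `images` match the model's image size.
#' @return An object of class `latent_matrix`: list with `values`
#'   (n x L matrix, columns `z_0 .. z_{L-1}`), `labels` and `source_ids`.
#' @export
extract_latents <- function(model, dataset) {
  if (inherits(model, "trained_vae")) model <- model$model
  mv_assert(inherits(model, "vae_model"), "model must be a vae_model")
  n <- length(dataset$images)
  mv_assert(n > 0, "dataset is empty", "morphovae_data_error")
  L <- model$config$latent_dim
  values <- matrix(NA_real_, n, L)
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- encode(model, dataset$images[s:e])
    values[s:e, ] <- p$mu
  }
  colnames(values) <- paste0("z_", seq_len(L) - 1L)
  labels <- if (!is.null(dataset$labels)) dataset$labels else
    vapply(dataset$images, function(im) im$group, character(1))
  ids <- vapply(dataset$images, function(im) im$source_id, character(1))
  structure(list(values = values, labels = labels, source_ids = ids),
            class = "latent_matrix")
}

#' @export
print.latent_matrix <- function(x, ...) {
  cat(sprintf("<latent_matrix %d x %d (%s)>\n", nrow(x$values), ncol(x$values),
              paste(unique(x$labels), collapse = " vs ")))
  invisible(x)
}

#' Write / read a latent matrix as CSV
#'
#' Columns `z_0 .. z_{L-1}`, `label`, `source_id`.
#'
#' @param latents A `latent_matrix`.
#' @param path CSV file path.
#' @return `path` (write) or a `latent_matrix` (read).
#' @export
write_latents <- function(latents, path) {
  df <- data.frame(latents$values, label = latents$labels,
                   source_id = latents$source_ids, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  zc <- grep("^z_", names(df), value = TRUE)
  structure(list(values = as.matrix(df[, zc, drop = FALSE]),
                 labels = df$label, source_ids = df$source_id),
            class = "latent_matrix")
}

#' Save / load a training checkpoint
#'
#' One file per run holding the trained weights, configurations and
#' training history.
#'
#' @param trained A `trained_vae`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the `trained_vae` (load).
#' @export
save_checkpoint <- function(trained, path) {
  mv_assert(inherits(trained, "trained_vae"), "not a trained_vae")
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  mv_assert(file.exists(path), sprintf("no checkpoint at %s", path),
            "morphovae_io_error")
  obj <- readRDS(path)
  mv_assert(inherits(obj, "trained_vae"), "file is not a morphovae checkpoint",
            "morphovae_io_error")
  obj
}
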