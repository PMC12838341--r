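test_that("encode is deterministic, shaped, and order-preserving", {
  model <- init_model(tiny_config(), seed = 1)
  set.seed(4)
  imgs <- lapply(1:5, function(i) matrix(runif(256), 16, 16))
  p1 <- encode(model, imgs)
  p2 <- encode(model, imgs)
  expect_identical(p1, p2)
  expect_equal(dim(p1$mu), c(5, 3))
  expect_equal(dim(p1$logvar), c(5, 3))
  # order-preserving: single-image encodings match the batch rows
  for (i in c(1, 3, 5))
    expect_equal(encode(model, imgs[[i]])$mu[1, ], p1$mu[i, ])
  expect_error(encode(model, matrix(0, 8, 8)), "16 x 16")
})

test_that("reparameterize follows z = mu + sigma * eps", {
  # variance -> 0 limit gives z = mu
  p <- posterior_params(c(1, -2), c(-30, -30))
  set.seed(1)
  expect_equal(as.vector(reparameterize(p)), c(1, -2), tolerance = 1e-6)

  p2 <- posterior_params(matrix(0, 1, 2), matrix(0, 1, 2))
  set.seed(9); z1 <- reparameterize(p2)
  set.seed(9); z2 <- reparameterize(p2)
  expect_identical(z1, z2)

  # CLT bound: 10,000 standard normal samples per dim
  pbig <- posterior_params(matrix(0, 10000, 1), matrix(0, 10000, 1))
  set.seed(10)
  z <- reparameterize(pbig)
  expect_lt(abs(mean(z)), 3 / sqrt(10000))
})

test_that("kl_standard_normal matches the closed form", {
  expect_equal(kl_standard_normal(posterior_params(0, 0)), 0)
  expect_equal(kl_standard_normal(posterior_params(1, 0)), 0.5)
  expect_equal(kl_standard_normal(posterior_params(0, log(4))),
               0.5 * (4 - log(4) - 1))
  expect_equal(round(kl_standard_normal(posterior_params(0, log(4))), 5),
               0.80685)
  # non-negativity on random posteriors, zero iff standard normal
  set.seed(5)
  p <- posterior_params(matrix(rnorm(40), 10, 4), matrix(rnorm(40, 0, 0.5), 10, 4))
  expect_true(all(kl_standard_normal(p) >= 0))
})

test_that("beta_vae_loss combines MSE and KL linearly", {
  x <- matrix(runif(20), 2, 10)
  prior <- posterior_params(matrix(0, 2, 3), matrix(0, 2, 3))
  l0 <- beta_vae_loss(x, x, prior, beta = 6)
  expect_equal(l0$total, 0)

  set.seed(6)
  y <- matrix(runif(20), 2, 10)
  p <- posterior_params(matrix(rnorm(6), 2, 3), matrix(rnorm(6, 0, .3), 2, 3))
  m <- mean(rowSums((x - y)^2))
  k <- mean(kl_standard_normal(p))
  l1 <- beta_vae_loss(x, y, p, beta = 1)
  expect_equal(l1$total, m + k)
  l6 <- beta_vae_loss(x, y, p, beta = 6)
  expect_equal(l6$total, m + 6 * k)
  expect_equal(l6$reconstruction, m)
  expect_equal(l6$kl, k)
})

test_that("TCVAE estimator: identity, null, and single-dimension TC", {
  # TC is exactly zero at L = 1 (joint equals the single marginal)
  set.seed(7)
  p1 <- posterior_params(matrix(rnorm(64), 64, 1), matrix(rnorm(64, 0, .3), 64, 1))
  z1 <- reparameterize(p1)
  l1 <- tcvae_loss(p1, z1, dataset_size = 64)
  expect_equal(l1$tc, 0, tolerance = 1e-10)

  # decomposition identity: MI + TC + dimwise telescopes to
  # log q(z|x) - log p(z) exactly, for any weights of the estimator
  set.seed(8)
  M <- 64
  p <- posterior_params(matrix(rnorm(M * 2), M, 2),
                        matrix(rnorm(M * 2, 0, .4), M, 2))
  z <- reparameterize(p)
  l <- tcvae_loss(p, z, alpha = 1, beta = 1, gamma = 1, dataset_size = 200)
  direct <- mean(rowSums(dnorm(z, p$mu, exp(p$logvar / 2), log = TRUE)) -
                   rowSums(dnorm(z, log = TRUE)))
  expect_equal(l$total, direct, tolerance = 1e-10)

  # batch of 1 rejected
  ps <- posterior_params(matrix(0, 1, 2), matrix(0, 1, 2))
  expect_error(tcvae_loss(ps, matrix(0, 1, 2), dataset_size = 10),
               class = "morphovae_degenerate_error")
})

test_that("aggregate_latents is the elementwise mean", {
  expect_equal(aggregate_latents(c(1, 1), c(2, 2), c(3, 3)), c(2, 2))
  z <- c(-1, 0.5, 2)
  expect_equal(aggregate_latents(z, z, z), z)
  a <- rnorm(4); b <- rnorm(4); cc <- rnorm(4)
  expect_equal(aggregate_latents(a, b, cc), aggregate_latents(cc, a, b))
  expect_error(aggregate_latents(1:2, 1:3, 1:2), "length")
})

test_that("me_vae_forward reduces to the single-encoder model when tied", {
  cfg <- tiny_config("me_vae")
  model <- init_model(cfg, seed = 3)
  model$encoders[[2]] <- model$encoders[[1]]
  model$encoders[[3]] <- model$encoders[[1]]
  set.seed(12)
  x <- matrix(runif(256), 16, 16)
  out <- me_vae_forward(model, x, x, x, sample = FALSE)

  # identical views + tied weights: aggregate equals the single-encoder
  # posterior (compare against the beta_vae path sharing the weights)
  m1 <- model
  m1$config$kind <- "beta_vae"
  m1$encoders <- model$encoders[1]
  single <- encode(m1, x)
  expect_equal(out$posterior$mu, single$mu)
  expect_equal(out$posterior$logvar, single$logvar)
  expect_equal(out$z, out$posterior$mu)   # sample = FALSE uses the mean
  expect_equal(matrix(out$reconstruction[1, ], 16, 16),
               decode(model, out$z[1, ]))

  # untied: aggregated mu is the mean of the three encoder mus
  model2 <- init_model(cfg, seed = 4)
  v <- make_views(x)
  out2 <- me_vae_forward(model2, v$original, v$rotated, v$polar, sample = FALSE)
  mus <- lapply(1:3, function(i) {
    m <- model2
    m$config$kind <- "beta_vae"   # single-encoder path
    m$encoders <- m$encoders[i]
    encode(m, list(v$original, v$rotated, v$polar)[[i]])$mu
  })
  expect_equal(out2$posterior$mu, (mus[[1]] + mus[[2]] + mus[[3]]) / 3)
  expect_true(is.finite(out2$loss$total))
  expect_gte(out2$loss$reconstruction, 0)

  # shape mismatch among views rejected
  expect_error(me_vae_forward(model, x, x, matrix(0, 8, 8)), "16 x 16")
})

test_that("decode is deterministic, bounded, and composes with aggregation", {
  model <- init_model(tiny_config(), seed = 2)
  z <- c(0.5, -1, 2)
  img1 <- decode(model, z)
  expect_identical(img1, decode(model, z))
  expect_equal(dim(img1), c(16, 16))
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(decode(model, aggregate_latents(z, z, z)), img1)
  expect_error(decode(model, c(1, 2)), "length")
})
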