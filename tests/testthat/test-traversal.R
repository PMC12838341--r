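test_that("traverse sweeps the requested coordinate around the baseline", {
  model <- init_model(tiny_config(L = 3), seed = 1)
  tr <- traverse(model, dim = 1, n_steps = 7)
  expect_equal(tr$values, c(-3, -2, -1, 0, 1, 2, 3))
  expect_length(tr$images, 7)
  expect_true(all(vapply(tr$images, function(m) all(m >= 0 & m <= 1), logical(1))))

  # value 0 on the zero baseline decodes the zero vector
  expect_equal(tr$images[[4]], decode(model, c(0, 0, 0)))

  # deterministic
  tr2 <- traverse(model, dim = 1, n_steps = 7)
  expect_identical(tr$images, tr2$images)

  # non-zero baseline respected
  base <- c(0.5, -1, 2)
  trb <- traverse(model, dim = 0, n_steps = 2, baseline = base)
  expect_equal(trb$images[[1]], decode(model, c(-3, -1, 2)))

  expect_error(traverse(model, dim = 3), "dim")
})

test_that("abs_difference_map basics", {
  set.seed(2)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(abs_difference_map(a, a), matrix(0, 8, 8))
  expect_equal(abs_difference_map(a, b), abs_difference_map(b, a))
  expect_equal(abs_difference_map(matrix(0, 4, 4), matrix(1, 4, 4)),
               matrix(1, 4, 4))
  expect_error(abs_difference_map(a, matrix(0, 4, 4)), "shape")
})

test_that("ssim_map agrees with an independent scalar implementation", {
  set.seed(3)
  a <- matrix(runif(24 * 24), 24, 24)

  # self-similarity is 1 everywhere
  expect_equal(ssim_map(a, a), matrix(1, 24, 24), tolerance = 1e-9)
  expect_equal(ssim_dissimilarity(a, a), matrix(0, 24, 24), tolerance = 1e-9)

  b <- clamp_local <- pmin(pmax(a + matrix(rnorm(24 * 24, 0, 0.1), 24, 24), 0), 1)
  expect_equal(ssim_map(a, b), ssim_map(b, a), tolerance = 1e-12)

  # reduction identity: mean of the map equals the scalar SSIM oracle
  expect_equal(mean(ssim_map(a, b)), oracle_ssim_mean(a, b), tolerance = 1e-6)

  # dissimilarity lives in [0, 1]
  dm <- ssim_dissimilarity(a, b)
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("threshold_map counts pixels by quantile", {
  # constant map: all pixels tie -> all masked
  expect_true(all(threshold_map(matrix(0.3, 5, 5), 0.95)))

  # 100 strictly increasing values at quantile 0.95 -> 5 pixels
  g <- matrix(seq(0.01, 1, length.out = 100), 10, 10)
  expect_equal(sum(threshold_map(g, 0.95)), 5)

  # raising the quantile never grows the mask
  set.seed(4)
  m <- matrix(runif(400), 20, 20)
  masks <- lapply(c(0.5, 0.8, 0.95), function(q) threshold_map(m, q))
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))

  # mask size matches ceiling((1-q) * H * W) up to ties
  expect_equal(sum(threshold_map(m, 0.9)), ceiling(0.1 * 400), tolerance = 2)

  expect_error(threshold_map(m, 1.5), "quantile")
})

test_that("difference_report orders, flags, and degenerates correctly", {
  model <- init_model(tiny_config(L = 4), seed = 5)

  # a decoder that ignores z produces all-zero difference maps
  blind <- model
  blind$decoder$hidden[[1]]$W[] <- 0
  lat <- structure(list(values = `colnames<-`(matrix(rnorm(80), 20, 4),
                                              paste0("z_", 0:3)),
                        labels = rep(c("control", "treated"), 10),
                        source_ids = as.character(1:20)),
                   class = "latent_matrix")
  tab <- effect_size_table(lat)
  rep0 <- difference_report(blind, tab, top_k = 1, bottom_k = 1)
  expect_lt(max(rep0$summary$mean_abs_diff), 1e-12)
  expect_lt(max(rep0$summary$mean_dissim), 1e-9)

  # structure and determinism on a live decoder
  rep1 <- difference_report(model, tab, top_k = 2, bottom_k = 1)
  expect_equal(nrow(rep1$summary), 3)
  expect_setequal(rep1$summary$end, c("top", "bottom"))
  expect_equal(rep1$summary$dimension[1], ranked_dimensions(tab)[1])
  rep2 <- difference_report(model, tab, top_k = 2, bottom_k = 1)
  expect_equal(rep1$summary, rep2$summary)

  expect_error(difference_report(model, tab, top_k = 4, bottom_k = 1), "exceed")
})
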