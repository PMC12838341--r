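test_that("sample_cell_params follows the configured distributions", {
  # degenerate: all sds zero -> exactly the means
  cfg <- group_config("control", sds = setNames(rep(0, 8), c(
    "radius", "ring_width", "ring_intensity", "interior_intensity",
    "irregularity_amp", "irregularity_order", "noise_sd", "background")))
  set.seed(1)
  p <- sample_cell_params(cfg)
  for (f in c("radius", "ring_width", "ring_intensity", "interior_intensity"))
    expect_equal(p[[f]], cfg$means[[f]])

  # determinism under a fixed seed
  cfg2 <- group_config("control")
  set.seed(7); p1 <- sample_cell_params(cfg2)
  set.seed(7); p2 <- sample_cell_params(cfg2)
  expect_identical(p1, p2)

  # Monte-Carlo: 10,000 radius draws, mean 20 sd 2 -> mean within 3 SE
  cfg3 <- group_config("control", means = c(radius = 20), sds = c(radius = 2))
  set.seed(11)
  draws <- replicate(10000, sample_cell_params(cfg3)$radius)
  expect_lt(abs(mean(draws) - 20), 3 * 2 / sqrt(10000))

  # invalid config rejected
  expect_error(group_config("control", sds = c(radius = -1)), "deviations")
})

test_that("render_cell geometry and degenerate cases behave", {
  # rotational symmetry without noise/irregularity
  p <- morph_params(radius = 5, ring_width = 1.5, noise_sd = 0,
                    irregularity_amp = 0)
  img <- render_cell(p, size = 17)
  rot90 <- t(img)[rev(seq_len(ncol(img))), ]
  expect_equal(img, rot90)
  expect_true(all(img >= 0 & img <= 1))

  # ring_width = 0 -> no pixel takes ring_intensity
  p0 <- morph_params(radius = 5, ring_width = 0, ring_intensity = 0.9,
                     interior_intensity = 0.4, background = 0.1, noise_sd = 0)
  img0 <- render_cell(p0, size = 16)
  expect_false(any(img0 == 0.9))

  # interior == background -> indistinguishable without noise
  pe <- morph_params(radius = 5, ring_width = 1, ring_intensity = 0.9,
                     interior_intensity = 0.2, background = 0.2, noise_sd = 0)
  expect_setequal(unique(as.vector(render_cell(pe, size = 16))), c(0.2, 0.9))

  # oversized cell rejected
  expect_error(render_cell(morph_params(radius = 40), size = 32),
               class = "morphovae_frame_error")
})

test_that("generate_dataset is balanced, deterministic, and parameter-faithful", {
  g <- default_group_configs()
  ds <- generate_dataset(g$control, g$treated, n_per_group = 3, size = 64,
                         seed = 2)
  expect_length(ds$images, 6)
  expect_equal(sum(ds$labels == "control"), 3)
  expect_equal(sum(ds$labels == "treated"), 3)
  expect_equal(nrow(ds$params), 6)
  expect_true(all(vapply(ds$images, function(im)
    all(im$pixels >= 0 & im$pixels <= 1), logical(1))))

  ds2 <- generate_dataset(g$control, g$treated, n_per_group = 3, size = 64,
                          seed = 2)
  expect_identical(ds, ds2)
})

test_that("empirical factor effect sizes match the injected ones", {
  # null: identical configs -> d within Monte-Carlo error of 0
  base <- group_config("control")
  same <- group_config("treated")
  ds <- generate_dataset(base, same, n_per_group = 500, size = 64, seed = 3)
  se <- sqrt(1000 / (500 * 500))
  for (f in c("radius", "ring_width", "interior_intensity")) {
    d <- cohens_d(ds$params[[f]][ds$labels == "control"],
                  ds$params[[f]][ds$labels == "treated"])
    expect_lt(abs(d), 3 * se)
  }

  # injected d = 2 on ring_width recovered from stored params
  g <- default_group_configs()
  expect_equal(injected_effect_size(g$control, g$treated, "ring_width"), 2)
  ds2 <- generate_dataset(g$control, g$treated, n_per_group = 500, size = 64,
                          seed = 4)
  d2 <- cohens_d(ds2$params$ring_width[ds2$labels == "control"],
                 ds2$params$ring_width[ds2$labels == "treated"])
  se2 <- sqrt(1000 / 250000 + 4 / 2000)
  expect_lt(abs(d2 - 2), 3 * se2)
})

test_that("injected_effect_size arithmetic and errors", {
  c1 <- group_config("control", means = c(radius = 10), sds = c(radius = 1))
  t1 <- group_config("treated", means = c(radius = 10), sds = c(radius = 1))
  expect_equal(injected_effect_size(c1, t1, "radius"), 0)
  t2 <- group_config("treated", means = c(radius = 11), sds = c(radius = 1))
  expect_equal(injected_effect_size(c1, t2, "radius"), 1)
  # delta = 2, sds 1 and 2 -> 2 / sqrt(2.5)
  t3 <- group_config("treated", means = c(radius = 12), sds = c(radius = 2))
  expect_equal(injected_effect_size(c1, t3, "radius"), 2 / sqrt(2.5),
               tolerance = 1e-12)
  expect_equal(round(injected_effect_size(c1, t3, "radius"), 5), 1.26491)
  # both sds zero -> error
  cz <- group_config("control", sds = c(ring_intensity = 0))
  tz <- group_config("treated", sds = c(ring_intensity = 0))
  expect_error(injected_effect_size(cz, tz, "ring_intensity"),
               class = "morphovae_degenerate_error")
})

test_that("dataset round-trips through disk", {
  ds <- tiny_dataset(n_per_group = 4, size = 16)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "params.csv")))
  expect_length(list.files(dir, pattern = "\\.png$", recursive = TRUE), 8)
  back <- load_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$params$ring_width, ds$params$ring_width, tolerance = 1e-12)
  # pixels survive up to 8-bit quantization
  expect_lt(max(abs(back$images[[1]]$pixels - ds$images[[1]]$pixels)), 1 / 255)
})
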