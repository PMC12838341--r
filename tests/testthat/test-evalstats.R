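test_that("cohens_d matches the brute-force oracle and its symmetries", {
  expect_equal(cohens_d(c(0, 1), c(0, 1)), 0)
  expect_equal(cohens_d(c(0, 1), c(2, 3)), 2 / sqrt(0.5 / 2 * 2), tolerance = 1e-12)
  expect_equal(round(cohens_d(c(0, 1), c(2, 3)), 5), 2.82843)

  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -2, 2))
    d <- cohens_d(a, b)
    expect_equal(d, oracle_cohens_d(a, b), tolerance = 1e-10)
    expect_equal(cohens_d(b, a), -d, tolerance = 1e-12)       # antisymmetry
    expect_equal(abs(cohens_d(a * 3.7, b * 3.7)), abs(d), tolerance = 1e-10)
  }

  expect_error(cohens_d(c(1), c(1, 2)), class = "morphovae_degenerate_error")
  expect_error(cohens_d(c(1, 1), c(2, 2)), class = "morphovae_degenerate_error")
})

test_that("cohens_d_ci uses the normal approximation correctly", {
  ci <- cohens_d_ci(0, 1000, 1000, level = 0.95)
  half <- qnorm(0.975) * sqrt(2000 / (1000 * 1000))
  expect_equal(unname(ci), c(-half, half), tolerance = 1e-12)
  expect_equal(round(half, 5), 0.08765)

  # level -> 0 collapses the interval
  ci0 <- cohens_d_ci(1.3, 50, 50, level = 1e-12)
  expect_equal(unname(ci0), c(1.3, 1.3), tolerance = 1e-6)

  # monotone: wider with level, narrower with n
  w <- function(ci) diff(ci)
  expect_gt(w(cohens_d_ci(1, 30, 30, 0.99)), w(cohens_d_ci(1, 30, 30, 0.9)))
  expect_lt(w(cohens_d_ci(1, 300, 300, 0.95)), w(cohens_d_ci(1, 30, 30, 0.95)))
  expect_error(cohens_d_ci(1, 30, 30, level = 1.2), "level")
})

test_that("effect_size_table ranks, recovers signal, and is permutation-invariant", {
  # constructed indicator dimension must rank first
  set.seed(2)
  n <- 40; L <- 5
  V <- matrix(rnorm(2 * n * L, 0, 0.01), 2 * n, L)
  labs <- rep(c("control", "treated"), each = n)
  V[, 4] <- ifelse(labs == "treated", 1, 0) + rnorm(2 * n, 0, 0.01)
  lat <- structure(list(values = `colnames<-`(V, paste0("z_", 0:4)),
                        labels = labs,
                        source_ids = as.character(seq_len(2 * n))),
                   class = "latent_matrix")
  tab <- effect_size_table(lat)
  expect_equal(tab$dimension[tab$rank == 1], 3)  # 0-based index of column 4
  expect_setequal(tab$rank, 1:5)
  expect_true(all(tab$ci_low <= tab$d & tab$d <= tab$ci_high))
  # |d| non-increasing in rank
  expect_true(all(diff(abs(tab$d[order(tab$rank)])) <= 1e-12))

  # permutation invariance
  perm <- sample(2 * n)
  lat2 <- lat; lat2$values <- lat$values[perm, ]; lat2$labels <- lat$labels[perm]
  lat2$source_ids <- lat$source_ids[perm]
  expect_equal(effect_size_table(lat2), tab)

  # recovery: injected standardized shift delta is estimated within 3 SE
  set.seed(3)
  delta <- 1.5; n2 <- 500
  V2 <- matrix(rnorm(2 * n2 * 6), 2 * n2, 6)
  labs2 <- rep(c("control", "treated"), each = n2)
  V2[labs2 == "treated", 2] <- V2[labs2 == "treated", 2] + delta
  lat3 <- structure(list(values = `colnames<-`(V2, paste0("z_", 0:5)),
                         labels = labs2,
                         source_ids = as.character(seq_len(2 * n2))),
                    class = "latent_matrix")
  tab3 <- effect_size_table(lat3)
  se <- sqrt(2 * n2 / n2^2 + delta^2 / (4 * n2))
  expect_equal(tab3$dimension[tab3$rank == 1], 1)
  expect_lt(abs(tab3$d[tab3$dimension == 1] - delta), 3 * se)

  expect_error(effect_size_table(structure(list(
    values = V, labels = rep("control", 2 * n),
    source_ids = as.character(seq_len(2 * n))), class = "latent_matrix")),
    class = "morphovae_data_error")
})

test_that("kde produces normalized, symmetric densities under Scott's rule", {
  set.seed(4)
  x <- rnorm(400)
  cv <- kde(x)
  expect_true(all(cv$density >= 0))
  expect_equal(cv$bandwidth, sd(x) * 400^(-1 / 5))
  expect_lt(abs(density_integral(cv) - 1), 0.01)

  sym <- kde(c(-1, 1))
  expect_equal(sym$density, rev(sym$density), tolerance = 1e-12)
  expect_equal(sym$grid, -rev(sym$grid), tolerance = 1e-12)

  expect_error(kde(rep(2, 10)), class = "morphovae_degenerate_error")
})

test_that("density_overlap separates what it should", {
  set.seed(5)
  a <- rnorm(500); b <- rnorm(500)
  expect_gt(density_overlap(kde(a), kde(b)), 0.9)
  far <- rnorm(500, mean = 10)
  expect_lt(density_overlap(kde(a), kde(far)), 0.01)
})

test_that("violin_summary quantiles and equivariance", {
  v <- violin_summary(c(1, 2, 3, 4, 5))
  expect_equal(v$median, 3); expect_equal(v$q1, 2); expect_equal(v$q3, 4)

  vc <- violin_summary(rep(3, 6))
  expect_equal(vc$median, vc$q1)
  expect_equal(vc$median, vc$q3)

  set.seed(6)
  x <- rnorm(50)
  v1 <- violin_summary(x)
  v2 <- violin_summary(2.5 * x - 1)
  expect_equal(v2$median, 2.5 * v1$median - 1, tolerance = 1e-12)
  expect_equal(v2$q1, 2.5 * v1$q1 - 1, tolerance = 1e-12)

  expect_error(violin_summary(1:3), class = "morphovae_degenerate_error")
})
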