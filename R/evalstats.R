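#' Cohen's d standardized mean difference
#'
#' `d = (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)` with n-1
#' sample variances. The equal-weight pooled standard deviation matches
#' the study's equal-group-size design; `b` is the treated group and `a`
#' the control group, so `d > 0` means treated > control. Set
#' `pooling = "weighted"` for the (n-1)-weighted pooled variance when
#' group sizes differ.
#'
#' @param a Control sample (numeric, length >= 2).
#' @param b Treated sample (numeric, length >= 2).
#' @param pooling `"equal"` (default) or `"weighted"`.
#' @return The effect size (a number).
#' @export
cohens_d <- function(a, b, pooling = c("equal", "weighted")) {
  pooling <- match.arg(pooling)
  mv_assert(length(a) >= 2 && length(b) >= 2,
            "each sample needs at least 2 observations",
            "morphovae_degenerate_error")
  mv_assert(all(is.finite(a)) && all(is.finite(b)), "samples must be finite")
  va <- var(a); vb <- var(b)
  mv_assert(va > 0 || vb > 0, "both samples are degenerate (zero variance)",
            "morphovae_degenerate_error")
  sp2 <- if (pooling == "equal") (va + vb) / 2 else
    ((length(a) - 1) * va + (length(b) - 1) * vb) / (length(a) + length(b) - 2)
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Confidence interval for Cohen's d
#'
#' Large-sample normal approximation:
#' `d +/- z * sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))`.
#'
#' @param d Effect size.
#' @param n1,n2 Group sizes (>= 2).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
cohens_d_ci <- function(d, n1, n2, level = 0.95) {
  mv_assert(is_number(d), "d must be a number")
  mv_assert(n1 >= 2 && n2 >= 2, "n1 and n2 must be >= 2")
  mv_assert(is_number(level) && level > 0 && level < 1, "level must be in (0, 1)")
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm((1 + level) / 2)
  c(low = d - z * se, high = d + z * se)
}

#' Per-dimension effect sizes of a two-group latent matrix
#'
#' Computes Cohen's d with a confidence interval for every latent
#' dimension and ranks dimensions by `|d|` (rank 1 = largest; ties broken
#' by lower dimension index). This is the screening step that identifies
#' which latent factors separate the groups.
#'
#' @param latents A `latent_matrix` (see [extract_latents()]) whose
#'   labels contain exactly two groups, each with >= 2 rows.
#' @param control,treated Labels of the two groups; defaults `"control"`
#'   and `"treated"`.
#' @param level Confidence level for the intervals.
#' @return A data frame of class `effect_size_table` with columns
#'   `dimension` (0-based, matching the `z_i` naming), `d`, `ci_low`,
#'   `ci_high`, `rank`, `mean_control`, `mean_treated`, `sd_control`,
#'   `sd_treated`, `pooled_sd`, ordered by dimension.
#' @export
effect_size_table <- function(latents, control = "control", treated = "treated",
                              level = 0.95) {
  mv_assert(inherits(latents, "latent_matrix"), "latents must be a latent_matrix")
  ia <- latents$labels == control
  ib <- latents$labels == treated
  mv_assert(sum(ia) >= 2 && sum(ib) >= 2,
            sprintf("both groups ('%s', '%s') need >= 2 rows", control, treated),
            "morphovae_data_error")
  V <- latents$values
  L <- ncol(V)
  rows <- lapply(seq_len(L), function(j) {
    a <- V[ia, j]; b <- V[ib, j]
    d <- cohens_d(a, b)
    ci <- cohens_d_ci(d, sum(ia), sum(ib), level = level)
    data.frame(dimension = j - 1L, d = d, ci_low = ci[["low"]],
               ci_high = ci[["high"]], rank = NA_integer_,
               mean_control = mean(a), mean_treated = mean(b),
               sd_control = sd(a), sd_treated = sd(b),
               pooled_sd = sqrt((var(a) + var(b)) / 2))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-abs(tab$d), tab$dimension)
  tab$rank[ord] <- seq_len(L)
  class(tab) <- c("effect_size_table", "data.frame")
  tab
}

#' Dimensions by rank
#'
#' Convenience accessor: the 0-based dimension indices of an
#' [effect_size_table()] ordered by rank (rank 1 first).
#'
#' @param table An `effect_size_table`.
#' @return Integer vector of dimension indices.
#' @export
ranked_dimensions <- function(table) {
  table$dimension[order(table$rank)]
}

#' Gaussian kernel density estimate
#'
#' Density on an even grid spanning the data range plus three bandwidths
#' on each side. Bandwidth defaults to Scott's rule
#' `sd(x) * n^(-1/5)`.
#'
#' @param values Numeric sample (length >= 2, non-degenerate).
#' @param bandwidth Kernel bandwidth; `NULL` for Scott's rule.
#' @param n_grid Number of grid points.
#' @param group Optional group label carried into the result.
#' @return An object of class `density_curve`: list with `grid`,
#'   `density`, `bandwidth`, `group`.
#' @export
kde <- function(values, bandwidth = NULL, n_grid = 512L, group = NA_character_) {
  mv_assert(length(values) >= 2, "need at least 2 values",
            "morphovae_degenerate_error")
  mv_assert(all(is.finite(values)), "values must be finite")
  mv_assert(sd(values) > 0, "zero-variance sample has no density estimate",
            "morphovae_degenerate_error")
  if (is.null(bandwidth)) bandwidth <- sd(values) * length(values)^(-1 / 5)
  mv_assert(is_number(bandwidth) && bandwidth > 0, "bandwidth must be > 0")
  grid <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
              length.out = n_grid)
  # vectorized kernel sum; chunk over data to bound memory
  dens <- numeric(n_grid)
  for (s in seq(1L, length(values), by = 1024L)) {
    v <- values[s:min(s + 1023L, length(values))]
    dens <- dens + colSums(exp(-outer(v, grid, "-")^2 / (2 * bandwidth^2)))
  }
  dens <- dens / (length(values) * bandwidth * sqrt(2 * pi))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 group = group),
            class = "density_curve")
}

#' Trapezoid integral of a density curve
#'
#' @param curve A `density_curve`.
#' @return The integral over the evaluated grid (close to 1).
#' @export
density_integral <- function(curve) {
  g <- curve$grid; d <- curve$density
  sum(diff(g) * (head(d, -1) + tail(d, -1)) / 2)
}

#' Overlap coefficient of two density curves
#'
#' Integral of the pointwise minimum of the two densities over a common
#' grid (1 = identical distributions, 0 = disjoint). Used to judge how
#' separated the two groups are along one latent dimension.
#'
#' @param curve_a,curve_b `density_curve` objects.
#' @param n_grid Number of points of the common grid.
#' @return Overlap in \[0, 1\] (up to quadrature error).
#' @export
density_overlap <- function(curve_a, curve_b, n_grid = 1024L) {
  lo <- min(curve_a$grid[1], curve_b$grid[1])
  hi <- max(max(curve_a$grid), max(curve_b$grid))
  g <- seq(lo, hi, length.out = n_grid)
  fa <- approx(curve_a$grid, curve_a$density, xout = g, yleft = 0, yright = 0)$y
  fb <- approx(curve_b$grid, curve_b$density, xout = g, yleft = 0, yright = 0)$y
  m <- pmin(fa, fb)
  sum(diff(g) * (head(m, -1) + tail(m, -1)) / 2)
}

#' Violin-plot summary statistics
#'
#' Median and quartiles (linear-interpolation quantiles) plus the
#' support range, the numbers displayed by a violin plot's inner
#' markers.
#'
#' @param values Numeric sample (length >= 4).
#' @return An object of class `violin_summary`: list with `median`, `q1`,
#'   `q3`, `range`.
#' @export
violin_summary <- function(values) {
  mv_assert(length(values) >= 4, "need at least 4 values",
            "morphovae_degenerate_error")
  mv_assert(all(is.finite(values)), "values must be finite")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q1 = q[1], q3 = q[3], range = range(values)),
            class = "violin_summary")
}
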