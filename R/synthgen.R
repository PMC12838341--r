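#' Generative factors of one synthetic cell
#'
#' Describes a single blob-like cell rendered by [render_cell()]: a bright
#' membrane ring of width `ring_width` around an interior disc, with a
#' wavy boundary (random-phase cosine harmonics) and additive Gaussian
#' pixel noise. All intensities are on the \[0, 1\] grayscale.
#'
#' @param radius Cell radius in pixels (> 0).
#' @param ring_width Membrane ring width in pixels (>= 0).
#' @param ring_intensity Ring gray level in \[0, 1\].
#' @param interior_intensity Interior gray level in \[0, 1\].
#' @param irregularity_amp Boundary perturbation amplitude as a fraction of
#'   the radius, in \[0, 0.5).
#' @param irregularity_order Number of cosine harmonics (non-negative
#'   integer); 0 disables the perturbation.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param background Background gray level in \[0, 1\].
#'
#' @return An object of class `morph_params` (a named list).
#' @export
morph_params <- function(radius, ring_width = 0, ring_intensity = 0.8,
                         interior_intensity = 0.4, irregularity_amp = 0,
                         irregularity_order = 0L, noise_sd = 0,
                         background = 0.1) {
  p <- list(radius = radius, ring_width = ring_width,
            ring_intensity = ring_intensity,
            interior_intensity = interior_intensity,
            irregularity_amp = irregularity_amp,
            irregularity_order = as.integer(round(irregularity_order)),
            noise_sd = noise_sd, background = background)
  validate_morph_params(p)
  structure(p, class = "morph_params")
}

morph_factor_names <- function() {
  c("radius", "ring_width", "ring_intensity", "interior_intensity",
    "irregularity_amp", "irregularity_order", "noise_sd", "background")
}

validate_morph_params <- function(p) {
  for (f in morph_factor_names())
    mv_assert(is_number(p[[f]]), sprintf("%s must be a finite number", f))
  mv_assert(p$radius > 0, "radius must be > 0")
  mv_assert(p$ring_width >= 0, "ring_width must be >= 0")
  for (f in c("ring_intensity", "interior_intensity", "background"))
    mv_assert(p[[f]] >= 0 && p[[f]] <= 1, sprintf("%s must be in [0, 1]", f))
  mv_assert(p$irregularity_amp >= 0 && p$irregularity_amp < 0.5,
            "irregularity_amp must be in [0, 0.5)")
  mv_assert(p$irregularity_order >= 0, "irregularity_order must be >= 0")
  mv_assert(p$noise_sd >= 0, "noise_sd must be >= 0")
  invisible(p)
}

#' Per-group sampling distribution of morphological factors
#'
#' Each factor of [morph_params()] is drawn independently from a normal
#' distribution with the configured mean and standard deviation, then
#' clipped to the factor's valid range.
#'
#' @param label Group label (e.g. `"control"` or `"treated"`).
#' @param means Named numeric vector of factor means; names must be a
#'   subset of the `morph_params` factors. Unspecified factors take the
#'   defaults below.
#' @param sds Named numeric vector of factor standard deviations (>= 0);
#'   unspecified factors default to 0 (held fixed).
#'
#' @details The package default configurations (see
#'   [default_group_configs()]) emulate the treatment response reported
#'   for nanoparticle-exposed macrophages: membrane expansion (wider
#'   ring), a central density shift (brighter interior) and shape
#'   distortion (larger boundary irregularity), each injected at a
#'   standardized effect size of 2 — see [injected_effect_size()].
#'
#' @return An object of class `group_config`.
#' @export
group_config <- function(label, means = numeric(), sds = numeric()) {
  base_means <- c(radius = 16, ring_width = 2.5, ring_intensity = 0.85,
                  interior_intensity = 0.45, irregularity_amp = 0.08,
                  irregularity_order = 4, noise_sd = 0.03, background = 0.15)
  base_sds <- c(radius = 2, ring_width = 0.8, ring_intensity = 0.05,
                interior_intensity = 0.06, irregularity_amp = 0.03,
                irregularity_order = 0, noise_sd = 0.005, background = 0.02)
  bad <- setdiff(names(means), names(base_means))
  mv_assert(length(bad) == 0, paste("unknown factors:", paste(bad, collapse = ", ")))
  bad <- setdiff(names(sds), names(base_sds))
  mv_assert(length(bad) == 0, paste("unknown factors:", paste(bad, collapse = ", ")))
  base_means[names(means)] <- means
  base_sds[names(sds)] <- sds
  mv_assert(all(is.finite(base_means)) && all(is.finite(base_sds)),
            "means and sds must be finite")
  mv_assert(all(base_sds >= 0), "standard deviations must be >= 0")
  structure(list(label = as.character(label), means = base_means,
                 sds = base_sds),
            class = "group_config")
}

#' Default two-group configuration
#'
#' Control and treated groups sharing all nuisance factors; the treated
#' group's `ring_width`, `interior_intensity` and `irregularity_amp`
#' means are shifted by two pooled standard deviations (injected
#' Cohen's d = 2 for each).
#'
#' @return Named list with elements `control` and `treated`.
#' @export
default_group_configs <- function() {
  control <- group_config("control")
  treated <- group_config("treated",
                          means = c(ring_width = 2.5 + 2 * 0.8,
                                    interior_intensity = 0.45 + 2 * 0.06,
                                    irregularity_amp = 0.08 + 2 * 0.03))
  list(control = control, treated = treated)
}

#' Sample morphological parameters for one cell
#'
#' Draws every factor independently from the group's normal distribution
#' and clips to the valid ranges. Uses R's global random number stream;
#' seed it with `set.seed()` for reproducibility.
#'
#' @param config A [group_config()].
#' @return A [morph_params()] object.
#' @export
sample_cell_params <- function(config) {
  mv_assert(inherits(config, "group_config"), "config must be a group_config")
  m <- config$means; s <- config$sds
  draw <- rnorm(length(m), mean = m, sd = s)
  names(draw) <- names(m)
  # clip to the type invariants
  draw["radius"] <- max(draw["radius"], 1e-6)
  draw["ring_width"] <- max(draw["ring_width"], 0)
  for (f in c("ring_intensity", "interior_intensity", "background"))
    draw[f] <- clamp(draw[f], 0, 1)
  draw["irregularity_amp"] <- clamp(draw["irregularity_amp"], 0, 0.5 - 1e-9)
  draw["irregularity_order"] <- max(round(draw["irregularity_order"]), 0)
  draw["noise_sd"] <- max(draw["noise_sd"], 0)
  morph_params(radius = draw[["radius"]], ring_width = draw[["ring_width"]],
               ring_intensity = draw[["ring_intensity"]],
               interior_intensity = draw[["interior_intensity"]],
               irregularity_amp = draw[["irregularity_amp"]],
               irregularity_order = draw[["irregularity_order"]],
               noise_sd = draw[["noise_sd"]],
               background = draw[["background"]])
}

#' Render one synthetic cell image
#'
#' The cell boundary in polar coordinates around the frame center is
#' `r(theta) = radius * (1 + irregularity_amp * s(theta))` where
#' `s(theta)` is the mean of `irregularity_order` cosine harmonics with
#' random phases (so `|s| <= 1`). Pixels within `ring_width` inside the
#' boundary take `ring_intensity`, deeper pixels take
#' `interior_intensity`, outside pixels take `background`; Gaussian noise
#' of sd `noise_sd` is added and the result clipped to \[0, 1\].
#'
#' @param params A [morph_params()] object.
#' @param size Image side length in pixels (>= 16).
#' @param phases Optional vector of harmonic phases (radians) of length
#'   `irregularity_order`; drawn uniformly from \[0, 2*pi) when `NULL`.
#' @return Numeric `size` x `size` matrix in \[0, 1\].
#' @export
render_cell <- function(params, size = 64, phases = NULL) {
  validate_morph_params(params)
  mv_assert(is_number(size) && size >= 16, "size must be >= 16")
  size <- as.integer(size)
  r_max <- params$radius * (1 + params$irregularity_amp)
  mv_assert(r_max <= size / 2 - 1,
            sprintf("cell (max radius %.1f px) exceeds the %d px frame", r_max, size),
            class = "morphovae_frame_error")
  k <- params$irregularity_order
  if (is.null(phases)) phases <- if (k > 0) runif(k, 0, 2 * pi) else numeric()
  mv_assert(length(phases) == k, "phases must have length irregularity_order")

  ctr <- (size + 1) / 2
  xs <- seq_len(size) - ctr
  dx <- matrix(xs, size, size, byrow = TRUE)   # column offsets
  dy <- matrix(xs, size, size)                 # row offsets
  rho <- sqrt(dx^2 + dy^2)
  img <- matrix(params$background, size, size)
  if (k > 0 && params$irregularity_amp > 0) {
    theta <- atan2(dy, dx)
    s <- 0
    for (h in seq_len(k)) s <- s + cos(h * theta + phases[h])
    r_bound <- params$radius * (1 + params$irregularity_amp * s / k)
  } else {
    r_bound <- matrix(params$radius, size, size)
  }
  inside <- rho <= r_bound
  ring <- inside & (params$ring_width > 0) & (rho >= r_bound - params$ring_width)
  interior <- inside & !ring
  img[interior] <- params$interior_intensity
  img[ring] <- params$ring_intensity
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(size * size, 0, params$noise_sd), size, size)
  clamp(img, 0, 1)
}

#' Generate a two-group synthetic dataset
#'
#' Samples `n_per_group` cells from each group configuration and renders
#' them; the per-image generative parameters are retained so that
#' injected group differences can be recovered and checked downstream.
#'
#' @param control,treated [group_config()] objects.
#' @param n_per_group Number of cells per group (>= 1).
#' @param size Image side length in pixels.
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of it.
#' @return An object of class `synthetic_dataset`: list with `images`
#'   (list of [cell_image()]), `params` (data frame, one row per image),
#'   `labels` (character vector), `size` and `seed`.
#' @export
generate_dataset <- function(control, treated, n_per_group = 200, size = 64,
                             seed = 1L) {
  mv_assert(inherits(control, "group_config") && inherits(treated, "group_config"),
            "control and treated must be group_config objects")
  mv_assert(is_number(n_per_group) && n_per_group >= 1, "n_per_group must be >= 1")
  n_per_group <- as.integer(n_per_group)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  groups <- list(control, treated)
  images <- vector("list", 2L * n_per_group)
  labels <- character(2L * n_per_group)
  rows <- vector("list", 2L * n_per_group)
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      p <- sample_cell_params(g)
      px <- render_cell(p, size = size)
      id <- sprintf("%s_%04d", g$label, i)
      images[[idx]] <- cell_image(px, group = g$label, source_id = id,
                                  provenance = "synthetic")
      labels[idx] <- g$label
      rows[[idx]] <- data.frame(source_id = id, label = g$label,
                                as.list(unclass(p)[morph_factor_names()]),
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(images = images, params = do.call(rbind, rows),
                 labels = labels, size = as.integer(size),
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset n=%d (%s) size=%dpx seed=%d>\n",
              length(x$images),
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              x$size, x$seed))
  invisible(x)
}

#' Analytic injected effect size of one generative factor
#'
#' Standardized mean difference between the two group distributions of a
#' factor, `(mu_treated - mu_control) / sqrt((sd_c^2 + sd_t^2) / 2)`,
#' ignoring range clipping. This is the ground-truth Cohen's d that the
#' empirical per-factor d estimated from a generated dataset converges to.
#'
#' @param control,treated [group_config()] objects.
#' @param factor Factor name (one of the [morph_params()] fields).
#' @return The injected effect size (a number).
#' @export
injected_effect_size <- function(control, treated, factor) {
  mv_assert(factor %in% morph_factor_names(),
            sprintf("unknown factor '%s'", factor))
  mu_c <- control$means[[factor]]; mu_t <- treated$means[[factor]]
  s_c <- control$sds[[factor]]; s_t <- treated$sds[[factor]]
  mv_assert(s_c > 0 || s_t > 0,
            sprintf("effect size undefined for '%s': both sds are zero", factor),
            class = "morphovae_degenerate_error")
  (mu_t - mu_c) / sqrt((s_c^2 + s_t^2) / 2)
}

#' Write a synthetic dataset to disk
#'
#' One 8-bit grayscale PNG per cell under `dir/<group>/`, a `params.csv`
#' with per-image generative factors and labels, and the generating
#' configuration as `config.yaml`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  mv_assert(inherits(dataset, "synthetic_dataset"), "not a synthetic_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mv_assert(dir.exists(dir), sprintf("cannot create directory %s", dir),
            "morphovae_io_error")
  files <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    sub <- file.path(dir, im$group)
    dir.create(sub, showWarnings = FALSE)
    files[i] <- file.path(im$group, paste0(im$source_id, ".png"))
    write_image(im, file.path(dir, files[i]))
  }
  tab <- cbind(dataset$params, file = files)
  write.csv(tab, file.path(dir, "params.csv"), row.names = FALSE)
  yaml::write_yaml(list(size = dataset$size, seed = dataset$seed,
                        n = length(dataset$images)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a dataset previously written by [write_dataset()]
#'
#' @param dir Dataset directory containing `params.csv` and the PNGs.
#' @return A `synthetic_dataset` (pixel values re-quantized to 8 bits).
#' @export
load_dataset <- function(dir) {
  pfile <- file.path(dir, "params.csv")
  mv_assert(file.exists(pfile), sprintf("no params.csv in %s", dir),
            "morphovae_io_error")
  tab <- read.csv(pfile, stringsAsFactors = FALSE)
  images <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    px <- read_image(file.path(dir, tab$file[i]))
    images[[i]] <- cell_image(px, group = tab$label[i],
                              source_id = tab$source_id[i],
                              provenance = "loaded")
  }
  size <- if (nrow(tab) > 0) nrow(images[[1]]$pixels) else NA_integer_
  cfg <- file.path(dir, "config.yaml")
  seed <- if (file.exists(cfg)) yaml::read_yaml(cfg)$seed else NA_integer_
  structure(list(images = images,
                 params = tab[, setdiff(names(tab), "file")],
                 labels = tab$label, size = size, seed = seed),
            class = "synthetic_dataset")
}

# Internal: save/restore the global RNG state so seeded generators do not
# disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
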