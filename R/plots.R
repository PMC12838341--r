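# Figure writers for the evaluation outputs (base graphics, PNG device).
# These mirror the standard presentation of the analysis: a forest plot
# of per-dimension effect sizes, KDE curves for high/low-effect
# dimensions, violin plots for the top dimensions, traversal strips and
# difference-map panels.

#' Forest plot of per-dimension effect sizes
#'
#' @param table An [effect_size_table()].
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_forest <- function(table, path, width = 900, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  L <- nrow(table)
  ord <- order(table$dimension)
  tab <- table[ord, ]
  plot(tab$d, seq_len(L), xlim = range(c(tab$ci_low, tab$ci_high, 0)),
       pch = 19, ylab = "latent dimension", xlab = "Cohen's d (treated - control)",
       yaxt = "n", main = "Per-dimension effect sizes (95% CI)")
  axis(2, at = seq_len(L), labels = paste0("z_", tab$dimension), las = 1,
       cex.axis = 0.7)
  segments(tab$ci_low, seq_len(L), tab$ci_high, seq_len(L))
  abline(v = 0, lty = 2, col = "gray40")
  invisible(path)
}

#' KDE comparison plot for one latent dimension
#'
#' @param curve_control,curve_treated `density_curve` objects.
#' @param path Output PNG path.
#' @param label Panel title (e.g. the dimension name).
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_kde <- function(curve_control, curve_treated, path, label = "",
                     width = 700, height = 500) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  xr <- range(c(curve_control$grid, curve_treated$grid))
  yr <- c(0, max(curve_control$density, curve_treated$density))
  plot(NA, xlim = xr, ylim = yr, xlab = "latent value", ylab = "density",
       main = paste("KDE", label))
  lines(curve_control$grid, curve_control$density, col = "steelblue", lwd = 2)
  lines(curve_treated$grid, curve_treated$density, col = "firebrick", lwd = 2)
  legend("topright", legend = c("control", "treated"),
         col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(path)
}

#' Violin plot for selected latent dimensions
#'
#' White dot = median, thick bar = interquartile range, outline = KDE of
#' the group's values.
#'
#' @param latents A `latent_matrix`.
#' @param dims 0-based dimension indices to show.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_violin <- function(latents, dims, path, width = 900, height = 500) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  groups <- c("control", "treated")
  cols <- c(control = "steelblue", treated = "firebrick")
  n <- length(dims)
  all_v <- latents$values[, dims + 1L, drop = FALSE]
  plot(NA, xlim = c(0.5, n + 0.5), ylim = range(all_v),
       xaxt = "n", xlab = "", ylab = "latent value",
       main = "Top-ranked latent dimensions")
  axis(1, at = seq_len(n), labels = paste0("z_", dims))
  for (i in seq_len(n)) {
    for (gi in 1:2) {
      v <- latents$values[latents$labels == groups[gi], dims[i] + 1L]
      if (sd(v) == 0) next
      cv <- kde(v)
      w <- 0.18 * cv$density / max(cv$density)
      xc <- i + ifelse(gi == 1, -0.2, 0.2)
      polygon(c(xc - w, rev(xc + w)), c(cv$grid, rev(cv$grid)),
              col = grDevices::adjustcolor(cols[gi], alpha.f = 0.5),
              border = cols[gi])
      vs <- violin_summary(v)
      segments(xc, vs$q1, xc, vs$q3, lwd = 3)
      points(xc, vs$median, pch = 21, bg = "white")
    }
  }
  legend("topright", legend = groups, fill = cols, bty = "n")
  invisible(path)
}

#' Write a traversal strip as one PNG image
#'
#' Concatenates the decoded images horizontally with 2-pixel separators.
#'
#' @param result A `traversal_result`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_traversal_strip <- function(result, path) {
  mv_assert(inherits(result, "traversal_result"), "not a traversal_result")
  sep <- matrix(1, nrow(result$images[[1]]), 2)
  pieces <- list()
  for (i in seq_along(result$images)) {
    pieces[[length(pieces) + 1L]] <- result$images[[i]]
    if (i < length(result$images)) pieces[[length(pieces) + 1L]] <- sep
  }
  write_image(do.call(cbind, pieces), path)
}

#' Write the panels of a difference map as PNGs
#'
#' Writes `<prefix>_abs.png` (absolute map, rescaled to \[0, 1\]),
#' `<prefix>_ssim.png` (dissimilarity) and `<prefix>_mask.png`.
#'
#' @param map A `difference_map` (one element of a
#'   [difference_report()]'s `maps`).
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_difference_maps <- function(map, prefix) {
  mv_assert(inherits(map, "difference_map"), "not a difference_map")
  p1 <- paste0(prefix, "_abs.png")
  p2 <- paste0(prefix, "_ssim.png")
  p3 <- paste0(prefix, "_mask.png")
  mx <- max(map$absolute)
  write_image(if (mx > 0) map$absolute / mx else map$absolute, p1)
  write_image(clamp(map$ssim_dissimilarity / max(max(map$ssim_dissimilarity), 1e-12), 0, 1), p2)
  write_image(map$mask * 1, p3)
  invisible(c(p1, p2, p3))
}
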