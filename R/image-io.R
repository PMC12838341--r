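#' Single-cell image container
#'
#' A `cell_image` wraps one grayscale image (a numeric matrix with values in
#' \[0, 1\]) together with its group label, a source identifier, and the list
#' of processing stages it has passed through.
#'
#' @param pixels Numeric matrix in \[0, 1\] (rows = image rows).
#' @param group Group label, one of the two configured groups
#'   (conventionally `"control"` / `"treated"`).
#' @param source_id Character identifier of the image's origin.
#' @param provenance Character vector of applied processing stages.
#'
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(pixels, group = NA_character_, source_id = "",
                       provenance = character()) {
  mv_assert(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  mv_assert(all(is.finite(pixels)), "pixels must be finite")
  structure(
    list(pixels = pixels, group = as.character(group),
         source_id = as.character(source_id),
         provenance = as.character(provenance)),
    class = "cell_image"
  )
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image %dx%d group=%s id=%s stages=[%s]>\n",
              nrow(x$pixels), ncol(x$pixels), x$group, x$source_id,
              paste(x$provenance, collapse = ",")))
  invisible(x)
}

# Internal: accept a cell_image or a bare matrix, return the pixel matrix.
as_pixels <- function(image) {
  if (inherits(image, "cell_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  if (is.array(image) && is.numeric(image)) return(image)
  mv_stop("expected a cell_image, numeric matrix, or numeric array")
}

#' Read a grayscale image from a PNG file
#'
#' Multi-channel PNGs are collapsed with [to_grayscale()]. Values are
#' returned in \[0, 1\].
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  mv_assert(file.exists(path), sprintf("no such file: %s", path), "morphovae_io_error")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(img)[3] == 2L) img <- img[, , 1L, drop = TRUE]    # gray+alpha
  }
  to_grayscale(img)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param pixels `cell_image` or numeric matrix; values are clipped to \[0, 1\]
#'   and quantized to 8 bits.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  m <- clamp(as_pixels(pixels), 0, 1)
  m <- round(m * 255) / 255
  png::writePNG(m, target = path)
  invisible(path)
}
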