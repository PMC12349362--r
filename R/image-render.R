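#' Render a calibrated cross-section image from a contour
#'
#' Draws the slice as a filled tissue band whose upper boundary is the
#' contour, on a pixel grid with a known physical calibration. Foreground
#' (`TRUE` / intensity 1) is tissue. Image row 1 is the top of the picture
#' and larger physical `y` points outward (towards the top), so the traced
#' epidermis is the first foreground pixel from the top of each column.
#'
#' @param contour Contour data frame (`x_mm`, `y_mm`) with strictly
#'   increasing `x` (graph-like).
#' @param px_per_mm Pixel calibration; at least 10 px/mm.
#' @param band_height_mm Tissue thickness rendered below the lowest contour
#'   point, mm.
#' @param margin_mm Background margin rendered above the highest contour
#'   point, mm.
#' @return An object of class `section_image`: list with `pixels` (logical
#'   matrix, row 1 = top), `px_per_mm`, `x0_mm` and `y_top_mm` (physical
#'   coordinates of the grid origin).
#' @examples
#' img <- render_section_image(generate_contour(wave_profile(0.3, 5), 0.05),
#'                             px_per_mm = 20)
#' dim(img$pixels)
#' @export
render_section_image <- function(contour, px_per_mm, band_height_mm = 5,
                                 margin_mm = 1) {
  contour <- validate_contour(contour)
  check_finite_scalar(px_per_mm, "px_per_mm", positive = TRUE)
  if (px_per_mm < 10) {
    stop_rugosity("`px_per_mm` must be >= 10 for a usable rendering.",
                  "rugosity_invalid_parameter")
  }
  check_finite_scalar(band_height_mm, "band_height_mm", positive = TRUE)
  if (any(diff(contour$x_mm) <= 0)) {
    stop_rugosity("Contour is not graph-like (x must be strictly increasing) and cannot be rendered.",
                  "rugosity_render_error")
  }
  x0 <- contour$x_mm[1]
  span <- contour$x_mm[nrow(contour)] - x0
  width <- max(2L, round(span * px_per_mm))
  y_top <- max(contour$y_mm) + margin_mm
  y_bottom <- min(contour$y_mm) - band_height_mm
  height <- max(2L, ceiling((y_top - y_bottom) * px_per_mm))

  x_centers <- x0 + (seq_len(width) - 0.5) / px_per_mm
  y_boundary <- stats::approx(contour$x_mm, contour$y_mm, xout = x_centers,
                              rule = 2)$y
  y_centers <- y_top - (seq_len(height) - 0.5) / px_per_mm
  # pixel is tissue iff its centre lies at or below the boundary
  pixels <- outer(y_centers, y_boundary, FUN = "<=")

  structure(
    list(pixels = pixels, px_per_mm = px_per_mm,
         x0_mm = x0, y_top_mm = y_top),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px at %g px/mm (%.1f x %.1f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$px_per_mm,
              ncol(x$pixels) / x$px_per_mm, nrow(x$pixels) / x$px_per_mm))
  invisible(x)
}

#' Write / read a section image as PNG with a JSON calibration sidecar
#'
#' The image is stored as an 8-bit grayscale PNG (tissue = white) and the
#' calibration as `<path>.json` holding `px_per_mm` plus the physical grid
#' origin, so a round trip preserves the coordinate frame.
#'
#' @param image A `section_image`.
#' @param path Output PNG path.
#' @return `write_section_image()` returns `path` invisibly;
#'   `read_section_image()` returns a `section_image` (pixels numeric in
#'   `[0, 1]`).
#' @export
write_section_image <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  png::writePNG(image$pixels * 1, target = path)
  jsonlite::write_json(
    list(px_per_mm = image$px_per_mm, x0_mm = image$x0_mm,
         y_top_mm = image$y_top_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_image
#' @export
read_section_image <- function(path) {
  pixels <- png::readPNG(path)
  if (length(dim(pixels)) == 3L) pixels <- pixels[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(pixels = pixels, px_per_mm = meta$px_per_mm,
         x0_mm = meta$x0_mm %||% 0, y_top_mm = meta$y_top_mm %||% 0),
    class = "section_image"
  )
}
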