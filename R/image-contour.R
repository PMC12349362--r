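#' Binarize a grayscale section image
#'
#' Thresholds the pixel grid under the tissue-is-foreground convention.
#' `method = "otsu"` picks the threshold maximising between-class variance
#' (via \pkg{EBImage} when installed, otherwise an exhaustive histogram
#' scan); `method = "fixed"` uses the supplied threshold. A binary input is
#' unchanged by `fixed(0.5)`.
#'
#' @param image A `section_image` or a numeric/logical matrix with
#'   intensities in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold in `[0, 1]` for `method = "fixed"`; pixels with
#'   intensity >= threshold become foreground.
#' @return A `section_image` whose `pixels` are logical, with attributes
#'   `method` and `threshold` recording what was applied.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  img <- as_section_image(image)
  px <- img$pixels
  if (is.logical(px)) px <- px * 1
  if (!all(is.finite(px))) {
    stop_rugosity("Image intensities must be finite.",
                  "rugosity_invalid_parameter")
  }
  t <- if (method == "otsu") otsu_threshold(px) else {
    check_finite_scalar(threshold, "threshold")
    threshold
  }
  mask <- px >= t
  if (all(mask) || !any(mask)) {
    stop_rugosity("Degenerate image: binarization gives an all-foreground or all-background mask.",
                  "rugosity_degenerate_image")
  }
  img$pixels <- mask
  attr(img, "method") <- method
  attr(img, "threshold") <- t
  img
}

as_section_image <- function(image, px_per_mm = NULL) {
  if (inherits(image, "section_image")) return(image)
  if (is.matrix(image)) {
    if (is.null(px_per_mm)) {
      stop_rugosity("A bare matrix needs `px_per_mm`.",
                    "rugosity_invalid_parameter")
    }
    return(structure(list(pixels = image, px_per_mm = px_per_mm,
                          x0_mm = 0, y_top_mm = 0),
                     class = "section_image"))
  }
  stop_rugosity("`image` must be a section_image or a matrix.",
                "rugosity_invalid_parameter")
}

otsu_threshold <- function(px, levels = 256L) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    rng <- range(px)
    if (rng[1] == rng[2]) {
      stop_rugosity("Degenerate image: constant intensity.",
                    "rugosity_degenerate_image")
    }
    return(EBImage::otsu(EBImage::Image(px), range = rng, levels = levels))
  }
  # exhaustive scan over candidate thresholds maximising between-class variance
  rng <- range(px)
  if (rng[1] == rng[2]) {
    stop_rugosity("Degenerate image: constant intensity.",
                  "rugosity_degenerate_image")
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(px, breaks, rightmost.closed = TRUE), levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1L]
}

#' Trace the outer (upper) epidermal boundary of a binary mask
#'
#' For every pixel column the uppermost foreground pixel is located and
#' converted to physical coordinates with a half-pixel offset (the boundary
#' is taken at the top edge of the first tissue pixel, the unbiased estimate
#' under pixel quantization). When the stored pixels are grayscale, the
#' 0.5-intensity crossing between the last background and first foreground
#' pixel is linearly interpolated instead. Columns with no foreground are
#' filled by linear interpolation provided the gap is at most `max_gap_px`
#' columns wide. Endpoint columns are extended to the full image span so the
#' traced contour covers the whole section.
#'
#' @param mask A binarized `section_image` (or output of
#'   [render_section_image()]).
#' @param max_gap_px Widest run of empty columns to gap-fill.
#' @return A contour tibble (`x_mm`, `y_mm`), ordered left to right, with
#'   larger `y` pointing outward.
#' @export
trace_upper_boundary <- function(mask, max_gap_px = 3) {
  img <- as_section_image(mask)
  px <- img$pixels
  grayscale <- !is.logical(px)
  fg <- if (grayscale) px >= 0.5 else px
  p <- img$px_per_mm
  ncol_img <- ncol(fg)

  top_row <- apply(fg, 2, function(col) {
    i <- which(col)
    if (length(i) == 0L) NA_integer_ else i[1]
  })

  if (all(is.na(top_row))) {
    stop_rugosity("No foreground pixels found in any column.",
                  "rugosity_broken_boundary")
  }
  if (anyNA(top_row)) {
    gaps <- rle(is.na(top_row))
    if (any(gaps$lengths[gaps$values] > max_gap_px)) {
      stop_rugosity(sprintf("Boundary broken: empty-column gap wider than max_gap_px = %d.",
                            max_gap_px),
                    "rugosity_broken_boundary")
    }
    if (is.na(top_row[1]) || is.na(top_row[ncol_img])) {
      stop_rugosity("Boundary broken: empty column at the image edge cannot be interpolated.",
                    "rugosity_broken_boundary")
    }
  }

  # boundary y at each column, in image rows (subpixel)
  row_sub <- vapply(seq_len(ncol_img), function(j) {
    r <- top_row[j]
    if (is.na(r)) return(NA_real_)
    if (grayscale && r > 1L) {
      below <- px[r, j]      # foreground intensity
      above <- px[r - 1L, j] # background intensity
      if (below > above) {
        # linear 0.5-crossing between the two pixel centres
        frac <- (0.5 - above) / (below - above) # in (0, 1]
        return(r - 1.5 + frac)
      }
    }
    r - 1L # top edge of the first foreground pixel (half-pixel offset)
  }, numeric(1))

  x <- img$x0_mm + (seq_len(ncol_img) - 0.5) / p
  y <- img$y_top_mm - row_sub / p
  if (anyNA(y)) {
    keep <- !is.na(y)
    y <- stats::approx(x[keep], y[keep], xout = x)$y
  }
  # extend half a pixel on both sides so the contour spans the full section
  x <- c(img$x0_mm, x, img$x0_mm + ncol_img / p)
  y <- c(y[1], y, y[length(y)])
  as_contour(tibble(x_mm = x, y_mm = y))
}

#' Smooth and resample a contour at fixed arc-length spacing
#'
#' Applies a centred moving average to `y` over a physical window (in mm),
#' then resamples the polyline at a fixed spacing along its arc length.
#' Endpoints are preserved exactly by both steps. Smoothing controls the
#' coastline effect: pixel-level jitter inflates the measured arc length,
#' and averaging over a window small relative to the ridge wavelength but
#' large relative to the pixel size removes most of that inflation.
#'
#' @param contour Contour data frame (`x_mm`, `y_mm`).
#' @param spacing_mm Arc-length resampling interval, mm; `NULL` skips
#'   resampling.
#' @param smooth_window_mm Moving-average window, mm; 0 skips smoothing.
#' @return A contour tibble.
#' @export
resample_smooth <- function(contour, spacing_mm = 0.1, smooth_window_mm = 0.5) {
  contour <- validate_contour(contour)
  check_finite_scalar(smooth_window_mm, "smooth_window_mm", non_negative = TRUE)
  x <- contour$x_mm
  y <- contour$y_mm
  n <- length(x)

  if (smooth_window_mm > 0 && n > 2L) {
    dx <- stats::median(abs(diff(x)))
    half <- floor(smooth_window_mm / (2 * dx))
    if (half >= 1L) {
      cs <- cumsum(c(0, y))
      idx <- seq_len(n)
      lo <- pmax(idx - half, 1L)
      hi <- pmin(idx + half, n)
      y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      y[1] <- contour$y_mm[1]
      y[n] <- contour$y_mm[n]
    }
  }

  if (!is.null(spacing_mm)) {
    check_finite_scalar(spacing_mm, "spacing_mm", positive = TRUE)
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    total <- s[length(s)]
    if (spacing_mm >= total) {
      stop_rugosity("`spacing_mm` exceeds the contour's arc length.",
                    "rugosity_invalid_parameter")
    }
    targets <- seq(0, total, by = spacing_mm)
    if (targets[length(targets)] != total) targets <- c(targets, total)
    x <- stats::approx(s, x, xout = targets, ties = "ordered")$y
    y <- stats::approx(s, y, xout = targets, ties = "ordered")$y
    x[1] <- contour$x_mm[1]
    x[length(x)] <- contour$x_mm[n]
  }
  as_contour(tibble(x_mm = x, y_mm = y))
}

#' Extract a physical-unit epidermal contour from a calibrated image
#'
#' End-to-end extraction pipeline: [binarize()] (skipped when the pixels are
#' already logical), [trace_upper_boundary()], then [resample_smooth()].
#' Defaults (0.5 mm smoothing window, 0.1 mm spacing) are small relative to
#' the ridge wavelengths of rugose fruit and large relative to pixel noise
#' at 20 px/mm and above.
#'
#' @param image A `section_image`.
#' @param method,threshold Passed to [binarize()].
#' @param max_gap_px Passed to [trace_upper_boundary()].
#' @param spacing_mm,smooth_window_mm Passed to [resample_smooth()].
#' @return A contour tibble (`x_mm`, `y_mm`).
#' @examples
#' p <- wave_profile(0.3, 5)
#' img <- render_section_image(generate_contour(p, 0.02), px_per_mm = 40)
#' cont <- extract_contour(img)
#' slice_ri(cont)
#' @export
extract_contour <- function(image, method = "otsu", threshold = 0.5,
                            max_gap_px = 3, spacing_mm = 0.1,
                            smooth_window_mm = 0.5) {
  img <- as_section_image(image)
  if (!is.logical(img$pixels)) {
    img <- binarize(img, method = method, threshold = threshold)
  }
  cont <- trace_upper_boundary(img, max_gap_px = max_gap_px)
  resample_smooth(cont, spacing_mm = spacing_mm,
                  smooth_window_mm = smooth_window_mm)
}
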