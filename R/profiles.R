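#' Parametric wavy epidermal profiles
#'
#' A `wave_profile` describes the outer epidermal contour of one longitudinal
#' fruit-section slice as a graph-like curve
#' \eqn{y(x) = \sum_j a_j \sin(2\pi x/\lambda_j + \phi_j)} on
#' \eqn{x \in [0, L]}, with optional i.i.d. Gaussian jitter added to `y` only.
#' The default section length is 30 mm (a 3 cm slice excised at the fruit
#' equator). A single harmonic is the canonical profile because its arc
#' length has an independent quadrature oracle ([true_ri_quadrature()]);
#' supplying vectors builds a composite multi-harmonic profile for
#' robustness checks.
#'
#' Each amplitude must be strictly smaller than its wavelength so that the
#' profile stays graph-like (single-valued in `x`).
#'
#' @param amplitude_mm Non-negative amplitude(s), mm.
#' @param wavelength_mm Positive wavelength(s), mm.
#' @param section_length_mm Section length `L`, mm. Default 30.
#' @param phase_rad Phase offset(s), radians. Recycled to match the number of
#'   harmonics.
#' @param noise_sd_mm Standard deviation of Gaussian y-jitter, mm. With 0 the
#'   profile is deterministic.
#' @param seed Integer seed used when `noise_sd_mm > 0`; `NULL` uses the
#'   current RNG stream.
#'
#' @return An object of class `wave_profile`.
#' @examples
#' wave_profile(amplitude_mm = 0.3, wavelength_mm = 5)
#' @export
wave_profile <- function(amplitude_mm, wavelength_mm, section_length_mm = 30,
                         phase_rad = 0, noise_sd_mm = 0, seed = NULL) {
  if (!all(is.finite(c(amplitude_mm, wavelength_mm, section_length_mm,
                       phase_rad, noise_sd_mm)))) {
    stop_rugosity("All profile parameters must be finite.",
                  "rugosity_invalid_parameter")
  }
  check_finite_scalar(section_length_mm, "section_length_mm", positive = TRUE)
  check_finite_scalar(noise_sd_mm, "noise_sd_mm", non_negative = TRUE)
  if (length(amplitude_mm) != length(wavelength_mm)) {
    stop_rugosity("`amplitude_mm` and `wavelength_mm` must have equal length.",
                  "rugosity_invalid_parameter")
  }
  if (any(wavelength_mm <= 0)) {
    stop_rugosity("`wavelength_mm` must be > 0.", "rugosity_invalid_parameter")
  }
  if (any(amplitude_mm < 0)) {
    stop_rugosity("`amplitude_mm` must be >= 0.", "rugosity_invalid_parameter")
  }
  if (any(amplitude_mm >= wavelength_mm)) {
    stop_rugosity("Each `amplitude_mm` must be < its `wavelength_mm` (graph-like profile).",
                  "rugosity_invalid_parameter")
  }
  phase_rad <- rep_len(phase_rad, length(amplitude_mm))
  structure(
    list(
      section_length_mm = section_length_mm,
      amplitude_mm = as.numeric(amplitude_mm),
      wavelength_mm = as.numeric(wavelength_mm),
      phase_rad = as.numeric(phase_rad),
      noise_sd_mm = noise_sd_mm,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "wave_profile"
  )
}

#' @export
print.wave_profile <- function(x, ...) {
  cat(sprintf(
    "<wave_profile> L = %g mm, %d harmonic(s), noise sd = %g mm\n",
    x$section_length_mm, length(x$amplitude_mm), x$noise_sd_mm))
  for (j in seq_along(x$amplitude_mm)) {
    cat(sprintf("  a = %g mm, lambda = %g mm, phase = %g rad\n",
                x$amplitude_mm[j], x$wavelength_mm[j], x$phase_rad[j]))
  }
  invisible(x)
}

profile_y <- function(profile, x) {
  y <- numeric(length(x))
  for (j in seq_along(profile$amplitude_mm)) {
    y <- y + profile$amplitude_mm[j] *
      sin(2 * pi * x / profile$wavelength_mm[j] + profile$phase_rad[j])
  }
  y
}

profile_dy <- function(profile, x) {
  d <- numeric(length(x))
  for (j in seq_along(profile$amplitude_mm)) {
    w <- 2 * pi / profile$wavelength_mm[j]
    d <- d + profile$amplitude_mm[j] * w *
      cos(w * x + profile$phase_rad[j])
  }
  d
}

#' Sample a contour polyline from a wave profile
#'
#' Evaluates the profile on a regular grid from `x = 0` to the section length
#' (both endpoints exactly included), adding Gaussian jitter to `y` when the
#' profile carries noise. The result is an ordered open polyline in mm, the
#' in-memory form of a traced epidermal contour.
#'
#' @param profile A [wave_profile()].
#' @param spacing_mm Sampling interval along `x`, mm. Must be positive and at
#'   most a quarter of the shortest wavelength so the waveform is resolved.
#'
#' @return A tibble with columns `x_mm`, `y_mm` (class `rugosity_contour`).
#' @examples
#' p <- wave_profile(0.5, 5)
#' head(generate_contour(p, spacing_mm = 0.05))
#' @export
generate_contour <- function(profile, spacing_mm) {
  stopifnot(inherits(profile, "wave_profile"))
  check_finite_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  if (spacing_mm > min(profile$wavelength_mm) / 4) {
    stop_rugosity("`spacing_mm` must be <= wavelength/4 to resolve the waveform.",
                  "rugosity_invalid_parameter")
  }
  L <- profile$section_length_mm
  x <- seq(0, L, by = spacing_mm)
  if (x[length(x)] != L) x <- c(x, L)
  y <- profile_y(profile, x)
  if (profile$noise_sd_mm > 0) {
    y <- y + with_seed_or_not(profile$seed,
                              rnorm(length(x), sd = profile$noise_sd_mm))
  }
  as_contour(tibble(x_mm = x, y_mm = y))
}

as_contour <- function(df) {
  out <- as_tibble(df)
  class(out) <- c("rugosity_contour", class(out))
  out
}

#' Rugosity index of an analytic profile by adaptive quadrature
#'
#' Independent oracle for the rugosity index of a noise-free wave profile:
#' \deqn{RI = 100 \left(\int_0^L \sqrt{1 + y'(x)^2}\,dx - L\right)/L}
#' computed by adaptive numerical quadrature to a relative tolerance of
#' 1e-9. Because it integrates the analytic derivative it is independent of
#' any polyline sampling and serves as the ground truth for contour-based
#' and image-based measurements.
#'
#' @param profile A noise-free [wave_profile()].
#' @return Rugosity index, percent.
#' @examples
#' true_ri_quadrature(wave_profile(0.5, 5))
#' @export
true_ri_quadrature <- function(profile) {
  stopifnot(inherits(profile, "wave_profile"))
  if (profile$noise_sd_mm > 0) {
    stop_rugosity("Quadrature oracle is defined for deterministic profiles only (noise_sd_mm = 0).",
                  "rugosity_unsupported")
  }
  L <- profile$section_length_mm
  arc <- integrate(function(x) sqrt(1 + profile_dy(profile, x)^2),
                   lower = 0, upper = L,
                   rel.tol = 1e-9, subdivisions = 2000L)$value
  100 * (arc - L) / L
}

#' Choose a sinusoid amplitude that attains a target rugosity index
#'
#' Inverts [true_ri_quadrature()] for a single-harmonic profile by bisection
#' on the amplitude. Useful for building test images whose true RI is chosen
#' in advance.
#'
#' @param ri_percent Target rugosity index, percent (>= 0).
#' @param wavelength_mm Wavelength of the sinusoid, mm.
#' @param section_length_mm Section length, mm.
#' @return Amplitude in mm.
#' @export
amplitude_for_ri <- function(ri_percent, wavelength_mm, section_length_mm = 30) {
  check_finite_scalar(ri_percent, "ri_percent", non_negative = TRUE)
  check_finite_scalar(wavelength_mm, "wavelength_mm", positive = TRUE)
  if (ri_percent == 0) return(0)
  f <- function(a) {
    true_ri_quadrature(wave_profile(a, wavelength_mm, section_length_mm)) -
      ri_percent
  }
  upper <- wavelength_mm * 0.49
  if (f(upper) < 0) {
    stop_rugosity("Target RI not attainable with a graph-like sinusoid at this wavelength.",
                  "rugosity_invalid_parameter")
  }
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}
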