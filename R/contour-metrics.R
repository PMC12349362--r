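#' Arc length of an ordered polyline
#'
#' Sums Euclidean segment lengths of the contour in the order given, the
#' digital analogue of reading a traced polyline's total length off a CAD
#' "LIST" query. No smoothing or resampling is applied here; see
#' [resample_smooth()] for coastline control on extracted contours.
#'
#' @param contour A data frame with columns `x_mm`, `y_mm` and at least two
#'   rows, ordered along the epidermis.
#' @return Length in mm. Always at least the endpoint chord length.
#' @examples
#' polyline_length(tibble::tibble(x_mm = c(0, 3), y_mm = c(0, 4)))
#' @export
polyline_length <- function(contour) {
  contour <- validate_contour(contour)
  sum(sqrt(diff(contour$x_mm)^2 + diff(contour$y_mm)^2))
}

validate_contour <- function(contour) {
  if (!is.data.frame(contour) ||
      !all(c("x_mm", "y_mm") %in% names(contour))) {
    stop_rugosity("A contour needs `x_mm` and `y_mm` columns.",
                  "rugosity_invalid_contour")
  }
  if (nrow(contour) < 2L) {
    stop_rugosity("A contour needs at least two points.",
                  "rugosity_invalid_contour")
  }
  if (!all(is.finite(contour$x_mm)) || !all(is.finite(contour$y_mm))) {
    stop_rugosity("Contour coordinates must be finite.",
                  "rugosity_invalid_contour")
  }
  contour
}

#' Rugosity index from epidermal and section lengths
#'
#' The rugosity index is the percent excess of the traced epidermal length
#' over the straight section length:
#' \deqn{RI(\%) = 100\,(\mathrm{epidermal} - \mathrm{section})/\mathrm{section}.}
#' A perfectly flat epidermis gives 0. A measured epidermal length slightly
#' below the section length can arise from tracing error; the (negative)
#' value is returned as-is with a warning so raw measurements are preserved.
#'
#' @param epidermal_length_mm Traced epidermal contour length, mm.
#' @param section_length_mm Straight section length, mm (> 0).
#' @param tolerance_mm Shortfall below which no tracing-error warning is
#'   raised.
#' @return Rugosity index, percent. Vectorised over both lengths.
#' @examples
#' rugosity_index(31.05, 30) # 3.5
#' @export
rugosity_index <- function(epidermal_length_mm, section_length_mm,
                           tolerance_mm = 1e-6) {
  if (!all(is.finite(epidermal_length_mm)) ||
      !all(is.finite(section_length_mm))) {
    stop_rugosity("Lengths must be finite.", "rugosity_invalid_parameter")
  }
  if (any(section_length_mm <= 0)) {
    stop_rugosity("`section_length_mm` must be > 0.",
                  "rugosity_invalid_parameter")
  }
  if (any(epidermal_length_mm < section_length_mm - tolerance_mm)) {
    warn_rugosity("Epidermal length below section length: possible tracing error; negative RI returned.",
                  "rugosity_tracing_warning")
  }
  100 * (epidermal_length_mm - section_length_mm) / section_length_mm
}

#' Measure the rugosity index of one slice contour
#'
#' Computes the epidermal length via [polyline_length()] and divides by a
#' section length taken either as the supplied nominal excision length
#' (default 30 mm, matching a 3 cm slice) or as the chord distance between
#' the contour's endpoints. Chord mode is the right choice when the excised
#' slice does not span the nominal length exactly.
#'
#' @param contour Contour data frame (`x_mm`, `y_mm`).
#' @param mode `"nominal"` (use `section_mm`) or `"chord"` (endpoint
#'   distance).
#' @param section_mm Nominal section length, mm; used in nominal mode.
#' @return One-row tibble: `epidermal_mm`, `section_mm`, `ri_percent`.
#' @examples
#' flat <- tibble::tibble(x_mm = c(0, 30), y_mm = c(0, 0))
#' slice_ri(flat)
#' @export
slice_ri <- function(contour, mode = c("nominal", "chord"), section_mm = 30) {
  mode <- match.arg(mode)
  contour <- validate_contour(contour)
  epidermal <- polyline_length(contour)
  section <- if (mode == "nominal") {
    check_finite_scalar(section_mm, "section_mm", positive = TRUE)
    section_mm
  } else {
    n <- nrow(contour)
    chord <- sqrt((contour$x_mm[n] - contour$x_mm[1])^2 +
                    (contour$y_mm[n] - contour$y_mm[1])^2)
    if (chord == 0) {
      stop_rugosity("Chord length is zero (closed contour); chord mode needs an open contour.",
                    "rugosity_invalid_contour")
    }
    chord
  }
  tibble(
    epidermal_mm = epidermal,
    section_mm = section,
    ri_percent = rugosity_index(epidermal, section)
  )
}

#' Rugosity level scheme
#'
#' Level boundaries (percent RI) separating the four ordinal rugosity
#' levels. The default boundaries 1.5 / 2.5 / 3.5 define Level 1 = [0, 1.5),
#' Level 2 = [1.5, 2.5), Level 3 = [2.5, 3.5), Level 4 = [3.5, Inf):
#' intervals are left-closed / right-open so every RI maps to exactly one
#' level and the top class is the only unbounded one.
#'
#' @param boundaries_percent Strictly increasing non-negative boundaries.
#' @return An object of class `level_scheme`.
#' @export
level_scheme <- function(boundaries_percent = c(1.5, 2.5, 3.5)) {
  if (!is.numeric(boundaries_percent) || length(boundaries_percent) < 1L ||
      !all(is.finite(boundaries_percent)) ||
      any(boundaries_percent < 0) ||
      is.unsorted(boundaries_percent, strictly = TRUE)) {
    stop_rugosity("`boundaries_percent` must be strictly increasing and >= 0.",
                  "rugosity_invalid_parameter")
  }
  structure(list(boundaries_percent = as.numeric(boundaries_percent)),
            class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  b <- x$boundaries_percent
  cat("<level_scheme>", length(b) + 1, "levels; boundaries at",
      paste0(b, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Classify rugosity index values into ordinal levels
#'
#' Assigns each RI to a level via the left-closed / right-open intervals of
#' the scheme (default: Level 1 for RI in [0, 1.5), ..., Level 4 for
#' RI >= 3.5). Negative RI values (possible from tracing error) are clamped
#' to 0 for classification, with a warning.
#'
#' @param ri_percent Numeric vector of rugosity indices, percent.
#' @param scheme A [level_scheme()].
#' @return Integer vector of levels in `1:(length(boundaries) + 1)`.
#' @examples
#' classify_level(c(0, 1.5, 3.49, 3.5))
#' @export
classify_level <- function(ri_percent, scheme = level_scheme()) {
  stopifnot(inherits(scheme, "level_scheme"))
  if (!is.numeric(ri_percent) || any(!is.finite(ri_percent))) {
    stop_rugosity("`ri_percent` must be finite.", "rugosity_invalid_parameter")
  }
  if (any(ri_percent < 0)) {
    warn_rugosity("Negative RI clamped to 0 for classification.",
                  "rugosity_clamp_warning")
    ri_percent <- pmax(ri_percent, 0)
  }
  b <- scheme$boundaries_percent
  findInterval(ri_percent, b, left.open = FALSE) + 1L
}

#' Aggregate slice measurements into a per-fruit rugosity call
#'
#' The per-fruit rugosity index is the arithmetic mean of its slice RIs
#' (four slices per fruit is the expected design; any other count raises a
#' warning but is still aggregated), then classified with the level scheme.
#'
#' @param slices Data frame of slice measurements with at least `ri_percent`;
#'   typically rows of [slice_ri()] output.
#' @param fruit_id Identifier recorded in the output.
#' @param scheme A [level_scheme()].
#' @return One-row tibble: `fruit_id`, `mean_ri_percent`, `level`,
#'   `n_slices`.
#' @examples
#' fruit_ri(tibble::tibble(ri_percent = c(1, 2, 3, 4)), fruit_id = "F1")
#' @export
fruit_ri <- function(slices, fruit_id = "fruit", scheme = level_scheme()) {
  if (!is.data.frame(slices) || !"ri_percent" %in% names(slices)) {
    stop_rugosity("`slices` must be a data frame with a `ri_percent` column.",
                  "rugosity_invalid_input")
  }
  if (nrow(slices) == 0L) {
    stop_rugosity("At least one slice measurement is required.",
                  "rugosity_invalid_input")
  }
  if (nrow(slices) != 4L) {
    warn_rugosity(sprintf("Expected 4 slices per fruit, got %d.", nrow(slices)),
                  "rugosity_slice_count_warning")
  }
  mean_ri <- mean(slices$ri_percent)
  tibble(
    fruit_id = fruit_id,
    mean_ri_percent = mean_ri,
    level = suppressWarnings(classify_level(mean_ri, scheme)),
    n_slices = nrow(slices)
  )
}

#' Measure and classify a batch of slice contours
#'
#' Convenience wrapper over [slice_ri()], [fruit_ri()] and
#' [classify_level()]: takes a table with one row per slice holding
#' list-column `contour`, groups by `fruit_id`, and returns the fruit-level
#' summary.
#'
#' @param manifest Data frame with columns `fruit_id`, `slice_id` and a
#'   list-column `contour` of contour data frames.
#' @inheritParams slice_ri
#' @param scheme A [level_scheme()].
#' @return Tibble with one row per fruit: `fruit_id`, `mean_ri_percent`,
#'   `level`, `n_slices`.
#' @export
measure_fruits <- function(manifest, mode = c("nominal", "chord"),
                           section_mm = 30, scheme = level_scheme()) {
  mode <- match.arg(mode)
  if (!all(c("fruit_id", "contour") %in% names(manifest))) {
    stop_rugosity("`manifest` needs `fruit_id` and `contour` columns.",
                  "rugosity_invalid_input")
  }
  slices <- manifest |>
    dplyr::mutate(measure = purrr::map(.data$contour, slice_ri,
                                       mode = mode, section_mm = section_mm)) |>
    tidyr::unnest("measure")
  slices |>
    dplyr::group_by(.data$fruit_id) |>
    dplyr::group_modify(function(df, key) {
      suppressWarnings(fruit_ri(df, fruit_id = key$fruit_id, scheme = scheme))[
        , c("mean_ri_percent", "level", "n_slices")]
    }) |>
    dplyr::ungroup()
}
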