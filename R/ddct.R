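#' Relative qPCR expression by the 2^-ddCt method
#'
#' For every gene x sample cell, technical-replicate Ct readings are
#' averaged on the Ct scale first; then
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}},
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}},
#' and relative expression is \eqn{2^{-\Delta\Delta Ct}}. The calibrator
#' sample therefore scores exactly 1 for every gene.
#'
#' @param ct Tibble with columns `gene`, `sample`, `replicate`,
#'   `ct_target`, `ct_reference` (e.g. from [generate_ct_table()] or
#'   [read_ct_csv()]).
#' @param calibrator Name of the calibrator sample; defaults to the
#'   `calibrator` attribute when present, else the first sample.
#' @return Tibble: `gene`, `sample`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expression`.
#' @examples
#' ct <- generate_ct_table(1, 2, true_log2_ratios = c(0, 2))
#' delta_delta_ct(ct) # calibrator 1.0, second sample 4.0
#' @export
delta_delta_ct <- function(ct, calibrator = NULL) {
  needed <- c("gene", "sample", "ct_target", "ct_reference")
  if (!is.data.frame(ct) || !all(needed %in% names(ct))) {
    stop_rugosity("`ct` needs columns gene, sample, ct_target, ct_reference.",
                  "rugosity_invalid_input")
  }
  if (anyNA(ct$ct_reference) || !all(is.finite(ct$ct_reference))) {
    bad <- unique(ct$sample[!is.finite(ct$ct_reference)])
    stop_rugosity(paste0("Missing reference-gene Ct for sample(s): ",
                         paste(bad, collapse = ", ")),
                  "rugosity_missing_reference")
  }
  if (!all(is.finite(ct$ct_target)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    stop_rugosity("Ct values must be finite and positive.",
                  "rugosity_invalid_input")
  }
  calibrator <- calibrator %||% attr(ct, "calibrator") %||% ct$sample[1]
  if (!calibrator %in% ct$sample) {
    stop_rugosity(sprintf("Calibrator sample '%s' not present.", calibrator),
                  "rugosity_invalid_input")
  }
  per_cell <- ct |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(ct_target = mean(.data$ct_target),
                     ct_reference = mean(.data$ct_reference),
                     .groups = "drop") |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_reference)
  cal <- per_cell |>
    dplyr::filter(.data$sample == calibrator) |>
    dplyr::select("gene", cal_delta_ct = "delta_ct")
  missing_cal <- setdiff(unique(per_cell$gene), cal$gene)
  if (length(missing_cal)) {
    stop_rugosity(paste0("Calibrator Ct missing for gene(s): ",
                         paste(missing_cal, collapse = ", ")),
                  "rugosity_invalid_input")
  }
  per_cell |>
    dplyr::left_join(cal, by = "gene") |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct - .data$cal_delta_ct,
                  rel_expression = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("gene", "sample", "delta_ct", "delta_delta_ct",
                  "rel_expression")
}
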