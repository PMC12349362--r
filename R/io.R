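#' Read and write the package's plain-text data dialects
#'
#' Contours: CSV with header `x_mm,y_mm`, one ordered point per row.
#' Phenotypes: CSV `fruit_id,ri_percent,sensory_level,RF,...,PME` (empty
#' fields allowed for missing values; ground-truth columns such as
#' `true_level` are not part of the dialect and are dropped on write).
#' Counts: TSV with `gene_id`, `gene_length_bp`, then one column per
#' sample named `<genotype><stage>_r<rep>`.
#' Ct tables: CSV `gene,sample,replicate,ct_target,ct_reference`.
#'
#' @param path File path.
#' @param contour,table,counts,ct Object to write.
#' @name rugosity-io
NULL

#' @rdname rugosity-io
#' @export
read_contour_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    x_mm = readr::col_double(), y_mm = readr::col_double()))
  as_contour(validate_contour(df))
}

#' @rdname rugosity-io
#' @export
write_contour_csv <- function(contour, path) {
  readr::write_csv(validate_contour(contour)[, c("x_mm", "y_mm")], path)
  invisible(path)
}

phenotype_dialect_cols <- function() {
  c("fruit_id", "ri_percent", "sensory_level",
    default_indicator_profiles()$indicator)
}

#' @rdname rugosity-io
#' @export
read_phenotype_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    fruit_id = readr::col_character(),
    .default = readr::col_double()))
}

#' @rdname rugosity-io
#' @export
write_phenotype_csv <- function(table, path) {
  cols <- intersect(phenotype_dialect_cols(), names(table))
  readr::write_csv(table[, cols], path, na = "")
  invisible(path)
}

#' @rdname rugosity-io
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    gene_length_bp = readr::col_integer(),
    .default = readr::col_double()))
}

#' @rdname rugosity-io
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_counts_tbl(counts), path)
  invisible(path)
}

#' @rdname rugosity-io
#' @export
read_ct_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), sample = readr::col_character(),
    replicate = readr::col_integer(),
    ct_target = readr::col_double(), ct_reference = readr::col_double()))
}

#' @rdname rugosity-io
#' @export
write_ct_csv <- function(ct, path) {
  readr::write_csv(
    as_tibble(ct)[, c("gene", "sample", "replicate", "ct_target",
                      "ct_reference")],
    path)
  invisible(path)
}
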