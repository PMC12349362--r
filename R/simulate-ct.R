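#' Simulate a qPCR Ct table with known relative expression
#'
#' Builds per-gene, per-sample Ct values for a target gene and a shared
#' reference gene (the internal control, e.g. a ubiquitin gene) such that
#' relative quantification by [delta_delta_ct()] recovers the configured
#' log2 expression ratios exactly when `noise_sd_ct = 0`. The first sample
#' is the calibrator, so the first column of `true_log2_ratios` should be 0.
#'
#' Each extra cycle of the target Ct halves apparent expression, so a gene
#' expressed `2^r`-fold relative to the calibrator gets
#' `Ct_target = base - r` in that sample.
#'
#' @param n_genes,n_samples Table dimensions.
#' @param true_log2_ratios Numeric `n_genes x n_samples` matrix of log2
#'   expression ratios relative to the calibrator (recycled from a vector
#'   of length `n_samples` if needed). Default 0 everywhere.
#' @param n_replicates Technical replicates per gene x sample.
#' @param noise_sd_ct Gaussian noise sd added independently to every Ct
#'   reading, cycles.
#' @param reference_gene Name recorded for the internal control.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble of class `ct_table` with columns `gene`, `sample`,
#'   `replicate`, `ct_target`, `ct_reference`; the true ratio matrix is
#'   attached as attribute `truth` and the calibrator name as
#'   `calibrator`.
#' @examples
#' ct <- generate_ct_table(2, 3, true_log2_ratios = c(0, 1, 2))
#' delta_delta_ct(ct)
#' @export
generate_ct_table <- function(n_genes, n_samples, true_log2_ratios = 0,
                              n_replicates = 3, noise_sd_ct = 0,
                              reference_gene = "UBI", seed = NULL) {
  check_finite_scalar(n_genes, "n_genes", positive = TRUE)
  check_finite_scalar(n_samples, "n_samples", positive = TRUE)
  check_finite_scalar(n_replicates, "n_replicates", positive = TRUE)
  check_finite_scalar(noise_sd_ct, "noise_sd_ct", non_negative = TRUE)
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  ratios <- matrix(0, n_genes, n_samples)
  ratios[] <- if (is.matrix(true_log2_ratios)) true_log2_ratios else
    matrix(true_log2_ratios, n_genes, n_samples, byrow = TRUE)
  if (any(ratios[, 1] != 0)) {
    stop_rugosity("The first (calibrator) column of `true_log2_ratios` must be 0.",
                  "rugosity_invalid_parameter")
  }

  genes <- sprintf("TG%03d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  grid <- expand.grid(replicate = seq_len(as.integer(n_replicates)),
                      sample = seq_len(n_samples),
                      gene = seq_len(n_genes))
  base_ct <- 24 # arbitrary but fixed baseline cycle number
  with_seed_or_not(seed, {
    ct_target <- base_ct - ratios[cbind(grid$gene, grid$sample)] +
      rnorm(nrow(grid), sd = noise_sd_ct)
    ct_reference <- 20 + rnorm(nrow(grid), sd = noise_sd_ct)
    out <- tibble(
      gene = genes[grid$gene],
      sample = samples[grid$sample],
      replicate = grid$replicate,
      ct_target = ct_target,
      ct_reference = ct_reference
    )
    attr(out, "truth") <- `dimnames<-`(ratios, list(genes, samples))
    attr(out, "calibrator") <- samples[1]
    attr(out, "reference_gene") <- reference_gene
    class(out) <- c("ct_table", class(out))
    out
  })
}
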