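#' Configuration for a synthetic two-genotype RNA-seq count matrix
#'
#' Describes a 2 genotype (M = rugose, G = smooth) x 3 stage (6, 10, 14
#' days post-anthesis) x `n_replicates` design with negative-binomial
#' counts. A chosen number of genes is planted as differentially expressed
#' between genotypes at a fixed absolute log2 fold change (sign drawn per
#' gene), constant across stages; their identities and signed effects are
#' recorded so downstream detection can be scored against truth.
#'
#' @param n_genes Number of genes.
#' @param n_de Number of planted genotype-DE genes (<= `n_genes`).
#' @param log2fc_de Absolute log2 fold change of planted genes; must be
#'   >= 1.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_mean Expected column sum per sample.
#' @param gene_length_range_bp Integer range of simulated gene lengths, bp.
#' @param n_replicates Biological replicates per genotype x stage cell.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `counts_config`.
#' @export
counts_config <- function(n_genes = 2000, n_de = 100, log2fc_de = 2,
                          dispersion = 0.05, library_size_mean = 5e6,
                          gene_length_range_bp = c(500L, 5000L),
                          n_replicates = 3, seed = NULL) {
  check_finite_scalar(n_genes, "n_genes", positive = TRUE)
  check_finite_scalar(n_de, "n_de", non_negative = TRUE)
  if (n_de > n_genes) {
    stop_rugosity("`n_de` cannot exceed `n_genes`.",
                  "rugosity_invalid_parameter")
  }
  check_finite_scalar(log2fc_de, "log2fc_de")
  if (n_de > 0 && abs(log2fc_de) < 1) {
    stop_rugosity("`log2fc_de` must have |value| >= 1.",
                  "rugosity_invalid_parameter")
  }
  check_finite_scalar(dispersion, "dispersion", positive = TRUE)
  check_finite_scalar(library_size_mean, "library_size_mean", positive = TRUE)
  structure(
    list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
         log2fc_de = log2fc_de, dispersion = dispersion,
         library_size_mean = library_size_mean,
         gene_length_range_bp = as.integer(gene_length_range_bp),
         n_replicates = as.integer(n_replicates),
         genotypes = c("M", "G"), stages = c(6L, 10L, 14L),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "counts_config"
  )
}

#' Simulate a gene x sample count matrix with planted DE genes
#'
#' Gene baseline abundances are log-normal; sample means scale them to the
#' configured library size; planted DE genes multiply their mean in the M
#' genotype by `2^(signed log2fc)`; counts are negative-binomial with the
#' configured dispersion. Samples are named `<genotype><stage>_r<rep>`
#' (e.g. `M10_r2`).
#'
#' @param config A [counts_config()].
#' @return A list of class `sim_counts` with elements `counts` (tibble:
#'   `gene_id`, `gene_length_bp`, one column per sample) and `truth`
#'   (tibble: `gene_id`, `is_de`, `log2fc`).
#' @examples
#' sim <- generate_counts(counts_config(n_genes = 100, n_de = 5, seed = 1))
#' sim$counts[1:3, 1:4]
#' @export
generate_counts <- function(config = counts_config()) {
  stopifnot(inherits(config, "counts_config"))
  with_seed_or_not(config$seed, {
    ng <- config$n_genes
    gene_id <- sprintf("GENE%05d", seq_len(ng))
    gene_length <- sample(seq(config$gene_length_range_bp[1],
                              config$gene_length_range_bp[2]),
                          ng, replace = TRUE)
    rel <- rlnorm(ng, meanlog = 0, sdlog = 1.2)
    rel <- rel / sum(rel)

    de_idx <- if (config$n_de > 0) sort(sample.int(ng, config$n_de)) else integer(0)
    sign_de <- integer(ng)
    sign_de[de_idx] <- sample(c(-1L, 1L), length(de_idx), replace = TRUE)
    log2fc <- sign_de * abs(config$log2fc_de)

    samples <- expand.grid(rep = seq_len(config$n_replicates),
                           stage = config$stages,
                           genotype = config$genotypes,
                           stringsAsFactors = FALSE)
    sample_name <- sprintf("%s%d_r%d", samples$genotype, samples$stage,
                           samples$rep)

    counts <- matrix(0L, nrow = ng, ncol = nrow(samples),
                     dimnames = list(gene_id, sample_name))
    for (s in seq_len(nrow(samples))) {
      mu <- rel * config$library_size_mean
      if (samples$genotype[s] == "M") {
        mu <- mu * 2^log2fc
      }
      counts[, s] <- rnbinom(ng, mu = mu, size = 1 / config$dispersion)
    }

    structure(
      list(
        counts = dplyr::bind_cols(
          tibble(gene_id = gene_id, gene_length_bp = gene_length),
          as_tibble(counts)
        ),
        truth = tibble(gene_id = gene_id,
                       is_de = seq_len(ng) %in% de_idx,
                       log2fc = log2fc)
      ),
      class = "sim_counts"
    )
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("<sim_counts> %d genes x %d samples, %d planted DE genes\n",
              nrow(x$counts), ncol(x$counts) - 2L, sum(x$truth$is_de)))
  invisible(x)
}
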