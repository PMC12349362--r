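#' Parse sample metadata from count-matrix column names
#'
#' Sample columns follow the `<genotype><stage>_r<rep>` convention
#' (e.g. `M10_r2`: rugose genotype, 10 days post-anthesis, replicate 2).
#'
#' @param counts A counts/FPKM tibble (`gene_id`, `gene_length_bp`, sample
#'   columns) or a `sim_counts` object.
#' @return Tibble: `sample`, `genotype`, `stage`, `replicate`, `group`
#'   (genotype-stage label such as `M10`).
#' @export
sample_info <- function(counts) {
  counts <- as_counts_tbl(counts)
  s <- setdiff(names(counts), c("gene_id", "gene_length_bp"))
  m <- regmatches(s, regexec("^([MG])(\\d+)_r(\\d+)$", s))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_rugosity(paste0("Sample names not in <genotype><stage>_r<rep> form: ",
                         paste(s[bad], collapse = ", ")),
                  "rugosity_invalid_input")
  }
  tibble(
    sample = s,
    genotype = vapply(m, `[`, "", 2L),
    stage = as.integer(vapply(m, `[`, "", 3L)),
    replicate = as.integer(vapply(m, `[`, "", 4L))
  ) |>
    dplyr::mutate(group = paste0(.data$genotype, .data$stage))
}

as_counts_tbl <- function(counts) {
  if (inherits(counts, "sim_counts")) counts <- counts$counts
  if (!is.data.frame(counts) ||
      !all(c("gene_id", "gene_length_bp") %in% names(counts))) {
    stop_rugosity("Expected a counts tibble with `gene_id` and `gene_length_bp` columns.",
                  "rugosity_invalid_input")
  }
  as_tibble(counts)
}

counts_matrix <- function(counts) {
  counts <- as_counts_tbl(counts)
  s <- setdiff(names(counts), c("gene_id", "gene_length_bp"))
  m <- as.matrix(counts[, s])
  rownames(m) <- counts$gene_id
  m
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \deqn{FPKM_{gs} = 10^9 \, c_{gs} / (\ell_g N_s)} with \eqn{c_{gs}} the
#' count, \eqn{\ell_g} the gene length in bp and \eqn{N_s} the sample's
#' total counts. The denominator uses the in-matrix column sum as the
#' mapped-read total.
#'
#' @param counts Counts tibble or `sim_counts`.
#' @return A tibble of the same shape with FPKM values in the sample
#'   columns, flagged via attribute `units = "fpkm"`.
#' @examples
#' sim <- generate_counts(counts_config(n_genes = 50, seed = 1))
#' fpkm(sim)[1:3, 1:4]
#' @export
fpkm <- function(counts) {
  tbl <- as_counts_tbl(counts)
  if (any(tbl$gene_length_bp <= 0)) {
    stop_rugosity("Gene lengths must be > 0.", "rugosity_invalid_input")
  }
  m <- counts_matrix(tbl)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop_rugosity(paste0("Sample(s) with zero total counts: ",
                         paste(colnames(m)[totals == 0], collapse = ", ")),
                  "rugosity_degenerate_sample")
  }
  f <- sweep(m, 1, tbl$gene_length_bp, "/")
  f <- sweep(f, 2, totals, "/") * 1e9
  out <- dplyr::bind_cols(tbl[, c("gene_id", "gene_length_bp")], as_tibble(f))
  attr(out, "units") <- "fpkm"
  out
}

#' Median-of-ratios library-size factors
#'
#' Per-sample scaling factors computed as the median across genes of the
#' ratio of each sample's count to the gene's geometric mean over samples
#' (genes with any zero count are excluded from the reference).
#'
#' @param counts Counts tibble or `sim_counts`.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  log_geo <- rowMeans(log(m))
  ok <- is.finite(log_geo)
  if (!any(ok)) {
    stop_rugosity("No gene has all-positive counts; size factors undefined.",
                  "rugosity_degenerate_sample")
  }
  apply(m, 2, function(col) exp(stats::median((log(col) - log_geo)[ok])))
}

#' Two-group differential-expression screen
#'
#' Operational DE screen for synthetic benchmarking: counts are scaled by
#' median-of-ratios size factors, log2-transformed with pseudocount 1, and
#' each gene is tested with a two-sided pooled-variance t-test between the
#' groups; the log2 fold change is the difference of group means on that
#' scale. This is a calibrated stand-in — its contract is uniform null
#' p-values and power on planted effects, not numerical agreement with any
#' particular DE package.
#'
#' @param counts Counts tibble or `sim_counts`.
#' @param group_a,group_b Character vectors of sample column names, or a
#'   single genotype letter (`"M"`/`"G"`) optionally combined with
#'   `stage`.
#' @param stage Optional stage filter (e.g. `10`) applied when groups are
#'   given as genotype letters.
#' @return Tibble: `gene_id`, `log2fc` (a minus b), `p_value`.
#' @examples
#' sim <- generate_counts(counts_config(n_genes = 200, n_de = 10, seed = 1))
#' de <- de_test(sim, "M", "G")
#' @export
de_test <- function(counts, group_a, group_b, stage = NULL) {
  tbl <- as_counts_tbl(counts)
  info <- sample_info(tbl)
  resolve <- function(g) {
    if (length(g) == 1L && g %in% c("M", "G")) {
      sel <- info$genotype == g
      if (!is.null(stage)) sel <- sel & info$stage %in% stage
      info$sample[sel]
    } else {
      if (!all(g %in% info$sample)) {
        stop_rugosity("Unknown sample name(s) in group specification.",
                      "rugosity_invalid_input")
      }
      g
    }
  }
  a <- resolve(group_a)
  b <- resolve(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_rugosity("Each group needs at least 2 replicates.",
                  "rugosity_insufficient_replication")
  }
  m <- counts_matrix(tbl)
  sf <- size_factors(tbl)
  norm <- sweep(m, 2, sf, "/")
  lg <- log2(norm + 1)
  la <- lg[, a, drop = FALSE]
  lb <- lg[, b, drop = FALSE]
  na <- ncol(la); nb <- ncol(lb)
  mean_a <- rowMeans(la)
  mean_b <- rowMeans(lb)
  var_a <- rowSums((la - mean_a)^2) / (na - 1)
  var_b <- rowSums((lb - mean_b)^2) / (nb - 1)
  pooled <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
  se <- sqrt(pooled * (1 / na + 1 / nb))
  tstat <- (mean_a - mean_b) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(tstat), df)
  p[se == 0 & mean_a == mean_b] <- 1
  tibble(gene_id = rownames(m), log2fc = mean_a - mean_b, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop_rugosity("`p_values` must be numbers in [0, 1].",
                  "rugosity_invalid_input")
  }
  p.adjust(p_values, method = "BH")
}

#' Threshold DE statistics into a DEG set
#'
#' A gene passes if its absolute fold change is at least `fc_threshold`
#' (inclusive, i.e. |log2FC| >= log2(fc_threshold)) and its BH-adjusted
#' q-value is strictly below `fdr_threshold`. Defaults |FC| >= 2,
#' FDR < 0.01.
#'
#' @param stats Tibble with `gene_id`, `log2fc` and either `q_value` or
#'   `p_value` (q computed by [bh_fdr()] when absent).
#' @param fc_threshold Fold-change threshold on the natural scale (>= 1).
#' @param fdr_threshold FDR threshold.
#' @return Tibble: `gene_id`, `log2fc`, `p_value` (if available),
#'   `q_value`, `pass`.
#' @examples
#' filter_degs(tibble::tibble(gene_id = "g1", log2fc = 1, p_value = 0.001))
#' @export
filter_degs <- function(stats, fc_threshold = 2, fdr_threshold = 0.01) {
  if (!all(c("gene_id", "log2fc") %in% names(stats))) {
    stop_rugosity("`stats` needs `gene_id` and `log2fc` columns.",
                  "rugosity_invalid_input")
  }
  check_finite_scalar(fc_threshold, "fc_threshold", positive = TRUE)
  out <- as_tibble(stats)
  if (!"q_value" %in% names(out)) {
    if (!"p_value" %in% names(out)) {
      stop_rugosity("`stats` needs a `p_value` or `q_value` column.",
                    "rugosity_invalid_input")
    }
    out$q_value <- bh_fdr(out$p_value)
  }
  out$pass <- abs(out$log2fc) >= log2(fc_threshold) &
    out$q_value < fdr_threshold
  out
}

#' Standardized group-mean expression profiles
#'
#' Averages FPKM (log2 with pseudocount 1) over replicates within each
#' genotype-stage group and standardizes every gene's profile across the
#' groups to mean 0, sd 1 — the representation clustered into
#' co-expression modules. Genes with a constant profile are dropped with a
#' warning.
#'
#' @param fpkm_tbl FPKM tibble (from [fpkm()]).
#' @param genes Optional character vector restricting to a gene subset
#'   (e.g. a DEG set).
#' @return Numeric matrix, genes x groups (ordered M then G, by stage),
#'   rows standardized.
#' @export
zscore_profiles <- function(fpkm_tbl, genes = NULL) {
  tbl <- as_counts_tbl(fpkm_tbl)
  info <- sample_info(tbl)
  m <- log2(counts_matrix(tbl) + 1)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(m))
    if (length(missing_genes)) {
      stop_rugosity("Unknown gene id(s) in `genes`.", "rugosity_invalid_input")
    }
    m <- m[genes, , drop = FALSE]
  }
  groups <- unique(info$group[order(match(info$genotype, c("M", "G")),
                                    info$stage)])
  prof <- vapply(groups, function(g) {
    rowMeans(m[, info$sample[info$group == g], drop = FALSE])
  }, numeric(nrow(m)))
  if (length(groups) < 2L) {
    stop_rugosity("Need at least 2 sample groups to build profiles.",
                  "rugosity_invalid_input")
  }
  sds <- apply(prof, 1, sd)
  if (any(sds == 0)) {
    warn_rugosity(sprintf("%d constant gene profile(s) dropped before standardization.",
                          sum(sds == 0)),
                  "rugosity_constant_gene_warning")
    prof <- prof[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (prof - rowMeans(prof)) / sds
}

#' K-means co-expression modules on standardized profiles
#'
#' Clusters standardized group-mean profiles with Euclidean K-means,
#' keeping the best of `n_init` random restarts under a fixed seed, so the
#' assignment is reproducible.
#'
#' @param profiles Genes x groups matrix from [zscore_profiles()].
#' @param k Number of modules (2 <= k <= number of genes).
#' @param seed Integer seed controlling initialization.
#' @param n_init Number of random restarts.
#' @return An object of class `cluster_modules`: `assignment` tibble
#'   (`gene_id`, `module`), `centers` (module x group matrix of mean
#'   standardized profiles), `withinss` total, `k`, `seed`.
#' @export
kmeans_modules <- function(profiles, k, seed = 1, n_init = 25) {
  if (!is.matrix(profiles) || is.null(rownames(profiles))) {
    stop_rugosity("`profiles` must be a matrix with gene ids as rownames.",
                  "rugosity_invalid_input")
  }
  check_finite_scalar(k, "k", positive = TRUE)
  if (k < 2 || k > nrow(profiles)) {
    stop_rugosity("`k` must satisfy 2 <= k <= number of genes.",
                  "rugosity_invalid_parameter")
  }
  km <- with_seed_or_not(seed,
                         kmeans(profiles, centers = k, nstart = n_init,
                                iter.max = 100))
  # relabel modules by decreasing size for a deterministic presentation
  ord <- order(-km$size, seq_along(km$size))
  relabel <- match(seq_along(ord), ord)
  structure(
    list(
      assignment = tibble(gene_id = rownames(profiles),
                          module = relabel[km$cluster]),
      centers = km$centers[ord, , drop = FALSE],
      withinss = sum(km$withinss),
      k = as.integer(k),
      seed = seed,
      profiles = profiles
    ),
    class = "cluster_modules"
  )
}

#' @export
print.cluster_modules <- function(x, ...) {
  cat(sprintf("<cluster_modules> %d genes in %d modules (total within-SS %.2f)\n",
              nrow(x$assignment), x$k, x$withinss))
  print(dplyr::count(x$assignment, .data$module))
  invisible(x)
}

#' Principal component analysis of samples
#'
#' PCA of samples on log2(FPKM + 1), genes centred, no scaling. Reports
#' sample coordinates with their design metadata and the fraction of
#' variance explained per component.
#'
#' @param fpkm_tbl FPKM tibble (from [fpkm()]); raw counts also work, the
#'   log transform is applied either way.
#' @param n_components Number of components to keep.
#' @return An object of class `sample_pca`: `scores` tibble (`sample`,
#'   `genotype`, `stage`, `replicate`, `PC1`, ...), `var_explained`
#'   numeric vector (fractions, non-increasing).
#' @export
pca_samples <- function(fpkm_tbl, n_components = 5) {
  tbl <- as_counts_tbl(fpkm_tbl)
  info <- sample_info(tbl)
  if (nrow(info) < 3L) {
    stop_rugosity("PCA needs at least 3 samples.", "rugosity_invalid_input")
  }
  m <- t(log2(counts_matrix(tbl) + 1)) # samples x genes
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_components, ncol(pc$x)))
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(info[, c("sample", "genotype", "stage", "replicate")],
                             as_tibble(pc$x[, keep, drop = FALSE]))
  structure(list(scores = scores, var_explained = var_explained[keep]),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca>\n  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
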