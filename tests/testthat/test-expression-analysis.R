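test_that("fpkm matches the per-cell definition", {
  # unit example: 100 counts, 1 kb gene, 1e6 library -> FPKM 100
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"), gene_length_bp = c(1000L, 2000L),
    M6_r1 = c(100, 1e6 - 100), M6_r2 = c(50, 1e6 - 50))
  f <- fpkm(counts)
  expect_equal(f$M6_r1[1], 100 * 1e9 / (1000 * 1e6))

  # doubling every count in a sample leaves its FPKM unchanged
  doubled <- counts
  doubled$M6_r1 <- doubled$M6_r1 * 2
  expect_equal(fpkm(doubled)$M6_r1, f$M6_r1)

  # random matrix against the brute-force formula
  sim <- generate_counts(counts_config(n_genes = 120, n_de = 0, seed = 14))
  f2 <- fpkm(sim)
  m <- rugosity:::counts_matrix(sim$counts)
  fm <- rugosity:::counts_matrix(f2)
  lens <- sim$counts$gene_length_bp
  for (idx in withr::with_seed(1, sample(length(m), 50))) {
    g <- (idx - 1) %% nrow(m) + 1
    s <- (idx - 1) %/% nrow(m) + 1
    expected <- m[g, s] * 1e9 / (lens[g] * sum(m[, s]))
    expect_equal(fm[g, s], expected, tolerance = 1e-12)
  }

  zero <- counts
  zero$M6_r1 <- 0
  expect_error(fpkm(zero), class = "rugosity_degenerate_sample")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  sim <- generate_counts(counts_config(n_genes = 400, n_de = 20, seed = 6))
  m <- rugosity:::counts_matrix(sim$counts)
  ours <- size_factors(sim)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("de_test gives zero log2FC on identical groups and power on planted effects", {
  sim <- generate_counts(counts_config(n_genes = 100, n_de = 0, seed = 2))
  counts <- sim$counts
  # duplicate one sample into both groups -> identical groups
  counts$G6_r1 <- counts$M6_r1
  counts$G6_r2 <- counts$M6_r2
  de_same <- de_test(counts, c("M6_r1", "M6_r2"), c("G6_r1", "G6_r2"))
  expect_true(all(de_same$log2fc == 0))
  expect_true(all(de_same$p_value == 1))

  # planted strong effects rank on top
  sim2 <- generate_counts(counts_config(n_genes = 2000, n_de = 50,
                                        log2fc_de = 4, dispersion = 0.01,
                                        seed = 33))
  de <- de_test(sim2, "M", "G", stage = 10)
  top <- de$gene_id[order(de$p_value)][1:50]
  planted <- sim2$truth$gene_id[sim2$truth$is_de]
  expect_gte(length(intersect(top, planted)), 45)

  # null p-values approximately uniform (KS vs U(0,1))
  de_null <- de_test(generate_counts(counts_config(n_genes = 2000, n_de = 0,
                                                   seed = 55)),
                     "M", "G")
  ks <- suppressWarnings(stats::ks.test(de_null$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  expect_error(de_test(sim, c("M6_r1"), c("G6_r1", "G6_r2")),
               class = "rugosity_insufficient_replication")
})

test_that("bh_fdr matches hand-applied step-up rules", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "rugosity_invalid_input")

  # independent step-up oracle on random p-vectors (exact match)
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- runif(sample(5:200, 1))^sample(1:3, 1)
      expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-14)
    }
  })
})

test_that("filter_degs applies inclusive FC and strict FDR boundaries", {
  stats_tbl <- tibble::tibble(
    gene_id = c("exact_fc", "fdr_at_limit", "both_pass", "neither"),
    log2fc = c(1.0, 3, -2, 0.5),
    q_value = c(0.005, 0.01, 0.001, 0.5))
  out <- filter_degs(stats_tbl)
  expect_identical(out$pass,
                   c(TRUE,   # |FC| = 2 exactly is inclusive
                     FALSE,  # FDR must be strictly < 0.01
                     TRUE, FALSE))

  # 20-gene toy table equals the brute-force double-loop filter
  toy <- withr::with_seed(9, tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    log2fc = rnorm(20, sd = 2),
    p_value = runif(20)^2))
  got <- filter_degs(toy, fc_threshold = 2, fdr_threshold = 0.05)
  q <- bh_stepup_oracle(toy$p_value)
  brute <- logical(20)
  for (i in 1:20) {
    brute[i] <- abs(toy$log2fc[i]) >= log2(2) && q[i] < 0.05
  }
  expect_identical(got$pass, brute)
})

test_that("zscore_profiles standardizes rows and preserves monotone order", {
  sim <- generate_counts(counts_config(n_genes = 60, n_de = 10, seed = 18))
  prof <- zscore_profiles(fpkm(sim))
  expect_identical(colnames(prof), c("M6", "M10", "M14", "G6", "G10", "G14"))
  expect_lt(max(abs(rowMeans(prof))), 1e-9)
  expect_lt(max(abs(apply(prof, 1, sd) - 1)), 1e-9)

  # constant gene dropped with warning (hand-built FPKM-like table)
  flat_tbl <- tibble::tibble(
    gene_id = c("gflat", "gvar"), gene_length_bp = c(1000L, 1000L),
    M6_r1 = c(7, 1), M6_r2 = c(7, 2), M10_r1 = c(7, 3), M10_r2 = c(7, 4),
    G6_r1 = c(7, 5), G6_r2 = c(7, 6))
  expect_warning(prof2 <- zscore_profiles(flat_tbl),
                 class = "rugosity_constant_gene_warning")
  expect_identical(rownames(prof2), "gvar")

  # a monotone-increasing profile stays strictly increasing after z-scoring
  mono <- matrix(c(1, 2, 4, 8, 16, 32), nrow = 1,
                 dimnames = list("g", c("M6", "M10", "M14", "G6", "G10", "G14")))
  z <- (mono - mean(mono)) / sd(mono)
  expect_true(all(diff(z[1, ]) > 0))
})

test_that("kmeans_modules recovers planted archetypes deterministically", {
  # two well-separated profile archetypes
  arch <- withr::with_seed(23, {
    up <- matrix(rep(c(-1, -0.5, 0, 0.5, 1, 1.5), each = 30), ncol = 6) +
      rnorm(180, sd = 0.05)
    down <- matrix(rep(c(1.5, 1, 0.5, 0, -0.5, -1), each = 30), ncol = 6) +
      rnorm(180, sd = 0.05)
    rbind(up, down)
  })
  rownames(arch) <- sprintf("g%03d", 1:60)
  colnames(arch) <- c("M6", "M10", "M14", "G6", "G10", "G14")
  truth <- rep(1:2, each = 30)

  cm <- kmeans_modules(arch, k = 2, seed = 7)
  expect_equal(rand_index_adjusted(cm$assignment$module, truth), 1.0)

  # deterministic under a fixed seed
  cm2 <- kmeans_modules(arch, k = 2, seed = 7)
  expect_identical(cm$assignment, cm2$assignment)

  # module centers equal the mean member profile
  for (mod in 1:2) {
    members <- cm$assignment$gene_id[cm$assignment$module == mod]
    expect_lt(max(abs(cm$centers[mod, ] -
                        colMeans(arch[members, , drop = FALSE]))), 1e-9)
  }

  expect_error(kmeans_modules(arch, k = 100),
               class = "rugosity_invalid_parameter")
  expect_error(kmeans_modules(arch, k = 1),
               class = "rugosity_invalid_parameter")
})

test_that("pca_samples separates genotypes and orders variance fractions", {
  sim <- generate_counts(counts_config(n_genes = 500, n_de = 50,
                                       log2fc_de = 2, seed = 40))
  pca <- pca_samples(fpkm(sim))
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-9)

  # PC1 separates genotypes: silhouette on PC1 alone is positive
  sc <- pca$scores
  sil <- vapply(seq_len(nrow(sc)), function(i) {
    same <- sc$genotype == sc$genotype[i]
    a <- mean(abs(sc$PC1[i] - sc$PC1[same & seq_len(nrow(sc)) != i]))
    b <- mean(abs(sc$PC1[i] - sc$PC1[!same]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)

  # duplicated samples get coincident coordinates
  counts <- sim$counts
  counts$G14_r3 <- counts$G14_r2
  pca2 <- pca_samples(fpkm(counts))
  s2 <- pca2$scores
  expect_equal(s2$PC1[s2$sample == "G14_r3"], s2$PC1[s2$sample == "G14_r2"],
               tolerance = 1e-9)
  expect_equal(s2$PC2[s2$sample == "G14_r3"], s2$PC2[s2$sample == "G14_r2"],
               tolerance = 1e-9)
})

test_that("delta_delta_ct handles replicates, calibrators and missing references", {
  ct <- generate_ct_table(2, 3, true_log2_ratios = c(0, 1, -2),
                          n_replicates = 3)
  res <- delta_delta_ct(ct)
  expect_equal(res$rel_expression[res$sample == "S01"], c(1, 1))
  expect_equal(res$rel_expression[res$sample == "S02"], c(2, 2))
  expect_equal(res$rel_expression[res$sample == "S03"], c(0.25, 0.25))

  # ddCt identities: +1 -> 0.5, -2 -> 4
  ct1 <- generate_ct_table(1, 3, true_log2_ratios = c(0, -1, 2))
  res1 <- delta_delta_ct(ct1)
  expect_equal(res1$rel_expression, c(1, 0.5, 4))

  bad <- ct
  bad$ct_reference[1] <- NA
  expect_error(delta_delta_ct(bad), class = "rugosity_missing_reference")
})

test_that("the full expression pipeline runs end to end quickly", {
  t0 <- Sys.time()
  sim <- generate_counts(counts_config(n_genes = 2000, n_de = 100,
                                       log2fc_de = 3, seed = 77))
  de <- de_test(sim, "M", "G")
  degs <- filter_degs(de)
  expect_gt(sum(degs$pass), 0)
  prof <- zscore_profiles(fpkm(sim), genes = degs$gene_id[degs$pass])
  cm <- kmeans_modules(prof, k = 4, seed = 1)
  expect_identical(nrow(tidy(cm)), sum(degs$pass))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
})
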