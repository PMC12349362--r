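test_that("sensory-on-RI regression reproduces exact and hand-computed fits", {
  # perfect linear relation
  tbl <- tibble::tibble(ri_percent = 1:10,
                        sensory_level = 1 + 0.5 * (1:10))
  fit <- suppressWarnings(fit_ri_sensory_regression(tbl)) # exact fit warns
  expect_equal(fit$beta0, 1, tolerance = 1e-12)
  expect_equal(fit$beta1, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # hand-computed Pearson r^2 for {(1,1),(2,2),(3,2),(4,3)}:
  # sxy = 3, sxx = 5, syy = 2 -> r^2 = 9/10
  tbl2 <- tibble::tibble(ri_percent = 1:4, sensory_level = c(1, 2, 2, 3))
  fit2 <- fit_ri_sensory_regression(tbl2)
  expect_equal(fit2$r_squared, 0.9, tolerance = 1e-12)

  expect_error(
    fit_ri_sensory_regression(tibble::tibble(ri_percent = rep(2, 5),
                                             sensory_level = 1:5)),
    class = "rugosity_degenerate_design")

  # R^2 equals squared Pearson r on arbitrary data
  pop <- generate_population(population_config(n_fruits = 150, seed = 5))
  fit3 <- fit_ri_sensory_regression(pop)
  expect_equal(fit3$r_squared,
               cor(pop$ri_percent, pop$sensory_level)^2,
               tolerance = 1e-10)
  # and equals squared Pearson r between fitted and observed
  expect_equal(fit3$r_squared,
               cor(predict(fit3$fit), pop$sensory_level)^2,
               tolerance = 1e-10)

  td <- tidy(fit3)
  expect_identical(td$term, c("(Intercept)", "ri_percent"))
  expect_equal(glance(fit3)$r.squared, fit3$r_squared)
})

test_that("anova_tukey flags the deviant group and letters match the p matrix", {
  # all groups identical -> F ~ 0, one shared letter
  base <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  same <- tibble::tibble(y = rep(base, 4), level = rep(1:4, each = 5))
  res_same <- anova_tukey(same, "y")
  expect_lt(res_same$f_statistic, 1e-10)
  expect_identical(unique(res_same$summary$letters), "a")

  # one deviant group gets a unique letter; verify Tukey p from first
  # principles via the studentized-range distribution
  dev <- withr::with_seed(2, tibble::tibble(
    y = c(rnorm(15, 10, 0.1), rnorm(5, 50, 0.1)),
    level = rep(1:4, each = 5)))
  res <- anova_tukey(dev, "y")
  l4 <- res$summary$letters[res$summary$group == "4"]
  expect_false(l4 %in% res$summary$letters[res$summary$group != "4"])

  mse <- sum(unlist(tapply(dev$y, dev$level,
                           function(v) (v - mean(v))^2))) / (20 - 4)
  means <- tapply(dev$y, dev$level, mean)
  q_obs <- abs(means[["4"]] - means[["1"]]) / sqrt(mse / 5)
  p_first_principles <- stats::ptukey(q_obs, nmeans = 4, df = 16,
                                      lower.tail = FALSE)
  p_pkg <- res$tukey$p_adj[res$tukey$group_a == "4" &
                             res$tukey$group_b == "1"]
  expect_equal(p_pkg, p_first_principles, tolerance = 1e-8)

  # letters partition invariant: sharing no letter <=> adjusted p < alpha
  pop <- generate_population(population_config(n_fruits = 120, seed = 8))
  for (ind in c("RF", "SF", "ISP")) {
    gc <- anova_tukey(pop, ind, group = "true_level")
    lookup <- setNames(gc$summary$letters, gc$summary$group)
    for (i in seq_len(nrow(gc$tukey))) {
      la <- strsplit(lookup[[gc$tukey$group_a[i]]], "")[[1]]
      lb <- strsplit(lookup[[gc$tukey$group_b[i]]], "")[[1]]
      shares <- length(intersect(la, lb)) > 0
      expect_identical(shares, gc$tukey$p_adj[i] >= gc$alpha)
    }
  }

  # planted monotone trend, noise-free: strictly decreasing RF means
  pop0 <- generate_population(population_config(
    n_fruits = 200, sensory_misgrade_prob = 0, indicator_noise_scale = 0,
    seed = 3))
  gc_rf <- suppressWarnings(anova_tukey(pop0, "RF", group = "true_level"))
  expect_true(all(diff(gc_rf$summary$mean) < 0))

  expect_error(anova_tukey(tibble::tibble(y = c(1, 2), level = c(1, 2)), "y"),
               class = "rugosity_insufficient_replication")
})

test_that("pairwise t-test reproduces the pooled-variance hand formula", {
  same <- pairwise_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- pairwise_ttest(c(1, 2, 3), c(11, 12, 13) + 1e-3 * c(1, -1, 0))
  expect_lt(sep$p_value, 0.001)

  # {1,2,3,4} vs {2,3,4,5}: pooled var = 5/3, se = sqrt(5/6), t = -1/se
  ht <- pairwise_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  t_hand <- -1 / sqrt((5 / 3) * (1 / 4 + 1 / 4))
  expect_equal(ht$statistic, t_hand, tolerance = 1e-12)
  expect_equal(ht$df, 6)
  expect_equal(ht$p_value, 2 * pt(t_hand, 6), tolerance = 1e-12)

  # Welch variant matches stats::t.test
  a <- c(1, 2, 3, 8); b <- c(2, 2.1, 2.2)
  expect_equal(pairwise_ttest(a, b, welch = TRUE)$p_value,
               t.test(a, b)$p.value)

  expect_error(pairwise_ttest(1, c(1, 2)), class = "rugosity_invalid_input")
  expect_error(pairwise_ttest(c(1, 1), c(2, 2)), class = "rugosity_degenerate")
})

test_that("pearson_matrix matches the definitional covariance oracle", {
  tbl <- withr::with_seed(4, tibble::tibble(
    a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  tbl$d <- -tbl$a
  res <- tidy(pearson_matrix(tbl, c("a", "b", "c", "d")))

  self <- res[res$var1 == "a" & res$var2 == "a", ]
  expect_equal(self$r, 1)
  anti <- res[res$var1 == "a" & res$var2 == "d", ]
  expect_equal(anti$r, -1, tolerance = 1e-12)
  expect_identical(anti$stars, "***")

  # brute-force r from the covariance definition, all pairs, 1e-12
  for (v1 in c("a", "b", "c", "d")) {
    for (v2 in c("a", "b", "c", "d")) {
      if (v1 == v2) next
      x <- tbl[[v1]]; y <- tbl[[v2]]
      r_def <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      r_pkg <- res$r[res$var1 == v1 & res$var2 == v2]
      expect_equal(r_pkg, r_def, tolerance = 1e-12)
    }
  }

  # symmetry and star consistency
  for (i in seq_len(nrow(res))) {
    mirror <- res$r[res$var1 == res$var2[i] & res$var2 == res$var1[i]]
    expect_equal(res$r[i], mirror)
    if (!is.na(res$p[i]) && res$var1[i] != res$var2[i]) {
      expect_identical(res$stars[i],
                       if (res$p[i] < 0.001) "***"
                       else if (res$p[i] < 0.01) "**"
                       else if (res$p[i] < 0.05) "*"
                       else "ns")
    }
  }

  # constant column: NA with warning
  tbl$e <- 1
  expect_warning(res2 <- pearson_matrix(tbl, c("a", "e")),
                 class = "rugosity_constant_column_warning")
  expect_true(is.na(tidy(res2)$r[tidy(res2)$var1 == "a" &
                                   tidy(res2)$var2 == "e"]))
})

test_that("level_ratio reproduces forced arithmetic and the planted fold ratio", {
  tbl <- tibble::tibble(v = c(65.5, 65.5, 10, 10), level = c(1, 1, 4, 4))
  expect_equal(level_ratio(tbl, "v"), 6.55)
  expect_equal(level_ratio(tbl, "v", level_a = 4, level_b = 1), 10 / 65.5)

  eq <- tibble::tibble(v = c(2, 2, 2, 2), level = c(1, 1, 4, 4))
  expect_equal(level_ratio(eq, "v"), 1)

  zero <- tibble::tibble(v = c(1, 1, 0, 0), level = c(1, 1, 4, 4))
  expect_error(level_ratio(zero, "v"), class = "rugosity_undefined_ratio")

  # noise-free generator: RF Level1/Level4 ratio is exactly 65.5/10
  pop0 <- generate_population(population_config(
    n_fruits = 400, indicator_noise_scale = 0, seed = 12))
  pop0$level <- pop0$true_level
  expect_equal(level_ratio(pop0, "RF"), 6.55, tolerance = 1e-12)
})

test_that("noise-free population recovers a near-perfect sensory regression", {
  pop <- generate_population(population_config(
    n_fruits = 277, sensory_misgrade_prob = 0, indicator_noise_scale = 0,
    seed = 21))
  fit <- fit_ri_sensory_regression(pop)
  expect_gte(fit$r_squared, 0.95)
})
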