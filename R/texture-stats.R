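#' Validate the rugosity index against sensory grading
#'
#' Ordinary least squares of the ordinal sensory grade (Y, treated as
#' numeric 1-4) on the quantitative rugosity index (X):
#' \eqn{Y = \beta_0 + \beta_1 X + \epsilon}. The coefficient of
#' determination measures how much of the sensory variance the index
#' explains; for simple regression it equals the squared Pearson
#' correlation of the two variables, so the direction of regression does
#' not affect it.
#'
#' @param table Data frame of phenotype records.
#' @param ri,sensory Column names (strings) of the rugosity index and the
#'   sensory grade.
#' @return An object of class `ri_regression` with fields `beta0`, `beta1`,
#'   `r_squared`, `p_value_slope`, `n` and the underlying `lm` fit. Has
#'   [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' pop <- generate_population(population_config(seed = 1))
#' fit_ri_sensory_regression(pop)
#' @export
fit_ri_sensory_regression <- function(table, ri = "ri_percent",
                                      sensory = "sensory_level") {
  if (!all(c(ri, sensory) %in% names(table))) {
    stop_rugosity("`table` must contain the RI and sensory columns.",
                  "rugosity_invalid_input")
  }
  x <- table[[ri]]
  y <- as.numeric(table[[sensory]])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_rugosity("Need at least 3 complete observations.",
                  "rugosity_invalid_input")
  }
  if (var(x) == 0) {
    stop_rugosity("Degenerate design: the RI column has zero variance.",
                  "rugosity_degenerate_design")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
         r_squared = sm$r.squared,
         p_value_slope = unname(sm$coefficients[2, 4]),
         n = length(x), fit = fit,
         data = tibble(ri_percent = x, sensory_level = y)),
    class = "ri_regression"
  )
}

#' @export
print.ri_regression <- function(x, ...) {
  cat(sprintf(
    "<ri_regression> n = %d\n  sensory = %.4f + %.4f * RI\n  R^2 = %.4f, slope p = %.3g\n",
    x$n, x$beta0, x$beta1, x$r_squared, x$p_value_slope))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD letters for one indicator across levels
#'
#' Fits a one-way ANOVA of the indicator on the (factor) rugosity level,
#' runs Tukey's honestly significant difference test on all level pairs
#' (Tukey-Kramer for unbalanced groups, via [stats::TukeyHSD()]), and
#' summarises the pairwise results as a compact letter display at the given
#' alpha: groups that share no letter differ significantly.
#'
#' @param table Data frame of phenotype records.
#' @param indicator Column name (string) of the indicator to compare.
#' @param group Column name of the grouping variable (default `"level"`;
#'   `"true_level"` and `"sensory_level"` also work on generated tables).
#' @param alpha Significance level for the letter display.
#' @return An object of class `group_comparison`: `summary` tibble (group,
#'   n, mean, se, letters), `f_statistic`, `p_value`, `tukey` tibble of
#'   pairwise adjusted p-values, `alpha`, `indicator`.
#' @examples
#' pop <- generate_population(population_config(seed = 1))
#' anova_tukey(pop, "RF", group = "true_level")
#' @export
anova_tukey <- function(table, indicator, group = "level", alpha = 0.05) {
  if (!all(c(indicator, group) %in% names(table))) {
    stop_rugosity("`table` must contain the indicator and grouping columns.",
                  "rugosity_invalid_input")
  }
  df <- tibble(y = table[[indicator]], g = factor(table[[group]]))
  df <- df[is.finite(df$y) & !is.na(df$g), ]
  df$g <- droplevels(df$g)
  counts <- table(df$g)
  if (length(counts) < 2L) {
    stop_rugosity("Need at least 2 groups for ANOVA.",
                  "rugosity_insufficient_replication")
  }
  if (any(counts < 2L)) {
    stop_rugosity("Every group needs at least 2 observations for ANOVA.",
                  "rugosity_insufficient_replication")
  }
  fit <- aov(y ~ g, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble(
    group_a = vapply(pairs, `[`, "", 1L),
    group_b = vapply(pairs, `[`, "", 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
  groups <- levels(df$g)
  means <- tapply(df$y, df$g, mean)
  ses <- tapply(df$y, df$g, function(v) sd(v) / sqrt(length(v)))
  letters <- compact_letter_display(groups, tukey, means, alpha)
  structure(
    list(
      summary = tibble(group = groups, n = as.integer(counts),
                       mean = as.numeric(means), se = as.numeric(ses),
                       letters = letters[groups]),
      f_statistic = an$`F value`[1],
      p_value = an$`Pr(>F)`[1],
      tukey = tukey,
      alpha = alpha,
      indicator = indicator
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F = %.3f, p = %.3g (alpha = %g)\n",
              x$indicator, x$f_statistic, x$p_value, x$alpha))
  print(x$summary)
  invisible(x)
}

# Insert-and-absorb compact letter display. Groups are processed in
# descending order of mean so letters read a, b, ... from the largest
# group downward; the result depends only on the significance pattern.
compact_letter_display <- function(groups, tukey, means, alpha) {
  ord <- groups[order(-means[groups])]
  k <- length(ord)
  sig <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  for (i in seq_len(nrow(tukey))) {
    a <- tukey$group_a[i]; b <- tukey$group_b[i]
    s <- is.finite(tukey$p_adj[i]) && tukey$p_adj[i] < alpha
    sig[a, b] <- s
    sig[b, a] <- s
  }
  # columns of `letters_mat` are letter classes: maximal sets of mutually
  # non-different groups
  classes <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!sig[ord[i], ord[j]]) next
      for (ci in seq_along(classes)) {
        cl <- classes[[ci]]
        if (cl[i] && cl[j]) {
          # duplicate the class, removing one offender from each copy
          c1 <- cl; c1[j] <- FALSE
          c2 <- cl; c2[i] <- FALSE
          classes[[ci]] <- c1
          classes[[length(classes) + 1L]] <- c2
        }
      }
      # absorb classes contained in another
      keep <- rep(TRUE, length(classes))
      for (a_i in seq_along(classes)) {
        for (b_i in seq_along(classes)) {
          if (a_i != b_i && keep[a_i] && keep[b_i] &&
              all(classes[[a_i]] <= classes[[b_i]])) {
            keep[a_i] <- FALSE
          }
        }
      }
      classes <- classes[keep]
    }
  }
  # order classes by first member so 'a' labels the top-mean class
  first <- vapply(classes, function(cl) which(cl)[1], integer(1))
  classes <- classes[order(first)]
  lab <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(classes, `[`, TRUE, i))], collapse = "")
  }, character(1))
  setNames(lab, ord)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test between two groups (the classical
#' Student form); `welch = TRUE` switches to the Welch unequal-variance
#' form.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @examples
#' pairwise_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
pairwise_ttest <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_rugosity("Each group needs at least 2 observations.",
                  "rugosity_invalid_input")
  }
  if (!welch && var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(statistic = 0, df = length(group_a) + length(group_b) - 2,
                    p_value = 1, mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop_rugosity("Zero pooled variance with unequal means: t is undefined.",
                  "rugosity_degenerate")
  }
  ht <- t.test(group_a, group_b, var.equal = !welch)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Pairwise Pearson correlations with significance stars
#'
#' Computes the Pearson correlation, its two-sided p-value and a star code
#' for every pair of indicator columns, using pairwise-complete
#' observations. Stars follow the conventional thresholds: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `ns` otherwise. Pairs involving a
#' constant column are reported as missing with a warning. The long-format
#' result feeds a dot-style correlation heatmap directly (point size
#' proportional to |r|).
#'
#' @param table Data frame of phenotype records.
#' @param indicators Character vector of column names; defaults to all
#'   numeric columns except identifiers and level columns.
#' @return An object of class `correlation_result`: a long tibble `var1`,
#'   `var2`, `r`, `p`, `stars` covering all ordered pairs (diagonal
#'   included).
#' @examples
#' pop <- generate_population(population_config(seed = 1))
#' head(tidy(pearson_matrix(pop, c("ri_percent", "RF", "PG"))))
#' @export
pearson_matrix <- function(table, indicators = NULL) {
  if (is.null(indicators)) {
    numeric_cols <- names(table)[vapply(table, is.numeric, TRUE)]
    indicators <- setdiff(numeric_cols,
                          c("true_level", "sensory_level", "level"))
  }
  missing_cols <- setdiff(indicators, names(table))
  if (length(missing_cols)) {
    stop_rugosity(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
                  "rugosity_invalid_input")
  }
  m <- length(indicators)
  out <- vector("list", m * m)
  constant_seen <- FALSE
  idx <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      idx <- idx + 1L
      xi <- table[[indicators[i]]]
      xj <- table[[indicators[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      xi <- xi[ok]; xj <- xj[ok]
      if (length(xi) < 3L) {
        stop_rugosity("Need >= 3 pairwise-complete rows for every pair.",
                      "rugosity_invalid_input")
      }
      if (i == j) {
        r <- 1; p <- 0
      } else if (sd(xi) == 0 || sd(xj) == 0) {
        constant_seen <- TRUE
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(xi, xj, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[idx]] <- tibble(var1 = indicators[i], var2 = indicators[j],
                           r = r, p = p, stars = star_code(p))
    }
  }
  if (constant_seen) {
    warn_rugosity("Constant column(s): correlations for their pairs are undefined and reported as NA.",
                  "rugosity_constant_column_warning")
  }
  structure(dplyr::bind_rows(out), class = c("correlation_result",
                                             "tbl_df", "tbl", "data.frame"))
}

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Ratio of indicator group means between two rugosity levels
#'
#' Plain ratio `mean(level_a) / mean(level_b)`, the form in which
#' between-level contrasts such as "smooth fruits rupture at 6.55 times the
#' force of highly rugose ones" are reported.
#'
#' @param table Data frame of phenotype records.
#' @param indicator Column name of the indicator.
#' @param level_a,level_b Levels to compare (numerator / denominator).
#' @param group Grouping column name.
#' @return A single number.
#' @export
level_ratio <- function(table, indicator, level_a = 1, level_b = 4,
                        group = "level") {
  if (!all(c(indicator, group) %in% names(table))) {
    stop_rugosity("`table` must contain the indicator and grouping columns.",
                  "rugosity_invalid_input")
  }
  ya <- table[[indicator]][table[[group]] == level_a]
  yb <- table[[indicator]][table[[group]] == level_b]
  ya <- ya[is.finite(ya)]; yb <- yb[is.finite(yb)]
  if (length(ya) == 0L || length(yb) == 0L) {
    stop_rugosity("Both level groups must be non-empty.",
                  "rugosity_invalid_input")
  }
  if (mean(yb) == 0) {
    stop_rugosity("Denominator group mean is zero: ratio undefined.",
                  "rugosity_undefined_ratio")
  }
  mean(ya) / mean(yb)
}
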