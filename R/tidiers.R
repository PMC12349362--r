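#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rugosity-sensory regression
#'
#' @param x An `ri_regression`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy ri_regression
#' @export
tidy.ri_regression <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "ri_percent"),
         estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.ri_regression
#' @return `glance()`: one row with `r.squared`, `p.value` (slope), `n`.
#' @method glance ri_regression
#' @export
glance.ri_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared, beta0 = x$beta0, beta1 = x$beta1,
         p.value = x$p_value_slope, n = x$n)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The per-group summary tibble (group, n, mean, se, letters).
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(indicator = x$indicator, f.statistic = x$f_statistic,
         p.value = x$p_value, n.groups = nrow(x$summary), alpha = x$alpha)
}

#' Tidy a correlation result
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return Long tibble `var1`, `var2`, `r`, `p`, `stars`.
#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy K-means co-expression modules
#'
#' @param x A `cluster_modules`.
#' @param ... Unused.
#' @return The gene-to-module assignment tibble.
#' @method tidy cluster_modules
#' @export
tidy.cluster_modules <- function(x, ...) x$assignment

#' @rdname tidy.cluster_modules
#' @method glance cluster_modules
#' @export
glance.cluster_modules <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignment), withinss = x$withinss,
         seed = x$seed)
}

#' Tidy a sample PCA
#'
#' @param x A `sample_pca`.
#' @param ... Unused.
#' @return The sample-score tibble with design metadata.
#' @method tidy sample_pca
#' @export
tidy.sample_pca <- function(x, ...) x$scores

#' @rdname tidy.sample_pca
#' @method glance sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained)
}
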