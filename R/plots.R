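#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar geom_text geom_abline labs theme_minimal
#'   scale_size_continuous facet_wrap
#' @export
ggplot2::autoplot

#' Plot a contour polyline
#'
#' @param contour Contour data frame (`x_mm`, `y_mm`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_contour <- function(contour, ...) {
  contour <- validate_contour(contour)
  ggplot(contour, aes(x = .data$x_mm, y = .data$y_mm)) +
    geom_line() +
    ggplot2::coord_fixed() +
    labs(x = "x (mm)", y = "y (mm)") +
    theme_minimal()
}

#' @method autoplot rugosity_contour
#' @export
autoplot.rugosity_contour <- function(object, ...) plot_contour(object, ...)

#' @method autoplot ri_regression
#' @export
autoplot.ri_regression <- function(object, ...) {
  ggplot(object$data, aes(x = .data$ri_percent, y = .data$sensory_level)) +
    geom_point(alpha = 0.4) +
    geom_abline(intercept = object$beta0, slope = object$beta1,
                colour = "firebrick") +
    labs(x = "Rugosity index (%)", y = "Sensory level",
         title = sprintf("R² = %.3f (n = %d)", object$r_squared,
                         object$n)) +
    theme_minimal()
}

#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.2) +
    geom_text(aes(y = .data$mean + .data$se, label = .data$letters),
              vjust = -0.5) +
    labs(x = "Rugosity level", y = object$indicator) +
    theme_minimal()
}

#' @method autoplot correlation_result
#' @export
autoplot.correlation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$var1, y = .data$var2)) +
    geom_point(aes(size = abs(.data$r), colour = .data$r)) +
    geom_text(aes(label = .data$stars), vjust = -1, size = 2.5) +
    scale_size_continuous(range = c(0.5, 6), limits = c(0, 1)) +
    ggplot2::scale_colour_gradient2(low = "steelblue", high = "firebrick",
                                    limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, size = "|r|", colour = "r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot cluster_modules
#' @export
autoplot.cluster_modules <- function(object, ...) {
  groups <- colnames(object$profiles)
  long <- as_tibble(object$profiles, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "group", values_to = "z") |>
    dplyr::left_join(object$assignment, by = "gene_id") |>
    dplyr::mutate(group = factor(.data$group, levels = groups))
  centers <- as_tibble(object$centers, rownames = "module") |>
    dplyr::mutate(module = as.integer(dplyr::row_number())) |>
    tidyr::pivot_longer(-"module", names_to = "group", values_to = "z") |>
    dplyr::mutate(group = factor(.data$group, levels = groups))
  ggplot(long, aes(x = .data$group, y = .data$z, group = .data$gene_id)) +
    geom_line(alpha = 0.15, colour = "grey60") +
    geom_line(data = centers, aes(group = .data$module), colour = "black",
              linewidth = 1) +
    facet_wrap(~module) +
    labs(x = NULL, y = "Standardized expression") +
    theme_minimal()
}

#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, ...) {
  ve <- 100 * object$var_explained
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            colour = .data$genotype,
                            shape = factor(.data$stage))) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.2f%%)", ve[1]),
         y = sprintf("PC2 (%.2f%%)", ve[2]),
         colour = "Genotype", shape = "Stage (DPA)") +
    theme_minimal()
}
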