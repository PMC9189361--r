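# ggplot2 autoplot methods for the package's result types.

#' Plot stage-wise expression-methylation scatter with fitted lines
#'
#' @param object A `cohort_table`.
#' @param x,y Column names to plot (default methylation rate vs miR-23).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_table <- function(object, x = "meth_rate", y = "mir23", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                       colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = x, y = y)
}

#' Plot group comparison as box + jitter
#'
#' @param object A `group_comparison`.
#' @param data The data frame the comparison was computed from.
#' @param group Grouping column name used in the comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_comparison <- function(object, data, group = "group", ...) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[object$value]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(
      subtitle = sprintf("one-way ANOVA F = %.2f, P = %.3g",
                         object$omnibus$statistic, object$omnibus$p_value))
}

#' Plot per-tumor F-values by group
#'
#' @param object A `regularity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regularity_report <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$f_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$f_value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(y = "F value (0 = circular)", x = NULL)
}

#' Plot per-site methylation rates
#'
#' @param object A `methylation_calls` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methylation_calls <- function(object, ...) {
  s <- site_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$site, y = .data$site_rate)) +
    ggplot2::geom_col(width = 2, fill = "grey30") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "CpG site offset (bp)", y = "methylation rate")
}

#' Plot a mask
#'
#' @param object A `tumor_mask`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tumor_mask <- function(object, ...) {
  d <- which(mask_matrix(object), arr.ind = TRUE)
  ggplot2::ggplot(tibble(row = d[, 1], col = d[, 2]),
                  ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
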