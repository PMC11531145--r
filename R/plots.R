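#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the model lattice ordered by log-likelihood
#'
#' @param object A `jsdm_lattice`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot jsdm_lattice
#' @export
autoplot.jsdm_lattice <- function(object, ...) {
  d <- tidy(object)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ll, y = .data$name,
                                  fill = .data$Cov)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "log-likelihood", y = NULL,
                  fill = "includes Cov",
                  title = "jSDM factor lattice") +
    ggplot2::theme_minimal()
}

#' Plot per-OTU factor attributions by guild
#'
#' @param object A `factor_attribution` (with guilds attached).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot factor_attribution
#' @export
autoplot.factor_attribution <- function(object, ...) {
  d <- object$llr
  p <- ggplot2::ggplot(d, ggplot2::aes(x = if ("guild" %in% names(d))
    .data$guild else "", y = .data$llr))
  p + ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-OTU log-likelihood ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a Mantel correlogram
#'
#' @param object A `mantel_correlogram`.
#' @param alpha Significance threshold on the FDR-adjusted p-values used to
#'   highlight classes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mantel_correlogram
#' @export
autoplot.mantel_correlogram <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$significant <- !is.na(d$q_value) & d$q_value < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_mid_m, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = "distance class midpoint (m)", y = "Mantel r",
                  shape = sprintf("q < %.2f", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the root-versus-soil habitat surface
#'
#' @param object A `habitat_points` tibble.
#' @param abundance Plot mean relative abundances instead of occurrence
#'   counts.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot habitat_points
#' @export
autoplot.habitat_points <- function(object, abundance = FALSE, ...) {
  if (abundance) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_log_rel_abund_soil,
                                         y = .data$mean_log_rel_abund_root)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "mean log10 relative abundance (soil)",
                    y = "mean log10 relative abundance (root)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$n_soil_detected,
                                         y = .data$n_root_detected)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "soil samples detected", y = "root samples detected") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of pair-level (two-dimensional) preference scores
#'
#' @param object A `two_dim_preference` or `preference_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot two_dim_preference
#' @export
autoplot.two_dim_preference <- function(object, ...) {
  sc <- if (inherits(object, "preference_result")) object$pair$score else object$score
  d <- tibble::as_tibble(as.table(sc), .name_repair = "minimal")
  names(d) <- c("otu_id", "plant", "score")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plant, y = .data$otu_id,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "2DP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' @method autoplot preference_result
#' @export
autoplot.preference_result <- autoplot.two_dim_preference

#' @importFrom rlang .data
NULL
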