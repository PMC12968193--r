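#' GGE biplot of an SREG decomposition
#'
#' Genotypes as points, environments as labelled arrows from the origin,
#' axes annotated with the variance fraction of each component.
#'
#' @param object an `sreg_fit` from [sreg()] or [sreg_decompose()].
#' @param label_lines label genotype points with their IDs.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sreg_fit
#' @export
autoplot.sreg_fit <- function(object, label_lines = FALSE, ...) {
  gs <- object$genotype_scores
  es <- object$env_scores
  # arrows drawn on the genotype-score scale
  sc <- max(abs(gs$PC1), abs(gs$PC2)) / max(abs(es$PC1), abs(es$PC2), 1e-12)
  es <- dplyr::mutate(es, PC1 = .data$PC1 * sc, PC2 = .data$PC2 * sc)
  p <- ggplot2::ggplot(gs, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2, colour = "grey30") +
    ggplot2::geom_segment(data = es,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          colour = "firebrick",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = es,
                       ggplot2::aes(label = .data$env),
                       colour = "firebrick", vjust = -0.5, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[1L]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * (if (length(object$var_fraction) > 1L)
                    object$var_fraction[2L] else 0)),
      title = sprintf("G+GE biplot (PC1+PC2: %.1f%%)",
                      100 * object$var_explained_12)) +
    ggplot2::theme_minimal()
  if (label_lines) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$line),
                                size = 2, vjust = -0.6, colour = "grey40")
  }
  p
}

#' Heatmap of between-environment correlations
#'
#' Tiles ordered by the average-linkage clustering stored in the
#' correlation table.
#'
#' @param object an `env_cor` from [env_correlations()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot env_cor
#' @export
autoplot.env_cor <- function(object, ...) {
  ord <- attr(object, "order")
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       env1 = factor(.data$env1, levels = ord),
                       env2 = factor(.data$env2, levels = ord))
  ggplot2::ggplot(dat, ggplot2::aes(.data$env1, .data$env2,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Environment correlations (%s)",
                                  attr(object, "trait"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Prediction-ability plot for cross-validation results
#'
#' Mean prediction ability per environment with one-SD error bars, one
#' panel per trait, coloured by model label.
#'
#' @param object a `cv_result` from [run_cv()] (or several row-bound).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  agg <- summarize_cv(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$env, y = .data$mean_r,
                                    fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "environment", y = "prediction ability (r)",
                  fill = "model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
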