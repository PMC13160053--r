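# ggplot2 displays. Colour scales and panel layout are presentation
# choices; the semantics live in the objects being plotted.

#' Heat map of a fitness landscape matrix
#'
#' Position x amino-acid tiles of weighted-mean selection coefficients.
#' With `significant_only = TRUE` (the conventional display) cells failing
#' the dual-replica significance rule are blanked.
#'
#' @param mat a `landscape_matrix` from [build_landscape_matrix()].
#' @param significant_only blank non-significant cells (default `TRUE`).
#' @param limits colour scale limits on s (default symmetric around 0 at
#'   the data range).
#' @return A ggplot object.
#' @export
plot_landscape <- function(mat, significant_only = TRUE, limits = NULL) {
  stopifnot(inherits(mat, "landscape_matrix"))
  df <- tidyr::expand_grid(position = mat$positions, mut_aa = mat$aa)
  df$s <- as.vector(t(mat$s))
  df$significant <- as.vector(t(mat$significant))
  if (significant_only) df$s[!df$significant] <- NA_real_
  if (is.null(limits)) {
    m <- max(abs(df$s), na.rm = TRUE)
    limits <- c(-m, m)
  }
  df$mut_aa <- factor(df$mut_aa, levels = mat$aa)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mut_aa, y = .data$position,
                                   fill = .data$s)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick3", mid = "white",
                                  high = "steelblue3", midpoint = 0,
                                  limits = limits, na.value = "grey92",
                                  name = "s") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "amino acid substitution", y = "position",
                  title = mat$condition) +
    ggplot2::theme_minimal()
}

#' Plot a distribution of fitness effects
#'
#' @param histogram histogram tibble from [dfe_summary()] or
#'   [dfe_shift_partition()] (optionally with `partition` / `condition`
#'   columns for facetting and colour).
#' @return A ggplot object.
#' @export
plot_dfe <- function(histogram) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$bin_mid, y = .data$count))
  if ("condition" %in% names(histogram)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$condition),
                               position = "identity", alpha = 0.55)
  } else {
    p <- p + ggplot2::geom_col(fill = "grey30")
  }
  if ("partition" %in% names(histogram)) {
    p <- p + ggplot2::facet_wrap(~partition, scales = "free_y")
  }
  p + ggplot2::labs(x = "selection coefficient", y = "mutations") +
    ggplot2::theme_minimal()
}

#' Scatter of fitness effects against predicted stability changes
#'
#' @param fit a `fitness_table` or aggregated substitution tibble.
#' @param ddg stability table from [read_ddg()].
#' @param positions optional position subset.
#' @return A ggplot object annotated with the Spearman rho.
#' @export
plot_stability <- function(fit, ddg, positions = NULL) {
  agg <- if (inherits(fit, "fitness_table")) {
    aggregate_substitutions(fit, per_replica = FALSE, classes = "missense")
  } else fit
  if (!is.null(positions)) agg <- agg[agg$position %in% positions, ]
  merged <- dplyr::inner_join(agg, ddg, by = c("position", "mut_aa"))
  res <- spearman_fitness_stability(agg, ddg, positions)
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$ddg, y = .data$s)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = expression(Delta * Delta * G ~ "(kcal/mol)"),
      y = "selection coefficient",
      subtitle = sprintf("Spearman rho = %.2f (n = %d)", res$rho, res$n)
    ) +
    ggplot2::theme_minimal()
}
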