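# ggplot2 displays for the main result types.

#' Volcano plot of Welch enrichment statistics
#'
#' -log10 P against log2 fold change with the selection cut-offs drawn as
#' dashed lines; ions passing both cuts are coloured by direction.
#'
#' @param volcano A `volcano_result` tibble from [volcano_welch()].
#' @param params A [selection_params()] supplying the cut-offs.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, params = selection_params()) {
  lfc <- log2(params$fc_thresh)
  df <- dplyr::mutate(
    tibble::as_tibble(volcano),
    status = dplyr::case_when(
      .data$p < params$p_thresh & .data$log2fc > lfc ~ "plant-enriched",
      .data$p < params$p_thresh & .data$log2fc < -lfc ~ "control-enriched",
      TRUE ~ "not selected"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neg_log10_p,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(params$p_thresh),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "plant-enriched" = "#1b9e77", "control-enriched" = "#d95f02",
      "not selected" = "grey70")) +
    ggplot2::labs(x = "log2 fold change (plant / control)",
                  y = "-log10 P (Welch)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pca_model <- function(object, components = c(1, 2),
                               labels = NULL, ...) {
  s <- object$scores[, components, drop = FALSE]
  df <- tibble::tibble(
    x = s[, 1], y = s[, 2],
    label = if (is.null(labels)) "sample" else as.character(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  object$explained_pct[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  object$explained_pct[components[2]]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plsda_model <- function(object, ...) {
  s <- object$scores
  df <- tibble::tibble(x = s[, 1],
                       y = if (ncol(s) > 1) s[, 2] else 0,
                       label = as.character(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "component 1", y = if (ncol(s) > 1) "component 2" else "",
      colour = NULL,
      title = sprintf("PLS-DA: R2 = %.3f, Q2 = %.3f", object$r2, object$q2)) +
    ggplot2::theme_minimal()
}

#' Rarefaction curves per sample
#'
#' @param rarefaction Tibble from [run_diversity_workflow()] (columns
#'   `sample_id`, `depth`, `mean_richness`, `sd_richness`).
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(rarefaction) {
  ggplot2::ggplot(rarefaction,
                  ggplot2::aes(.data$depth, .data$mean_richness,
                               colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_richness - .data$sd_richness,
                   ymax = .data$mean_richness + .data$sd_richness,
                   fill = .data$sample_id),
      alpha = 0.15, colour = NA) +
    ggplot2::labs(x = "subsampled reads", y = "observed OTU richness",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Metabolite-class composition bar chart
#'
#' @param composition Tibble from [class_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  df <- dplyr::mutate(composition,
                      met_class = stats::reorder(.data$met_class, .data$pct))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$met_class)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::labs(x = "% of counted ions", y = NULL) +
    ggplot2::theme_minimal()
}
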