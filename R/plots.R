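#' Volcano-style plot of a quantification table
#'
#' Combined z-score magnitude against log2 fold change, colored by the
#' regulation call; threshold lines are drawn from the table's recorded
#' thresholds.
#'
#' @param quant Flagged quantification tibble ([call_significance()]).
#' @return A ggplot object.
#' @export
plot_volcano <- function(quant) {
  th <- attr(quant, "thresholds") %||% default_thresholds(attr(quant, "level") %||% "phosphosite")
  ggplot2::ggplot(quant, ggplot2::aes(x = .data$log2fc, y = abs(.data$z),
                                      colour = .data$regulated)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = th$z, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(th$fc),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "combined log2 fold change", y = "|combined z|",
                  colour = "regulated") +
    ggplot2::theme_minimal()
}

#' Bar plot of kinase activity scores
#'
#' @param activity Activity-score tibble ([activity_scores()]).
#' @return A ggplot object.
#' @export
plot_activity <- function(activity) {
  th <- attr(activity, "threshold") %||% 0.53
  ggplot2::ggplot(activity,
                  ggplot2::aes(x = stats::reorder(.data$kinase, .data$score),
                               y = .data$score, fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-th, th), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "kinase activity score", fill = "call") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fold-enrichment bar plot of extracted motifs
#'
#' @param object A `phos_motifs` object ([motif_enrichment()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phos_motifs <- function(object, ...) {
  motifs <- tidy(object)
  ggplot2::ggplot(motifs,
                  ggplot2::aes(x = stats::reorder(.data$pattern,
                                                  .data$fold_enrichment),
                               y = .data$fold_enrichment)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_minimal()
}

#' Principal-component summary plot of per-channel fold-change vectors
#'
#' @param run A `phosflow_run` ([run_pipeline()]).
#' @return A ggplot object, or `NULL` when the run has no PCA summary.
#' @export
plot_fc_pca <- function(run) {
  if (is.null(run$pca)) return(NULL)
  ve <- run$pca$variance_explained
  ggplot2::ggplot(run$pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$sample_label,
                               shape = .data$experiment_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}
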