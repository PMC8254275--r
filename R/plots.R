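# ggplot2 views of results: CV metric distributions, ROC/PR curves, and
# similarity-matrix heatmaps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-validation metric distributions
#'
#' One boxplot per metric over the CV repeats.
#'
#' @param object An `anmda_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anmda_cv
#' @export
autoplot.anmda_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"repeat_id",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = NULL, y = "value",
      title = sprintf("%d-fold CV, %d repeat(s), %s%s",
                      object$protocol$n_folds, object$protocol$n_repeats,
                      object$protocol$learner,
                      if (object$protocol$smooth)
                        sprintf(" (ensemble S=%d)", object$protocol$n_subsets)
                      else " (single model)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC or precision-recall curve
#'
#' @inheritParams auroc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  ggplot2::ggplot(roc_curve(scores, labels),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUROC = %.4f", auroc(scores, labels))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
plot_pr <- function(scores, labels) {
  ggplot2::ggplot(pr_curve(scores, labels),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("AUPR = %.4f", aupr(scores, labels))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a labeled similarity matrix
#'
#' @param m A square labeled similarity matrix.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_similarity <- function(m, title = NULL) {
  df <- tibble::as_tibble(as.table(m), .name_repair = \(x) c("row", "col", "value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
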