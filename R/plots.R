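# ggplot2 visualisations for each result type.

#' @export
autoplot.meth_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(direction = "hv") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey50") +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)", title = "ROC curve"
    )
}

#' @export
autoplot.panel_metrics <- function(object, ...) {
  roc <- attr(object, "roc")
  if (is.null(roc)) abort("panel_metrics carries no ROC coordinates")
  autoplot(roc) +
    labs(subtitle = sprintf(
      "%s, %s: AUC = %.3f", object$scope[1], object$evaluation[1],
      object$auc[1]
    ))
}

#' @export
autoplot.gene_ranking <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot(d, aes(x = .data$vip, y = .data$gene_id, fill = .data$selected)) +
    geom_col() +
    labs(
      x = "Mean VIP over CV fits", y = NULL,
      title = "PLS variable importance", fill = "selected"
    )
}

#' @export
autoplot.cv_models <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$family, y = .data$auc)) +
    geom_boxplot() +
    geom_point(alpha = 0.5) +
    labs(
      x = NULL, y = "Out-of-fold AUC (one value per run)",
      title = "Cross-validated model comparison"
    )
}

#' Dendrogram plot of a cluster report
#'
#' @param report A `cluster_report`.
#' @param ... Passed to `plot.hclust`.
#' @return The report, invisibly.
#' @export
plot_dendrogram <- function(report, ...) {
  stopifnot(inherits(report, "cluster_report"))
  plot(report$hclust,
    hang = -1, xlab = "", sub = "",
    main = "Centroid-linkage clustering of samples", ...
  )
  invisible(report)
}
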