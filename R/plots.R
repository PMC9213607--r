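#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of DE results
#'
#' @param object A `telex_de` tibble.
#' @param p_max,lfc_min Guide lines for the selection thresholds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.telex_de <- function(object, p_max = 0.01, lfc_min = 1.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, y = -log10(.data$p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `telex_pca` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.telex_pca <- function(object, ...) {
  ve <- attr(object, "variance_explained")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * (ve[2] %||% 0)),
      subtitle = sprintf("group separation (mean silhouette): %.2f",
                         attr(object, "separation"))) +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted classifier
#'
#' @param object A `telex_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.telex_model <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("test AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Class-enrichment bar plot
#'
#' @param enrichment An enrichment tibble from [class_enrichment()] or
#'   [state_enrichment()].
#' @return A ggplot of log2 odds ratios, significant labels filled.
#' @export
plot_enrichment <- function(enrichment) {
  df <- enrichment |>
    mutate(log2_or = log2(pmax(.data$odds_ratio, 1e-3)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$log2_or,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "log2 odds ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
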