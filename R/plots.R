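# ggplot2 graphics for the result objects.

#' Plot a ROC curve
#'
#' @param roc Result of [roc_auc()].
#' @return A ggplot.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", roc$auc)) +
    ggplot2::theme_minimal()
}

#' Plot Gini feature importance
#'
#' @param object A `trained_forest`.
#' @param top_n Show only the `top_n` most important features.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trained_forest <- function(object, top_n = 34, ...) {
  d <- utils::head(rank_features_by_gini(object), top_n)
  d$feature <- stats::reorder(d$feature, d$importance)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean decrease in Gini index", y = NULL,
                  title = "Feature importance") +
    ggplot2::theme_minimal()
}

#' Plot per-repeat cross-validation metrics
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_repeat[c("repeat_", "acc", "sen", "spe", "auc")],
    -"repeat_", names_to = "metric")
  d$value <- ifelse(d$metric == "auc", d$value * 100, d$value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Percent (AUC x 100)",
                  title = "Repeated cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot a forward-feature-selection profile
#'
#' @param selection Result of [forward_feature_selection()].
#' @return A ggplot of OOB metrics against prefix size, with the
#'   recommended size marked.
#' @export
plot_forward_selection <- function(selection) {
  d <- tidyr::pivot_longer(
    selection$metrics[c("k", "acc", "sen", "spe", "mcc")],
    -"k", names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = selection$recommended_k,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Number of top-ranked features",
                  y = "OOB metric",
                  title = "Restricted forward feature selection") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot partial dependence profiles
#'
#' @param pd Result of [partial_dependence()] (rows for one or more
#'   features can be bound together).
#' @return A ggplot.
#' @export
plot_partial_dependence <- function(pd) {
  numeric_vals <- suppressWarnings(as.numeric(pd$value))
  pd$x <- if (anyNA(numeric_vals)) pd$value else numeric_vals
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$x, y = .data$mean_probability,
                                   group = .data$feature)) +
    (if (is.numeric(pd$x)) ggplot2::geom_line() else ggplot2::geom_col()) +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Mean predicted probability of TARGET",
                  title = "Partial dependence") +
    ggplot2::theme_minimal()
}
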