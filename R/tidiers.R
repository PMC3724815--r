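# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained forest
#'
#' One row per feature with its Gini importance rank.
#' @param x A `trained_forest`.
#' @param ... Unused.
#' @return A tibble: `rank`, `feature`, `importance`.
#' @export
tidy.trained_forest <- function(x, ...) {
  rank_features_by_gini(x)
}

#' One-row summary of a trained forest
#'
#' @param x A `trained_forest`.
#' @param ... Unused.
#' @return A tibble with tree count, mtry, feature count, OOB error
#'   (overall and per class).
#' @export
glance.trained_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees, mtry = x$mtry,
    n_features = length(x$features), n_train = x$n_train,
    oob_error = x$oob_error,
    oob_error_target = x$oob_class_error[["TARGET"]],
    oob_error_non_target = x$oob_class_error[["NON_TARGET"]])
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-metric summary tibble (`metric`, `mean`, `sd`).
#' @export
tidy.cv_result <- function(x, ...) x$summary

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with the metric means, the geometry and the
#'   repeat-averaged confusion counts.
#' @export
glance.cv_result <- function(x, ...) {
  m <- stats::setNames(x$summary$mean, x$summary$metric)
  cm <- x$mean_confusion
  tibble::tibble(acc = m[["acc"]], sen = m[["sen"]], spe = m[["spe"]],
                 mcc = m[["mcc"]], auc = m[["auc"]],
                 tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
                 k = x$k, repeats = x$repeats)
}
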