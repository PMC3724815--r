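#' Repeated stratified cross-validation of the classifier
#'
#' Default geometry is 10 folds x 5 repeats. Folds are stratified by
#' class; within each repeat the folds partition the rows and sizes
#' differ by at most one. Each fold's model is trained on the remaining
#' folds and scored on the held-out rows; per repeat the fold confusion
#' matrices are summed and the AUC is computed from the pooled
#' out-of-fold probabilities. Reported aggregates are the mean and
#' standard deviation over repeats, plus the repeat-averaged confusion
#' matrix (fractional counts).
#'
#' @param table Labelled feature table (n >= 2k).
#' @param cfg An [rf_config()].
#' @param k Folds per repeat.
#' @param repeats Repeats.
#' @param seed Integer seed for fold assignment and training.
#' @param features Features to train on.
#' @return An object of class `cv_result`: `per_fold`, `per_repeat`,
#'   `summary` tibbles, `mean_confusion` ([confusion_matrix()]) and
#'   `predictions` (pooled out-of-fold probabilities).
#' @export
repeated_cv <- function(table, cfg = rf_config(), k = 10, repeats = 5,
                        seed = cfg$rng_seed, features = feature_names()) {
  check_feature_table(table, require_label = TRUE)
  n <- nrow(table)
  if (n < 2 * k) stop("need at least 2k rows for ", k, "-fold CV")
  pos <- as_positive(table$label)

  per_fold <- list(); per_repeat <- list(); preds <- list()
  for (r in seq_len(repeats)) {
    folds <- withr::with_seed(seed + r, make_stratified_folds(pos, k))
    cm_sum <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    rep_prob <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      cfg_f <- cfg
      cfg_f$rng_seed <- cfg$rng_seed + 1000L * r + f
      fit <- train_forest(table[!test, , drop = FALSE], cfg_f,
                          features = features)
      pr <- predict(fit, table[test, , drop = FALSE])
      rep_prob[test] <- pr$probability
      truth <- pos[test]
      call_pos <- pr$class == "TARGET"
      cm <- c(tp = sum(call_pos & truth), tn = sum(!call_pos & !truth),
              fp = sum(call_pos & !truth), fn = sum(!call_pos & truth))
      cm_sum <- cm_sum + cm
      fold_auc <- if (any(truth) && !all(truth)) {
        roc_auc(pr$probability, truth)$auc
      } else NA_real_
      per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = f, n_test = sum(test)),
        metrics_from_confusion(do.call(confusion_matrix, as.list(cm))),
        tibble::tibble(auc = fold_auc))
    }
    rep_metrics <- metrics_from_confusion(do.call(confusion_matrix,
                                                  as.list(cm_sum)))
    per_repeat[[r]] <- dplyr::bind_cols(
      tibble::tibble(repeat_ = r), rep_metrics,
      tibble::tibble(auc = roc_auc(rep_prob, pos)$auc,
                     tp = cm_sum[["tp"]], tn = cm_sum[["tn"]],
                     fp = cm_sum[["fp"]], fn = cm_sum[["fn"]]))
    preds[[r]] <- tibble::tibble(repeat_ = r, row = seq_len(n),
                                 probability = rep_prob,
                                 label = table$label)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  per_repeat <- dplyr::bind_rows(per_repeat)
  metric_cols <- c("acc", "sen", "spe", "mcc", "auc")
  summary <- tidyr::pivot_longer(per_repeat[c("repeat_", metric_cols)],
                                 -"repeat_", names_to = "metric")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value),
                              .groups = "drop")
  summary <- summary[match(metric_cols, summary$metric), ]
  structure(
    list(per_fold = per_fold, per_repeat = per_repeat, summary = summary,
         mean_confusion = confusion_matrix(tp = mean(per_repeat$tp),
                                           tn = mean(per_repeat$tn),
                                           fp = mean(per_repeat$fp),
                                           fn = mean(per_repeat$fn)),
         predictions = dplyr::bind_rows(preds),
         k = k, repeats = repeats, seed = seed, features = features),
    class = "cv_result")
}

# Stratified fold labels: shuffle within class, then deal the combined
# order cyclically so per-class and total fold sizes differ by <= 1.
# Reshuffles (with a warning) in the unlikely event a training split
# lacks a class.
make_stratified_folds <- function(pos, k) {
  n <- length(pos)
  for (attempt in 1:10) {
    order_all <- c(sample(which(pos)), sample(which(!pos)))
    folds <- integer(n)
    folds[order_all] <- rep_len(seq_len(k), n)
    ok <- all(vapply(seq_len(k), function(f) {
      train <- folds != f
      any(pos[train]) && any(!pos[train])
    }, TRUE))
    if (ok) return(folds)
    warning("a training split lacked a class; reshuffling folds",
            call. = FALSE)
  }
  stop("could not stratify folds with both classes in every training split")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("repeated cross-validation: ", x$k, " folds x ", x$repeats,
      " repeats\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %8.3f (sd %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat("repeat-averaged confusion matrix:\n")
  print(x$mean_confusion)
  invisible(x)
}
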