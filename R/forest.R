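# Random-forest classifier over the duplex features: training, OOB
# estimates, Gini importance, mtry tuning with the one-standard-error
# rule, restricted forward feature selection and partial dependence.
# Tree growing is delegated to the randomForest package (bagged CART
# trees, per-node random feature subsets, majority vote); everything
# around it -- protocol, weighting convention, selection rules -- lives
# here.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500; the error rate of the
#'   ensemble stabilises well before that).
#' @param mtry Candidate features per split; `NULL` uses the classifier
#'   default, `floor(sqrt(p))`.
#' @param class_weights Named weights `c(TARGET = , NON_TARGET = )`
#'   acting as per-class misclassification costs in the vote
#'   aggregation: TARGET is called only when its vote fraction exceeds
#'   the cost-sensitive cutoff `w_NON / (w_NON + w_TARGET)`. Equal by
#'   default; [weighted_preset()] gives the imbalance-aware 0.3/0.7
#'   variant.
#' @param rng_seed Integer seed making training reproducible.
#' @param decision_threshold Probability cutoff: a row is called TARGET
#'   iff its predicted probability is strictly greater than this.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry = NULL,
                      class_weights = c(TARGET = 0.5, NON_TARGET = 0.5),
                      rng_seed = 1, decision_threshold = 0.5) {
  stopifnot(n_trees >= 1, all(class_weights > 0),
            all(c("TARGET", "NON_TARGET") %in% names(class_weights)),
            decision_threshold >= 0, decision_threshold <= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 class_weights = class_weights,
                 rng_seed = as.integer(rng_seed),
                 decision_threshold = decision_threshold),
            class = "rf_config")
}

#' Imbalance-aware class weights
#'
#' Misclassification penalties of 70% for the negative class and 30%
#' for the positive class.
#' @return Named weight vector for [rf_config()].
#' @export
weighted_preset <- function() c(TARGET = 0.3, NON_TARGET = 0.7)

# Effective probability cutoff for calling TARGET: the cost-sensitive
# threshold w_NON / (w_NON + w_TARGET) when class weights are unequal,
# otherwise the configured decision threshold (default 0.5, strict).
decision_cutoff <- function(cfg) {
  w <- cfg$class_weights
  if (w[["TARGET"]] != w[["NON_TARGET"]]) {
    w[["NON_TARGET"]] / (w[["NON_TARGET"]] + w[["TARGET"]])
  } else {
    cfg$decision_threshold
  }
}

# Feature matrix with position factors coerced to the fixed level set.
prepare_features <- function(table, features) {
  x <- as.data.frame(table[features])
  pos <- intersect(paste0("position_", 1:20), features)
  x[pos] <- lapply(x[pos], function(col)
    factor(as.character(col), levels = pair_category_levels()))
  x
}

#' Train the random-forest classifier
#'
#' Grows `cfg$n_trees` trees on bootstrap samples (~2/3 of the rows
#' each), with `mtry` randomly sampled candidate features per split.
#' Class weights enter the vote aggregation as misclassification costs.
#' Out-of-bag rows provide the error and vote estimates.
#'
#' @param table A labelled feature table (>= 10 rows, both classes).
#' @param cfg An [rf_config()].
#' @param features Feature names to train on (default all 34).
#' @return An object of class `trained_forest`: the ensemble plus
#'   `oob_error` (overall and per class), `oob_votes`, `gini_importance`
#'   and a config snapshot.
#' @export
train_forest <- function(table, cfg = rf_config(),
                         features = feature_names()) {
  check_feature_table(table, require_label = TRUE)
  if (nrow(table) < 10L) stop("need at least 10 training rows")
  y <- factor(as.character(table$label), levels = c("NON_TARGET", "TARGET"))
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  p <- length(features)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(p))) else as.integer(cfg$mtry)
  if (mtry > p) stop("mtry (", mtry, ") exceeds number of features (", p, ")")
  x <- prepare_features(table, features)
  # Misclassification penalties enter the vote aggregation: calling
  # TARGET must beat the expected cost of a false positive, i.e. the
  # vote cutoff for TARGET is w_NON / (w_NON + w_TARGET) (0.5 when the
  # weights are equal, matching the strict > 0.5 rule).
  cutoff <- rev(cfg$class_weights[c("NON_TARGET", "TARGET")])
  cutoff <- unname(cutoff) / sum(cutoff)
  names(cutoff) <- c("NON_TARGET", "TARGET")
  rf <- withr::with_seed(cfg$rng_seed,
    randomForest::randomForest(x = x, y = y, ntree = cfg$n_trees,
                               mtry = mtry, cutoff = cutoff))
  imp <- rf$importance[, "MeanDecreaseGini"]
  structure(
    list(rf = rf, features = features,
         config = cfg, mtry = mtry,
         oob_error = unname(rf$err.rate[cfg$n_trees, "OOB"]),
         oob_class_error = c(
           NON_TARGET = unname(rf$err.rate[cfg$n_trees, "NON_TARGET"]),
           TARGET = unname(rf$err.rate[cfg$n_trees, "TARGET"])),
         oob_votes = rf$votes[, "TARGET"],
         oob_predicted = rf$predicted,
         gini_importance = imp,
         n_train = nrow(table)),
    class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat("trained_forest: ", x$config$n_trees, " trees, mtry ", x$mtry,
      ", ", length(x$features), " features, ", x$n_train, " rows\n",
      "OOB error ", sprintf("%.3f", x$oob_error),
      " (TARGET ", sprintf("%.3f", x$oob_class_error[["TARGET"]]),
      ", NON_TARGET ", sprintf("%.3f", x$oob_class_error[["NON_TARGET"]]),
      ")\n", sep = "")
  invisible(x)
}

#' Predict target probabilities for new rows
#'
#' The probability is the fraction of trees voting TARGET; the hard
#' class is TARGET iff that probability is strictly greater than the
#' decision threshold (a row at exactly the threshold is NON_TARGET).
#'
#' @param object A `trained_forest`.
#' @param table A feature table with the training schema.
#' @param ... Unused.
#' @return A tibble with `pair_id` (when present), `probability` and
#'   `class`.
#' @export
predict.trained_forest <- function(object, table, ...) {
  missing <- setdiff(object$features, names(table))
  if (length(missing) > 0L) {
    stop("feature table is missing training feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- prepare_features(table, object$features)
  votes <- stats::predict(object$rf, newdata = x, type = "vote",
                          norm.votes = TRUE)
  prob <- unname(votes[, "TARGET"])
  thr <- decision_cutoff(object$config)
  out <- tibble::tibble(
    probability = prob,
    class = factor(ifelse(prob > thr, "TARGET", "NON_TARGET"),
                   levels = c("NON_TARGET", "TARGET")))
  if ("pair_id" %in% names(table)) {
    out <- dplyr::bind_cols(tibble::tibble(pair_id = table$pair_id), out)
  }
  out
}

#' Tune mtry by resampled AUC with the one-standard-error rule
#'
#' For each grid value, repeated stratified cross-validation yields a
#' mean and standard error of the AUC. The chosen value is the smallest
#' mtry whose mean AUC is within one standard error of the best mean --
#' the simplest model statistically indistinguishable from the optimum.
#'
#' @param table Labelled feature table.
#' @param cfg An [rf_config()].
#' @param grid Candidate mtry values; default `{2, floor(sqrt(p)),
#'   floor(p/3), floor(p/2)}`. Values exceeding the feature count are
#'   dropped with a warning.
#' @param features Features in play.
#' @param k,repeats Cross-validation geometry (default 10-fold, 5
#'   repeats).
#' @return A list with `mtry` (chosen) and `profile` (tibble of mtry,
#'   mean_auc, se_auc).
#' @export
tune_mtry <- function(table, cfg = rf_config(), grid = NULL,
                      features = feature_names(), k = 10, repeats = 5) {
  p <- length(features)
  if (is.null(grid)) {
    grid <- unique(pmax(1L, c(2L, floor(sqrt(p)), floor(p / 3), floor(p / 2))))
  }
  if (length(grid) == 0L) stop("empty mtry grid")
  drop <- grid > p
  if (any(drop)) {
    warning("dropping mtry value(s) exceeding feature count: ",
            paste(grid[drop], collapse = ", "), call. = FALSE)
    grid <- grid[!drop]
  }
  grid <- sort(unique(as.integer(grid)))
  profile <- purrr::map_dfr(grid, function(m) {
    cfg_m <- cfg
    cfg_m$mtry <- m
    cv <- repeated_cv(table, cfg_m, k = k, repeats = repeats,
                      features = features, seed = cfg$rng_seed)
    aucs <- cv$per_fold$auc
    aucs <- aucs[!is.na(aucs)]
    tibble::tibble(mtry = m, mean_auc = mean(aucs),
                   se_auc = if (length(aucs) > 1) {
                     stats::sd(aucs) / sqrt(length(aucs))
                   } else 0)
  })
  list(mtry = choose_mtry_one_se(profile), profile = profile)
}

#' One-standard-error choice from a tuning profile
#'
#' Smallest `mtry` whose mean AUC is within one standard error of the
#' best mean.
#'
#' @param profile Tibble with `mtry`, `mean_auc`, `se_auc`.
#' @return The chosen mtry value.
#' @export
choose_mtry_one_se <- function(profile) {
  best <- which.max(profile$mean_auc)
  cutoff <- profile$mean_auc[best] - profile$se_auc[best]
  min(profile$mtry[profile$mean_auc >= cutoff])
}

#' Rank features by Gini importance
#'
#' Mean decrease in node impurity (Gini index) accumulated over all
#' splits of all trees, in non-increasing order; ties break by schema
#' order.
#'
#' @param forest A `trained_forest`.
#' @return A tibble with `rank`, `feature`, `importance`.
#' @export
rank_features_by_gini <- function(forest) {
  imp <- forest$gini_importance
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(rank = seq_along(imp),
                 feature = names(imp)[ord],
                 importance = unname(imp[ord]))
}

#' Restricted forward feature selection
#'
#' Trains one forest per prefix of a fixed relevance ranking (most
#' relevant first) and scores each on its out-of-bag predictions. The
#' recommended size is the prefix maximising OOB MCC (smallest k on
#' ties) -- the best balance between specificity and sensitivity.
#'
#' @param table Labelled feature table.
#' @param cfg An [rf_config()].
#' @param ranking Feature names in decreasing relevance, covering every
#'   feature to consider (e.g. from [rank_features_by_gini()]).
#' @return A list with `metrics` (tibble: one row per k with OOB acc,
#'   sen, spe, mcc) and `recommended_k`.
#' @export
forward_feature_selection <- function(table, cfg = rf_config(),
                                      ranking = NULL) {
  if (is.null(ranking)) {
    ranking <- rank_features_by_gini(train_forest(table, cfg))$feature
  }
  metrics <- purrr::map_dfr(seq_along(ranking), function(kk) {
    f <- train_forest(table, cfg, features = ranking[seq_len(kk)])
    cm <- oob_confusion(f, table)
    dplyr::bind_cols(tibble::tibble(k = kk, feature_added = ranking[kk]),
                     metrics_from_confusion(cm)[c("acc", "sen", "spe", "mcc")])
  })
  best <- which.max(metrics$mcc)
  list(metrics = metrics, recommended_k = metrics$k[best])
}

# OOB confusion matrix of a trained forest (majority-vote OOB classes).
oob_confusion <- function(forest, table) {
  truth <- as_positive(table$label)
  pred <- forest$oob_predicted == "TARGET"
  confusion_matrix(tp = sum(pred & truth), tn = sum(!pred & !truth),
                   fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Partial dependence of the predicted probability on one feature
#'
#' Marginal effect: for each level (categorical) or quantile-grid value
#' (numeric) v of the feature, the mean over all rows of the predicted
#' TARGET probability with the feature forced to v in every row.
#'
#' @param forest A `trained_forest`.
#' @param feature A feature in the training schema.
#' @param table Feature table supplying the background rows.
#' @param grid_size Number of quantile points for numeric features.
#' @return A tibble with `feature`, `value`, `mean_probability`.
#' @export
partial_dependence <- function(forest, feature, table, grid_size = 10) {
  if (!feature %in% forest$features) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  col <- table[[feature]]
  values <- if (is.factor(col) || is.character(col)) {
    levels(factor(as.character(col)))
  } else {
    unique(unname(stats::quantile(col, probs = seq(0, 1,
                                                   length.out = grid_size))))
  }
  probs <- vapply(values, function(v) {
    forced <- table
    forced[[feature]] <- if (is.numeric(col)) as.numeric(v) else v
    mean(predict(forest, forced)$probability)
  }, 0)
  tibble::tibble(feature = feature, value = values,
                 mean_probability = unname(probs))
}

#' Serialise a trained forest to disk
#'
#' Versioned container written with R serialisation; restore with
#' [read_model()].
#'
#' @param forest A `trained_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(forest, path) {
  stopifnot(inherits(forest, "trained_forest"))
  saveRDS(list(container_version = 1L, forest = forest), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$container_version)) {
    stop("not a serialised model container: ", path, call. = FALSE)
  }
  obj$forest
}
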