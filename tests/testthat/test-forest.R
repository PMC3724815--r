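cfg_fast <- function(...) rf_config(n_trees = 150, ...)

test_that("a cleanly separable table trains to near-zero OOB error", {
  tab <- make_signal_table(n = 400, shift = 6)
  f <- train_forest(tab, cfg_fast(rng_seed = 2))
  expect_lte(f$oob_error, 0.05)
  expect_length(f$gini_importance, 34L)
  expect_true(all(f$gini_importance >= 0))
  expect_gte(f$oob_error, 0)
  expect_lte(f$oob_error, 1)
})

test_that("training rejects degenerate inputs", {
  tab <- make_signal_table(n = 40)
  tab$label <- factor("TARGET", levels = c("NON_TARGET", "TARGET"))
  expect_error(train_forest(tab, cfg_fast()), "single class")
  tab2 <- make_signal_table(n = 8)
  expect_error(train_forest(tab2, cfg_fast()), "at least 10")
  tab3 <- make_signal_table(n = 40)
  expect_error(train_forest(tab3, cfg_fast(mtry = 40)), "exceeds")
})

test_that("permuted labels give chance-level OOB accuracy", {
  tab <- make_signal_table(n = 200, shift = 6, seed = 3)
  tab$label <- withr::with_seed(42, sample(tab$label))
  f <- train_forest(tab, cfg_fast(rng_seed = 3))
  majority <- max(table(tab$label)) / nrow(tab)
  expect_lte(abs((1 - f$oob_error) - majority), 0.05)
})

test_that("prediction is deterministic, schema-checked, strict at the threshold", {
  tab <- make_signal_table(n = 120, shift = 4)
  f <- train_forest(tab, cfg_fast(rng_seed = 5))
  pred <- predict(f, tab)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # duplicated row -> identical probability
  two <- predict(f, dplyr::bind_rows(tab[7, ], tab[7, ]))
  expect_equal(two$probability[1], two$probability[2])
  # separable signal orders the class means
  expect_gt(mean(pred$probability[tab$label == "TARGET"]),
            mean(pred$probability[tab$label == "NON_TARGET"]))
  # schema mismatch names the missing features
  expect_error(predict(f, tab[setdiff(names(tab), "mfe_seed")]), "mfe_seed")
  # a probability exactly at the threshold is NON_TARGET
  f_thr <- f
  f_thr$config$decision_threshold <- pred$probability[1]
  pred_thr <- predict(f_thr, tab[1, ])
  expect_equal(as.character(pred_thr$class), "NON_TARGET")
  # strictly above -> TARGET
  f_thr$config$decision_threshold <- pred$probability[1] - 1e-9
  expect_equal(as.character(predict(f_thr, tab[1, ])$class), "TARGET")
})

test_that("training is reproducible under a fixed seed", {
  tab <- make_signal_table(n = 100)
  f1 <- train_forest(tab, cfg_fast(rng_seed = 11))
  f2 <- train_forest(tab, cfg_fast(rng_seed = 11))
  expect_equal(predict(f1, tab)$probability, predict(f2, tab)$probability)
  expect_equal(f1$gini_importance, f2$gini_importance)
})

test_that("the one-SE rule picks the simplest near-optimal mtry", {
  profile <- tibble::tibble(mtry = c(2, 4, 6),
                            mean_auc = c(0.90, 0.88, 0.91),
                            se_auc = c(0.01, 0.01, 0.02))
  expect_equal(choose_mtry_one_se(profile), 2)
  profile$se_auc <- c(0.001, 0.001, 0.001)
  expect_equal(choose_mtry_one_se(profile), 6)
  tab <- make_signal_table(n = 80, shift = 4)
  expect_equal(tune_mtry(tab, cfg_fast(), grid = 1, k = 3, repeats = 1)$mtry, 1)
  expect_warning(
    tm <- tune_mtry(tab, cfg_fast(), grid = c(2, 50), k = 3, repeats = 1),
    "dropping")
  expect_equal(tm$mtry, 2)
  # one-SE choice never exceeds the empirical argmax
  tm2 <- tune_mtry(tab, cfg_fast(), grid = c(2, 5, 11), k = 3, repeats = 2)
  argmax <- tm2$profile$mtry[which.max(tm2$profile$mean_auc)]
  expect_lte(tm2$mtry, argmax)
})

test_that("Gini ranking recovers a planted signal and orders deterministically", {
  tab <- make_signal_table(n = 200, informative = "mfe_seed", shift = 5,
                           seed = 13)
  f <- train_forest(tab, cfg_fast(rng_seed = 13))
  rk <- rank_features_by_gini(f)
  expect_equal(nrow(rk), 34L)
  expect_equal(rk$feature[1], "mfe_seed")
  expect_true(all(diff(rk$importance) <= 0))
  # a constant feature is never split on: importance 0, ranked last
  tab$count_gap_seed <- 0
  f0 <- train_forest(tab, cfg_fast(rng_seed = 13))
  rk0 <- rank_features_by_gini(f0)
  expect_equal(rk0$importance[rk0$feature == "count_gap_seed"], 0)
  expect_equal(rk0$feature[34], "count_gap_seed")
})

test_that("forward selection profiles every prefix and finds small subsets", {
  informative <- c("mfe_seed", "count_gc_seed", "alignment_score")
  tab <- make_signal_table(n = 150, informative = informative, shift = 3,
                           seed = 7)
  f <- train_forest(tab, cfg_fast(rng_seed = 7))
  ranking <- rank_features_by_gini(f)$feature
  sel <- forward_feature_selection(tab, cfg_fast(rng_seed = 7), ranking)
  expect_equal(nrow(sel$metrics), 34L)
  expect_equal(sel$metrics$feature_added, ranking)
  expect_lte(sel$recommended_k, 8)
  # the full prefix equals a directly trained all-feature forest (same
  # seed, same feature order)
  direct <- train_forest(tab, cfg_fast(rng_seed = 7), features = ranking)
  cm <- mirforest:::oob_confusion(direct, tab)
  expect_equal(sel$metrics$acc[34], metrics_from_confusion(cm)$acc)
  expect_equal(sel$metrics$mcc[34], metrics_from_confusion(cm)$mcc)
})

test_that("partial dependence equals its brute-force recomputation", {
  tab <- make_signal_table(n = 60, informative = "count_gc_seed", shift = 4,
                           seed = 9)
  f <- train_forest(tab, cfg_fast(rng_seed = 9))
  pd <- partial_dependence(f, "count_gc_seed", tab, grid_size = 5)
  # explicit loop over rows x grid values
  for (r in seq_len(nrow(pd))) {
    probs <- vapply(seq_len(nrow(tab)), function(i) {
      row <- tab[i, ]
      row$count_gc_seed <- pd$value[r]
      predict(f, row)$probability
    }, 0)
    expect_equal(pd$mean_probability[r], mean(probs))
  }
  # planted monotone effect -> non-decreasing profile
  expect_true(all(diff(pd$mean_probability) >= -1e-9))
  # categorical feature: one value per level present
  pdc <- partial_dependence(f, "position_2", tab)
  expect_setequal(pdc$value, levels(droplevels(tab$position_2)))
  expect_error(partial_dependence(f, "bogus", tab), "unknown feature")
})

test_that("zero-importance features have flat partial dependence", {
  tab <- make_signal_table(n = 80, informative = "mfe_seed", shift = 6,
                           seed = 15)
  tab$count_gap_total <- 1  # constant: never used by any split
  f <- train_forest(tab, cfg_fast(rng_seed = 15))
  pd <- partial_dependence(f, "count_gap_total", tab, grid_size = 4)
  expect_lt(diff(range(pd$mean_probability)), 1e-6)
})

test_that("raising the negative-class weight does not hurt specificity", {
  spes <- vapply(1:3, function(s) {
    tab <- make_signal_table(n = 200, shift = 1.2, seed = s)
    test <- make_signal_table(n = 200, shift = 1.2, seed = s + 100)
    spe_of <- function(w) {
      f <- train_forest(tab, cfg_fast(rng_seed = s, class_weights = w))
      pred <- predict(f, test)
      cmn <- table(pred$class, test$label)
      cmn["NON_TARGET", "NON_TARGET"] / sum(test$label == "NON_TARGET")
    }
    spe_of(c(TARGET = 0.2, NON_TARGET = 0.8)) -
      spe_of(c(TARGET = 0.5, NON_TARGET = 0.5))
  }, 0)
  expect_gte(mean(spes), 0)
})

test_that("models round-trip through the serialised container", {
  tab <- make_signal_table(n = 60)
  f <- train_forest(tab, cfg_fast())
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(f, path)
  back <- read_model(path)
  expect_equal(predict(back, tab)$probability, predict(f, tab)$probability)
  saveRDS(list(oops = 1), path)
  expect_error(read_model(path), "container")
})

test_that("tidy and glance summarise a forest", {
  tab <- make_signal_table(n = 60)
  f <- train_forest(tab, cfg_fast())
  expect_equal(nrow(tidy(f)), 34L)
  g <- glance(f)
  expect_equal(g$n_features, 34L)
  expect_equal(g$n_trees, 150L)
})
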