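# The 34-feature schema computed from each accepted duplex alignment:
# 2 alignment features, 1 thermodynamic, 5 structural counts, 20 nominal
# position features and 6 seed-region features (seed = columns 2-8 from
# the miRNA 5' end).

feature_schema_names <- c(
  "alignment_score", "alignment_length", "mfe_total",
  "count_gc_total", "count_au_total", "count_gu_total",
  "count_gap_total", "count_mismatch_total",
  paste0("position_", 1:20),
  "mfe_seed", "count_gc_seed", "count_au_seed", "count_gu_seed",
  "count_gap_seed", "count_mismatch_seed")

numeric_feature_names <- setdiff(feature_schema_names,
                                 paste0("position_", 1:20))

#' Names of the 34 duplex features
#'
#' @return Character vector of the 34 feature names, in schema order.
#' @export
feature_names <- function() feature_schema_names

#' Named feature subsets
#'
#' `"all"` is the full 34-feature schema. `"cat1"` to `"cat5"` are the
#' five feature categories (alignment, thermodynamic, structural,
#' seed-related, position-based, of sizes 2/1/5/6/20). `"top12"` is the
#' 12-feature subset with the greatest impact on predictive accuracy,
#' and `"seed_window"` collects every feature whose information is
#' confined to seed columns 2--8 (the six seed features plus positions
#' 2--8).
#'
#' @param preset One of `"all"`, `"top12"`, `"cat1"`..`"cat5"`,
#'   `"seed_window"`.
#' @return Character vector of feature names.
#' @export
feature_subset <- function(preset = c("all", "top12", "cat1", "cat2", "cat3",
                                      "cat4", "cat5", "seed_window")) {
  preset <- match.arg(preset)
  switch(preset,
    all = feature_schema_names,
    cat1 = c("alignment_score", "alignment_length"),
    cat2 = "mfe_total",
    cat3 = c("count_gc_total", "count_au_total", "count_gu_total",
             "count_gap_total", "count_mismatch_total"),
    cat4 = c("mfe_seed", "count_gc_seed", "count_au_seed", "count_gu_seed",
             "count_gap_seed", "count_mismatch_seed"),
    cat5 = paste0("position_", 1:20),
    top12 = c("alignment_score", "mfe_total", "count_gc_total",
              "count_au_total", "position_2", "position_4", "position_6",
              "position_7", "mfe_seed", "count_gc_seed", "count_au_seed",
              "count_gu_seed"),
    seed_window = c(paste0("position_", 2:8), "mfe_seed", "count_gc_seed",
                    "count_au_seed", "count_gu_seed", "count_gap_seed",
                    "count_mismatch_seed"))
}

#' Extract the 34 duplex features from one alignment
#'
#' Counts are taken over all L alignment columns; seed features over
#' columns 2--8; `position_k` is the pairing category of column k for
#' k <= min(L, 20), and the distinguished level `ABSENT` beyond the end
#' of a short alignment. Energies come from the thermodynamic model.
#'
#' @param alignment A `duplex_alignment` with at least 8 columns.
#' @param model An [energy_model()].
#' @return A one-row tibble with the 34 features (positions as factors
#'   over the six category levels).
#' @export
extract_features <- function(alignment, model = energy_model()) {
  L <- alignment$length
  if (L < 8L) stop("alignment has fewer than 8 columns; seed undefined")
  categories <- alignment$categories
  count <- function(idx, cat) sum(categories[idx] == cat)
  total <- seq_len(L)
  seed <- 2:8
  pos <- c(categories[seq_len(min(L, 20L))],
           rep("ABSENT", max(0L, 20L - L)))
  pos <- lapply(pos, factor, levels = pair_category_levels())
  names(pos) <- paste0("position_", 1:20)
  out <- tibble::tibble(
    alignment_score = as.numeric(alignment$score),
    alignment_length = as.numeric(L),
    mfe_total = as.numeric(if (!is.na(alignment$mfe)) alignment$mfe
                           else duplex_mfe(alignment, model)),
    count_gc_total = count(total, "GC_MATCH"),
    count_au_total = count(total, "AU_MATCH"),
    count_gu_total = count(total, "GU_WOBBLE"),
    count_gap_total = count(total, "GAP"),
    count_mismatch_total = count(total, "MISMATCH"),
    !!!pos,
    mfe_seed = as.numeric(seed_mfe(alignment, model)),
    count_gc_seed = count(seed, "GC_MATCH"),
    count_au_seed = count(seed, "AU_MATCH"),
    count_gu_seed = count(seed, "GU_WOBBLE"),
    count_gap_seed = count(seed, "GAP"),
    count_mismatch_seed = count(seed, "MISMATCH"))
  out[feature_schema_names]
}

#' Extract features for a list of alignments
#'
#' @param alignments List of `duplex_alignment` objects.
#' @param model An [energy_model()].
#' @param ids Optional row identifiers (default built from the
#'   alignments' miRNA/target ids).
#' @return A feature table: tibble with `pair_id` plus the 34 features.
#' @export
extract_feature_table <- function(alignments, model = energy_model(),
                                  ids = NULL) {
  if (inherits(alignments, "duplex_alignment")) alignments <- list(alignments)
  if (is.null(ids)) {
    ids <- vapply(alignments, function(a)
      paste0(a$mirna_id, "~", a$target_id), "")
    ids <- make.unique(ids, sep = "#")
  }
  feats <- purrr::map_dfr(alignments, extract_features, model = model)
  dplyr::bind_cols(tibble::tibble(pair_id = ids), feats)
}

#' Standardise the numeric features of a feature table
#'
#' Numeric features are centred and scaled to mean 0, sd 1 per column;
#' nominal position features are untouched. The fitted parameters are
#' attached so the identical transform can be applied to new data.
#'
#' @param table A feature table.
#' @param params Optional scaling parameters from a previous call (a
#'   tibble with `feature`, `center`, `scale`), applied as-is.
#' @return The scaled table, with the parameters in attribute
#'   `"scaling"`.
#' @export
scale_features <- function(table, params = NULL) {
  num <- intersect(numeric_feature_names, names(table))
  if (length(num) == 0L) stop("no numeric feature columns present")
  if (is.null(params)) {
    center <- vapply(table[num], mean, 0)
    scale <- vapply(table[num], stats::sd, 0)
    if (any(scale == 0)) {
      warning("constant numeric column(s) scaled to zero: ",
              paste(num[scale == 0], collapse = ", "), call. = FALSE)
    }
    params <- tibble::tibble(feature = num, center = center, scale = scale)
  } else {
    stopifnot(all(num %in% params$feature))
    params <- params[match(num, params$feature), ]
  }
  for (i in seq_along(num)) {
    s <- params$scale[i]
    table[[num[i]]] <-
      if (s == 0) rep(0, nrow(table))
      else (table[[num[i]]] - params$center[i]) / s
  }
  attr(table, "scaling") <- params
  table
}

#' Invert a feature scaling
#'
#' @param table A scaled feature table.
#' @param params Scaling parameters (taken from the table's `"scaling"`
#'   attribute when missing).
#' @return The table on the original scale.
#' @export
unscale_features <- function(table, params = attr(table, "scaling")) {
  stopifnot(!is.null(params))
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    if (f %in% names(table)) {
      table[[f]] <- table[[f]] * params$scale[i] + params$center[i]
    }
  }
  attr(table, "scaling") <- NULL
  table
}

#' Pearson correlation of the numeric features
#'
#' @param table A feature table with at least 3 rows.
#' @return Symmetric correlation matrix over the 14 numeric features,
#'   unit diagonal; rows/columns of zero-variance features are `NA`.
#' @export
feature_correlation <- function(table) {
  if (nrow(table) < 3L) stop("need at least 3 rows")
  num <- intersect(numeric_feature_names, names(table))
  x <- as.matrix(table[num])
  sds <- apply(x, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(x))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- ifelse(sds > 0, 1, NA_real_)
  cm
}
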