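# Feature-table TSV dialect: tab-separated, fixed header naming all 34
# features in schema order (snake_case), preceded by pair_id; a trailing
# `label` column (TARGET/NON_TARGET) is present iff the table is
# labelled. Bit-stable column order makes files diffable in tests.

#' Write a feature table to TSV
#'
#' @param table A feature table (tibble with `pair_id`, the 34 features,
#'   and optionally `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  cols <- c("pair_id", feature_schema_names,
            if ("label" %in% names(table)) "label")
  out <- table[cols]
  pos <- intersect(paste0("position_", 1:20), names(out))
  out[pos] <- lapply(out[pos], as.character)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' Round-trips [write_feature_table()] exactly, including column order,
#' position factor levels and label presence.
#'
#' @param path Path to a TSV written by [write_feature_table()].
#' @return A feature table tibble.
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("pair_id", feature_schema_names)
  unknown <- setdiff(names(tab), c(expected, "label"))
  if (length(unknown) > 0L) {
    stop("unknown column(s) in feature table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(expected, names(tab))
  if (length(missing) > 0L) {
    stop("feature table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- paste0("position_", 1:20)
  tab[pos] <- lapply(tab[pos], factor, levels = pair_category_levels())
  if ("label" %in% names(tab)) {
    tab$label <- factor(tab$label, levels = c("NON_TARGET", "TARGET"))
  }
  check_feature_table(tab)
  tab
}

# Shared validation: schema complete, labels all-or-none and valid.
check_feature_table <- function(table, require_label = FALSE) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(feature_schema_names, names(table))
  if (length(missing) > 0L) {
    stop("feature table missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("label" %in% names(table)) {
    lab <- as.character(table$label)
    if (anyNA(lab) || !all(lab %in% c("TARGET", "NON_TARGET"))) {
      stop("labels must all be TARGET or NON_TARGET", call. = FALSE)
    }
  } else if (require_label) {
    stop("feature table has no label column", call. = FALSE)
  }
  invisible(table)
}
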