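#' Align a miRNA against a candidate target
#'
#' Runs a Smith--Waterman local alignment (affine gaps) of the miRNA
#' (5'->3') against the reverse of the target sequence, so that alignment
#' columns read the target 3'->5' -- the antiparallel geometry of an
#' RNA:RNA duplex. The pairing matrix is the miRanda scheme (+5 G:C,
#' +5 A:U, +2 G:U wobble, -3 otherwise). Candidate sites are retained
#' only if they (a) score at least `cfg$score_threshold`, (b) pass the
#' four empirical binding-site rules ([check_empirical_rules()]), and
#' (c) have duplex free energy at most `cfg$energy_threshold` under
#' `model`. Multiple non-overlapping sites on one target are found
#' greedily by descending score.
#'
#' @param mirna,target RNA strings (A/C/G/U; `T` is normalised to `U`),
#'   or single-row data frames with a `residues` column.
#' @param cfg An [align_config()].
#' @param model An [energy_model()] used for the energy threshold.
#' @param mirna_id,target_id Optional identifiers carried into results.
#' @return A list of `duplex_alignment` objects, ordered by score
#'   (descending). Each has fields `mirna_row`, `target_row` (gapped,
#'   target 3'->5'), `categories`, `score`, `length`, `target_start`,
#'   `target_end` (1-based, on the ungapped target 5'->3'), and `mfe`
#'   (kcal/mol). Use [alignment_tbl()] to flatten to a tibble.
#' @export
align_duplex <- function(mirna, target, cfg = align_config(),
                         model = energy_model(),
                         mirna_id = "mirna", target_id = "target") {
  if (is.data.frame(mirna)) {
    if (nrow(mirna) != 1L) stop("`mirna` must be a single sequence")
    if ("id" %in% names(mirna)) mirna_id <- mirna$id
    mirna <- mirna$residues
  }
  if (is.data.frame(target)) {
    if (nrow(target) != 1L) stop("`target` must be a single sequence")
    if ("id" %in% names(target)) target_id <- target$id
    target <- target$residues
  }
  mirna <- normalize_rna(mirna, "miRNA sequence")
  target <- normalize_rna(target, "target sequence")
  rtarget <- str_rev(target)
  tlen <- nchar(target)

  mask <- rep(FALSE, tlen)
  hits <- list()
  for (k in seq_len(cfg$max_sites)) {
    raw <- .sw_align(mirna, rtarget, cfg$match_gc, cfg$match_au,
                     cfg$wobble_gu, cfg$mismatch, cfg$gap_open,
                     cfg$gap_extend, mask)
    if (!isTRUE(raw$found) || raw$score < cfg$score_threshold) break
    # claim the region regardless of filtering outcome, so the next
    # iteration moves on to a different site
    mask[raw$rtarget_start:raw$rtarget_end] <- TRUE
    aln <- new_duplex_alignment(raw, tlen, mirna_id, target_id)
    ok <- check_empirical_rules(aln)$accept
    if (!ok) next
    aln$mfe <- duplex_mfe(aln, model)
    if (aln$mfe > cfg$energy_threshold) next
    hits[[length(hits) + 1L]] <- aln
  }
  hits[order(vapply(hits, `[[`, 0, "score"), decreasing = TRUE)]
}

# Build a duplex_alignment from the raw DP result. Coordinates on the
# reversed target are converted to 1-based coordinates on the original
# (5'->3') target.
new_duplex_alignment <- function(raw, target_length, mirna_id, target_id) {
  mcols <- strsplit(raw$mirna_row, "")[[1]]
  tcols <- strsplit(raw$target_row, "")[[1]]
  structure(
    list(mirna_id = mirna_id, target_id = target_id,
         mirna_row = raw$mirna_row, target_row = raw$target_row,
         categories = classify_column(mcols, tcols),
         score = raw$score, length = length(mcols),
         target_start = target_length - raw$rtarget_end + 1L,
         target_end = target_length - raw$rtarget_start + 1L,
         mirna_start = raw$mirna_start, mirna_end = raw$mirna_end,
         mfe = NA_real_),
    class = "duplex_alignment")
}

#' Construct a duplex alignment from its two gapped rows
#'
#' Mostly useful for fixtures and for refining externally produced
#' alignment reports: categories are inferred per column from the residue
#' rows, and the score is recomputed under `cfg`.
#'
#' @param mirna_row Gapped miRNA row, 5'->3'.
#' @param target_row Gapped target row, 3'->5' (as displayed).
#' @param target_start,target_end 1-based inclusive coordinates on the
#'   ungapped target (5'->3'); optional.
#' @param score Alignment score; recomputed from the rows when missing.
#' @param cfg An [align_config()] for score recomputation.
#' @param mirna_id,target_id Identifiers.
#' @return A `duplex_alignment`.
#' @export
duplex_alignment <- function(mirna_row, target_row, target_start = NA_integer_,
                             target_end = NA_integer_, score = NULL,
                             cfg = align_config(), mirna_id = "mirna",
                             target_id = "target") {
  if (nchar(mirna_row) != nchar(target_row)) {
    stop("aligned rows differ in length (", nchar(mirna_row), " vs ",
         nchar(target_row), ")", call. = FALSE)
  }
  mcols <- strsplit(toupper(mirna_row), "")[[1]]
  tcols <- strsplit(toupper(target_row), "")[[1]]
  aln <- structure(
    list(mirna_id = mirna_id, target_id = target_id,
         mirna_row = paste(mcols, collapse = ""),
         target_row = paste(tcols, collapse = ""),
         categories = classify_column(mcols, tcols),
         score = 0, length = length(mcols),
         target_start = as.integer(target_start),
         target_end = as.integer(target_end),
         mirna_start = NA_integer_, mirna_end = NA_integer_,
         mfe = NA_real_),
    class = "duplex_alignment")
  aln$score <- if (is.null(score)) score_alignment(aln, cfg) else score
  aln
}

#' @export
print.duplex_alignment <- function(x, ...) {
  pipes <- c(GC_MATCH = "|", AU_MATCH = "|", GU_WOBBLE = ":",
             MISMATCH = " ", GAP = " ")[x$categories]
  cat("duplex alignment ", x$mirna_id, " ~ ", x$target_id,
      " (score ", format(x$score), ", ", x$length, " columns",
      if (!is.na(x$mfe)) paste0(", ", format(x$mfe), " kcal/mol"), ")\n",
      sep = "")
  cat("  5' ", x$mirna_row, " 3' miRNA\n", sep = "")
  cat("     ", paste(pipes, collapse = ""), "\n", sep = "")
  cat("  3' ", x$target_row, " 5' target [",
      x$target_start, "-", x$target_end, "]\n", sep = "")
  invisible(x)
}

#' Flatten a list of duplex alignments to a tibble
#'
#' @param alignments A list of `duplex_alignment` objects (or a single
#'   one).
#' @return A tibble with one row per alignment.
#' @export
alignment_tbl <- function(alignments) {
  if (inherits(alignments, "duplex_alignment")) alignments <- list(alignments)
  purrr::map_dfr(alignments, function(a) {
    tibble::tibble(
      mirna_id = a$mirna_id, target_id = a$target_id,
      score = a$score, length = a$length,
      target_start = a$target_start, target_end = a$target_end,
      mfe = a$mfe, mirna_row = a$mirna_row, target_row = a$target_row,
      categories = paste(substr(a$categories, 1, 2), collapse = ","))
  })
}
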