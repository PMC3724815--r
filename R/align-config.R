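#' Alignment configuration
#'
#' Scoring and filtering parameters for the miRanda-style duplex aligner.
#' The pairing matrix scores +5 for G:C, +5 for A:U, +2 for the
#' non-canonical G:U wobble and -3 for every other residue combination.
#' Gap penalties are affine: a gap run of length k costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' Thresholds are deliberately permissive by default (score >= 35,
#' duplex free energy <= -7 kcal/mol, mirroring the canonical aligner's
#' shipped defaults on the unscaled matrix): the aligner's job is to keep
#' every site meeting the minimal requirements of a binding site and
#' leave the refinement to the classifier.
#'
#' @param match_gc,match_au,wobble_gu,mismatch Per-column scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param score_threshold Minimum alignment score S for a site to be kept.
#' @param energy_threshold Maximum duplex free energy (kcal/mol).
#' @param max_sites Maximum number of non-overlapping sites reported per
#'   miRNA/target pair.
#' @return An object of class `align_config`.
#' @export
align_config <- function(match_gc = 5, match_au = 5, wobble_gu = 2,
                         mismatch = -3, gap_open = -8, gap_extend = -2,
                         score_threshold = 35, energy_threshold = -7,
                         max_sites = 8L) {
  stopifnot(is.finite(score_threshold), is.finite(energy_threshold),
            gap_open <= 0, gap_extend <= 0, max_sites >= 1)
  structure(
    list(match_gc = match_gc, match_au = match_au, wobble_gu = wobble_gu,
         mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend,
         score_threshold = score_threshold,
         energy_threshold = energy_threshold,
         max_sites = as.integer(max_sites)),
    class = "align_config")
}

#' Pairing category of one alignment column
#'
#' @param mirna_char,target_char Single characters in `A/C/G/U/-`.
#' @return One of `"GC_MATCH"`, `"AU_MATCH"`, `"GU_WOBBLE"`, `"MISMATCH"`,
#'   `"GAP"`. A column gapped in both rows is an error.
#' @export
#' @examples
#' classify_column("G", "C")  # GC_MATCH
#' classify_column("G", "U")  # GU_WOBBLE
classify_column <- function(mirna_char, target_char) {
  n <- max(length(mirna_char), length(target_char))
  mirna_char <- rep_len(mirna_char, n)
  target_char <- rep_len(target_char, n)
  if (any(mirna_char == "-" & target_char == "-")) {
    stop("alignment column gapped in both rows", call. = FALSE)
  }
  pair <- paste0(mirna_char, target_char)
  out <- rep("MISMATCH", n)
  out[pair %in% c("GC", "CG")] <- "GC_MATCH"
  out[pair %in% c("AU", "UA")] <- "AU_MATCH"
  out[pair %in% c("GU", "UG")] <- "GU_WOBBLE"
  out[mirna_char == "-" | target_char == "-"] <- "GAP"
  out
}

#' Pairing-category levels
#'
#' The five per-column categories plus `ABSENT`, the level used for
#' position features beyond the end of a short alignment.
#' @return Character vector of the six levels.
#' @export
pair_category_levels <- function() {
  c("GC_MATCH", "AU_MATCH", "GU_WOBBLE", "MISMATCH", "GAP", "ABSENT")
}

#' Recompute an alignment score from its columns
#'
#' Sums the per-column pairing matrix contributions and applies affine gap
#' penalties over maximal gap runs. Used as the additivity check for the
#' dynamic-programming aligner, which must report the same value.
#'
#' @param alignment A `duplex_alignment` (see [align_duplex()]).
#' @param cfg An [align_config()].
#' @return Numeric score.
#' @export
score_alignment <- function(alignment, cfg = align_config()) {
  categories <- alignment$categories
  if (length(categories) == 0L) return(0)
  per_col <- c(GC_MATCH = cfg$match_gc, AU_MATCH = cfg$match_au,
               GU_WOBBLE = cfg$wobble_gu, MISMATCH = cfg$mismatch,
               GAP = 0)[categories]
  score <- sum(per_col)
  runs <- rle(categories == "GAP")
  gap_runs <- runs$lengths[runs$values]
  if (length(gap_runs) > 0L) {
    score <- score + sum(cfg$gap_open + (gap_runs - 1) * cfg$gap_extend)
  }
  unname(score)
}

#' Apply the four empirical binding-site rules
#'
#' Counting alignment columns from the 5' end of the miRNA:
#' (i) no mismatches at positions 2--4; (ii) fewer than five mismatches at
#' positions 3--12; (iii) at least one mismatch between positions 9 and
#' L-5; (iv) fewer than two mismatches in the last five positions. For
#' rule purposes a "mismatch" is a `MISMATCH` or `GAP` column; the G:U
#' wobble is positively scored and displayed as a pair, so it counts as
#' pairing. Alignments shorter than 14 columns cannot host all four
#' windows and are rejected with the distinct code `"too_short"`.
#'
#' @param alignment A `duplex_alignment`, or a character vector of
#'   pairing categories.
#' @return A list with `accept` (logical) and `violated` (character vector
#'   of rule ids among `"i"`, `"ii"`, `"iii"`, `"iv"`, or `"too_short"`).
#' @export
check_empirical_rules <- function(alignment) {
  categories <- if (is.character(alignment)) alignment else alignment$categories
  L <- length(categories)
  if (L < 14L) {
    return(list(accept = FALSE, violated = "too_short"))
  }
  mm <- categories %in% c("MISMATCH", "GAP")
  violated <- character()
  if (any(mm[2:4])) violated <- c(violated, "i")
  if (sum(mm[3:12]) >= 5L) violated <- c(violated, "ii")
  if (!any(mm[9:(L - 5L)])) violated <- c(violated, "iii")
  if (sum(mm[(L - 4L):L]) >= 2L) violated <- c(violated, "iv")
  list(accept = length(violated) == 0L, violated = violated)
}
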