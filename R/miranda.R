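# miRanda-style alignment report: plain-text hit blocks. The dialect
# written and parsed here is:
#
#   Scores for this hit:
#   >mir-1	gene-1	score	mfe	target_start target_end	length
#      Query:    5' UGAGGUAG--UAGGUUGUAUAGUU 3'
#                   |||||||   ||||||:|||||||
#      Ref:      3' ACUCCAUCGGAUCCAGCAUAUCAA 5'
#
# The Query row is the miRNA 5'->3', the Ref row the target site 3'->5'.
# Pairing categories are inferred from the two residue rows, never from
# the pipe row (which is informational). Unknown banner lines outside
# hit blocks are skipped, tolerating version headers of external runs.

#' Write alignments as a miRanda-style report
#'
#' @param alignments List of `duplex_alignment` objects.
#' @param path Output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_miranda_report <- function(alignments, path) {
  if (inherits(alignments, "duplex_alignment")) alignments <- list(alignments)
  pipes_for <- function(a) {
    paste(c(GC_MATCH = "|", AU_MATCH = "|", GU_WOBBLE = ":",
            MISMATCH = " ", GAP = " ")[a$categories], collapse = "")
  }
  lines <- unlist(lapply(alignments, function(a) {
    c("Scores for this hit:",
      paste0(">", a$mirna_id, "\t", a$target_id, "\t", format(a$score),
             "\t", format(a$mfe), "\t", a$target_start, " ", a$target_end,
             "\t", a$length),
      paste0("   Query:    5' ", a$mirna_row, " 3'"),
      paste0("                ", pipes_for(a)),
      paste0("   Ref:      3' ", a$target_row, " 5'"),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a miRanda-style alignment report
#'
#' @param text Report text: a file path, or a character vector of lines.
#' @param cfg An [align_config()], used only to recompute scores when a
#'   block omits one.
#' @return List of `duplex_alignment` objects, one per hit block.
#' @export
parse_miranda_output <- function(text, cfg = align_config()) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n"))
  starts <- grep("^\\s*Scores for this hit:", lines)
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[b]
    block <- lines[i:min(i + 5L, length(lines))]
    hdr <- grep("^>", block, value = TRUE)
    qline <- grep("^\\s*Query:", block, value = TRUE)
    rline <- grep("^\\s*Ref:", block, value = TRUE)
    if (length(hdr) < 1L || length(qline) < 1L || length(rline) < 1L) {
      stop("truncated hit block at block ", b, call. = FALSE)
    }
    fields <- strsplit(sub("^>", "", hdr[1L]), "\t")[[1]]
    if (length(fields) < 6L) stop("malformed header in hit block ", b,
                                  call. = FALSE)
    coords <- as.integer(strsplit(trimws(fields[5L]), "\\s+")[[1]])
    qrow <- sub(".*5'\\s+(\\S+)\\s+3'.*", "\\1", qline[1L])
    rrow <- sub(".*3'\\s+(\\S+)\\s+5'.*", "\\1", rline[1L])
    if (nchar(qrow) != nchar(rrow)) {
      stop("residue rows of unequal length in hit block ", b,
           " (", nchar(qrow), " vs ", nchar(rrow), ")", call. = FALSE)
    }
    aln <- duplex_alignment(
      mirna_row = qrow, target_row = rrow,
      target_start = coords[1L], target_end = coords[2L],
      score = as.numeric(fields[3L]), cfg = cfg,
      mirna_id = fields[1L], target_id = fields[2L])
    aln$mfe <- suppressWarnings(as.numeric(fields[4L]))
    out[[b]] <- aln
  }
  out
}
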