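#' Read RNA (or DNA) sequences from a FASTA file
#'
#' Reads a multi-record FASTA file and returns one row per record. Sequences
#' are normalised to the RNA alphabet: case is folded to upper case and `T`
#' is converted to `U` (NCBI mRNA records are DNA-alphabet; a message is
#' emitted when this happens). Any residue outside `A/C/G/U` after
#' normalisation is an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @param role Optional role for all records, `"MIRNA"` or `"TARGET"`.
#'   Mature miRNAs are expected to be roughly 22 nt; a miRNA outside
#'   15--30 nt triggers a warning, not an error.
#' @return A tibble with columns `id` (full header text) and `residues`
#'   (5'->3' RNA string), and a `role` column when `role` is given.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">m1", "tgaggtag"), fa)
#' read_fasta(fa)
read_fasta <- function(path, role = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- tibble::tibble(id = character(), residues = character())
    if (!is.null(role)) out$role <- character()
    return(out)
  }
  ids <- names(set)
  seqs <- unname(toupper(as.character(set)))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    message("DNA-alphabet input: converting T to U")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]],
         "' contains characters outside the A/C/G/U alphabet",
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("record '", ids[which(nchar(seqs) == 0L)[1L]], "' is empty",
         call. = FALSE)
  }
  out <- tibble::tibble(id = ids, residues = seqs)
  if (!is.null(role)) {
    role <- match.arg(role, c("MIRNA", "TARGET"))
    out$role <- role
    if (role == "MIRNA") {
      len <- nchar(out$residues)
      off <- len < 15L | len > 30L
      if (any(off)) {
        warning(sum(off), " miRNA record(s) outside the expected 15-30 nt ",
                "length range (mature miRNAs are ~22 nt)", call. = FALSE)
      }
    }
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `residues` (as returned
#'   by [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::RNAStringSet(seqs$residues)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Validate a single RNA string; returns the normalised string.
normalize_rna <- function(residues, what = "sequence") {
  residues <- toupper(residues)
  residues <- gsub("T", "U", residues, fixed = TRUE)
  if (nchar(residues) == 0L) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGU]", residues)) {
    stop(what, " contains characters outside A/C/G/U", call. = FALSE)
  }
  residues
}

# Reverse a residue string (no complementation).
str_rev <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Watson-Crick complement of an RNA string (no reversal).
rna_complement <- function(x) {
  chartr("ACGU", "UGCA", x)
}
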