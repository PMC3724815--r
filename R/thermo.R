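# Nearest-neighbour duplex energy model.
#
# The builtin backend scores a *given* alignment: it sums Turner-style
# stacking free energies over adjacent paired columns, plus a duplex
# initiation penalty and an optional per-interior-loop penalty. It is a
# pure function of the alignment columns, so the pipeline is fully
# testable with no external binary. The rnaduplex backend shells out to
# an RNAduplex-compatible engine and lets it refold the two (ungapped)
# subsequences.

the_stack_env <- new.env(parent = emptyenv())

# Stack table keyed "Q1Q2|T1T2": columns i,i+1 with miRNA residues Q1,Q2
# (5'->3') and target residues T1,T2 (3'->5'). Shipped as a versioned
# data file under extdata.
load_stack_table <- function() {
  if (!is.null(the_stack_env$stacks)) return(the_stack_env$stacks)
  path <- system.file("extdata", "nn_stacks_v1.tsv", package = "mirforest",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stacks <- stats::setNames(tab$dg_kcal_mol, tab$step)
  the_stack_env$stacks <- stacks
  stacks
}

#' Duplex energy model
#'
#' @param backend `"builtin"` (nearest-neighbour stack sum over the
#'   alignment, the default) or `"rnaduplex"` (delegate to an external
#'   RNAduplex-compatible engine, which refolds the ungapped
#'   subsequences).
#' @param initiation Duplex initiation penalty, kcal/mol (positive).
#' @param loop_penalty Penalty per interior loop (run of unpaired columns
#'   between paired columns), kcal/mol. Default 0: unpaired columns break
#'   stacking, which is already the dominant cost.
#' @param engine Command for the external backend.
#' @return An object of class `energy_model`. Temperature is fixed at
#'   37 degrees C (the parameter table is a 37 C table).
#' @export
energy_model <- function(backend = c("builtin", "rnaduplex"),
                         initiation = 0.5, loop_penalty = 0,
                         engine = "RNAduplex") {
  backend <- match.arg(backend)
  stopifnot(initiation > 0, loop_penalty >= 0)
  structure(list(backend = backend, initiation = initiation,
                 loop_penalty = loop_penalty, engine = engine,
                 temperature = 37),
            class = "energy_model")
}

paired_categories <- c("GC_MATCH", "AU_MATCH", "GU_WOBBLE")

#' Minimum free energy of an aligned duplex
#'
#' For the builtin backend the energy of the alignment is the sum of
#' nearest-neighbour stacking terms over adjacent paired columns plus the
#' initiation penalty and `loop_penalty` per interior loop. An alignment
#' with no paired column has no duplex: the value is 0 and carries a
#' `no_duplex` attribute. For the rnaduplex backend the two rows are
#' gap-stripped and refolded by the external engine.
#'
#' @param alignment A `duplex_alignment` (at least 2 columns).
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol (<= 0 for any alignment with at least
#'   one stacked Watson--Crick step under the builtin backend).
#' @export
duplex_mfe <- function(alignment, model = energy_model()) {
  if (alignment$length < 2L) stop("alignment has fewer than 2 columns")
  paired <- alignment$categories %in% paired_categories
  if (!any(paired)) {
    return(structure(0, no_duplex = TRUE))
  }
  if (model$backend == "rnaduplex") {
    return(rnaduplex_energy(alignment, model))
  }
  stacks <- load_stack_table()
  m <- strsplit(alignment$mirna_row, "")[[1]]
  t <- strsplit(alignment$target_row, "")[[1]]
  L <- alignment$length
  dg <- model$initiation
  if (L >= 2L) {
    i <- which(paired[-L] & paired[-1L])
    if (length(i) > 0L) {
      keys <- paste0(m[i], m[i + 1L], "|", t[i], t[i + 1L])
      vals <- stacks[keys]
      if (anyNA(vals)) stop("missing stack parameters: ",
                            paste(unique(keys[is.na(vals)]), collapse = ", "))
      dg <- dg + sum(vals)
    }
  }
  if (model$loop_penalty > 0) {
    first <- which(paired)[1L]
    last <- rev(which(paired))[1L]
    if (last > first) {
      runs <- rle(paired[first:last])
      dg <- dg + model$loop_penalty * sum(!runs$values)
    }
  }
  unname(dg)
}

#' Seed-region free energy
#'
#' [duplex_mfe()] applied to the sub-alignment of columns 2--8 (the seed
#' window, counting from the 5'-most miRNA position). Gap columns carry
#' no pairs; for the external backend the rows are gap-stripped before
#' folding.
#'
#' @inheritParams duplex_mfe
#' @return Free energy in kcal/mol.
#' @export
seed_mfe <- function(alignment, model = energy_model()) {
  if (alignment$length < 8L) {
    stop("alignment has fewer than 8 columns; seed region undefined")
  }
  duplex_mfe(subset_alignment(alignment, 2:8), model)
}

# Column subset of an alignment, preserving class and ids.
subset_alignment <- function(alignment, cols) {
  m <- strsplit(alignment$mirna_row, "")[[1]][cols]
  t <- strsplit(alignment$target_row, "")[[1]][cols]
  out <- alignment
  out$mirna_row <- paste(m, collapse = "")
  out$target_row <- paste(t, collapse = "")
  out$categories <- alignment$categories[cols]
  out$length <- length(cols)
  out$score <- NA_real_
  out
}

# External backend: gap-strip both rows, restore the target to 5'->3',
# and parse the trailing "(dg)" from the engine's output line.
rnaduplex_energy <- function(alignment, model) {
  mirna <- gsub("-", "", alignment$mirna_row, fixed = TRUE)
  target <- str_rev(gsub("-", "", alignment$target_row, fixed = TRUE))
  if (nchar(mirna) == 0L || nchar(target) == 0L) {
    return(structure(0, no_duplex = TRUE))
  }
  out <- tryCatch(
    system2(model$engine, args = "--noconv",
            input = paste(mirna, target, sep = "\n"),
            stdout = TRUE, stderr = FALSE),
    error = function(e) stop("failed to run external duplex engine '",
                             model$engine, "': ", conditionMessage(e),
                             call. = FALSE))
  hit <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(hit) == 0L) stop("could not parse energy from '",
                              model$engine, "' output", call. = FALSE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", hit[1L]))
}
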