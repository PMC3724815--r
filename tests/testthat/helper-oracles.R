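# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Best local-alignment score by top-down memoised recursion over
# (i, j, last-move). Backward formulation, written independently of the
# compiled forward Gotoh matrices. A gap run of length k costs
# gap_open + (k - 1) * gap_extend; the optimum never starts or ends in
# a gap.
oracle_best_local_score <- function(mirna, target_rev, cfg) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target_rev, "")[[1]]
  nm <- length(m); nt <- length(t)
  memo <- new.env(parent = emptyenv())
  pair_s <- function(a, b) {
    ab <- paste0(a, b)
    if (ab %in% c("GC", "CG")) cfg$match_gc
    else if (ab %in% c("AU", "UA")) cfg$match_au
    else if (ab %in% c("GU", "UG")) cfg$wobble_gu
    else cfg$mismatch
  }
  # best score of an alignment ending at (i, j) whose final column has
  # type `last` ("M" pair, "E" gap in miRNA row, "F" gap in target row)
  g <- function(i, j, last) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (last == "M") {
      prev <- max(0, g(i - 1, j - 1, "M"), g(i - 1, j - 1, "E"),
                  g(i - 1, j - 1, "F"))
      prev + pair_s(m[i], t[j])
    } else if (last == "E") {
      max(g(i, j - 1, "M") + cfg$gap_open, g(i, j - 1, "E") + cfg$gap_extend)
    } else {
      max(g(i - 1, j, "M") + cfg$gap_open, g(i - 1, j, "F") + cfg$gap_extend)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(nm)) for (j in seq_len(nt)) {
    best <- max(best, g(i, j, "M"))
  }
  best
}

# Brute-force AUC: probability over all positive-negative pairs that
# the positive scores higher, ties counted 1/2.
oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Alignment fixture from explicit rows.
fix_alignment <- function(mirna_row, target_row, ...) {
  duplex_alignment(mirna_row, target_row, ...)
}

# A synthetic labelled feature table with schema-valid columns but
# hand-controlled signal, for classifier unit tests.
make_signal_table <- function(n = 200, informative = "count_gc_seed",
                              shift = 3, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c("TARGET", "NON_TARGET"), length.out = n)
    tab <- tibble::tibble(pair_id = sprintf("row%03d", seq_len(n)))
    for (f in mirforest::feature_names()) {
      tab[[f]] <- if (grepl("^position_", f)) {
        factor(sample(c("GC_MATCH", "AU_MATCH", "MISMATCH"), n,
                      replace = TRUE),
               levels = mirforest::pair_category_levels())
      } else {
        stats::rnorm(n)
      }
    }
    for (f in informative) {
      tab[[f]] <- tab[[f]] + ifelse(label == "TARGET", shift, 0)
    }
    tab$label <- factor(label, levels = c("NON_TARGET", "TARGET"))
    tab
  })
}
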