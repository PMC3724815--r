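# Synthetic labelled miRNA/target pairs. Positives embed a binding site
# built from the reverse complement of the miRNA, near-perfect in the
# seed (columns 2-8) and partially paired in the 3' out-seed region --
# the pairing architecture of animal miRNA targeting. Negatives embed a
# weakly complementary site. Degradation is column-wise i.i.d. given the
# per-region probabilities; no indels are planted (gaps are rare in real
# duplexes and are exercised by dedicated fixtures). Every planted
# positive site carries one guaranteed central non-pairing column so a
# perfect-complement site cannot be rejected wholesale by the central
# mismatch requirement of the empirical rules.

#' Synthetic-data configuration
#'
#' @param n_pos,n_neg Numbers of positive / negative pairs.
#' @param mirna_length miRNA length (default 22 nt).
#' @param target_length Target length (default 500 nt; must exceed
#'   `mirna_length + 10`).
#' @param seed_complementarity_pos,seed_complementarity_neg Probability
#'   that a seed position (2--8) pairs Watson--Crick, per class
#'   (defaults 0.95 / 0.4).
#' @param out_seed_pairing_pos,out_seed_pairing_neg Pairing
#'   probabilities outside the seed (defaults 0.6 / 0.3).
#' @param wobble_rate Probability that a planted pair is G:U instead of
#'   Watson--Crick, where chemically possible (default 0.08).
#' @param gc_content GC content of flanking sequence (default 0.5).
#' @param rng_seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 200, n_neg = 200, mirna_length = 22,
                             target_length = 500,
                             seed_complementarity_pos = 0.95,
                             seed_complementarity_neg = 0.4,
                             out_seed_pairing_pos = 0.6,
                             out_seed_pairing_neg = 0.3,
                             wobble_rate = 0.08, gc_content = 0.5,
                             rng_seed = 1) {
  probs <- c(seed_complementarity_pos, seed_complementarity_neg,
             out_seed_pairing_pos, out_seed_pairing_neg, wobble_rate,
             gc_content)
  stopifnot(all(probs >= 0 & probs <= 1), n_pos >= 0, n_neg >= 0)
  if (target_length < mirna_length + 10) {
    stop("target_length must be at least mirna_length + 10")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 mirna_length = as.integer(mirna_length),
                 target_length = as.integer(target_length),
                 seed_complementarity_pos = seed_complementarity_pos,
                 seed_complementarity_neg = seed_complementarity_neg,
                 out_seed_pairing_pos = out_seed_pairing_pos,
                 out_seed_pairing_neg = out_seed_pairing_neg,
                 wobble_rate = wobble_rate, gc_content = gc_content,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

random_rna <- function(n, gc) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Build the target-site residues (5'->3') bound by `mirna`, degrading
# per-position pairing with the given probabilities.
plant_site <- function(mirna, seed_p, out_p, wobble_rate) {
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  seed_idx <- 2:min(8L, L)
  central <- sample(10:(L - 6L), 1L)  # guaranteed non-pairing column
  t <- character(L)
  for (i in seq_len(L)) {
    p_pair <- if (i %in% seed_idx) seed_p else out_p
    pair <- i != central && stats::runif(1) < p_pair
    if (pair) {
      t[i] <- rna_complement(m[i])
      if (m[i] %in% c("G", "U") && stats::runif(1) < wobble_rate) {
        t[i] <- if (m[i] == "G") "U" else "G"  # G:U wobble partner
      }
    } else {
      # any residue that does not pair with m[i] (wobble counts as pairing)
      partners <- switch(m[i], A = "U", C = "G", G = c("C", "U"),
                         U = c("A", "G"))
      t[i] <- sample(setdiff(c("A", "C", "G", "U"), partners), 1L)
    }
  }
  # site read 5'->3' on the target is the reverse of the per-column rows
  paste(rev(t), collapse = "")
}

#' Generate labelled miRNA/target sequence pairs
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per pair: `pair_id`, `label`,
#'   `mirna_id`, `mirna`, `target_id`, `target`, `site_start`,
#'   `site_end` (the planted site's coordinates). Deterministic given
#'   `cfg$rng_seed`.
#' @export
generate_pairs <- function(cfg = synthetic_config()) {
  withr::with_seed(cfg$rng_seed, {
    n <- cfg$n_pos + cfg$n_neg
    labels <- rep(c("TARGET", "NON_TARGET"), c(cfg$n_pos, cfg$n_neg))
    purrr::map_dfr(seq_len(n), function(i) {
      positive <- labels[i] == "TARGET"
      mirna <- random_rna(cfg$mirna_length, cfg$gc_content)
      site <- plant_site(
        mirna,
        seed_p = if (positive) cfg$seed_complementarity_pos
                 else cfg$seed_complementarity_neg,
        out_p = if (positive) cfg$out_seed_pairing_pos
                else cfg$out_seed_pairing_neg,
        wobble_rate = cfg$wobble_rate)
      slack <- cfg$target_length - cfg$mirna_length
      at <- sample(0:slack, 1L)
      flank5 <- if (at > 0) random_rna(at, cfg$gc_content) else ""
      right <- slack - at
      flank3 <- if (right > 0) random_rna(right, cfg$gc_content) else ""
      tibble::tibble(
        pair_id = sprintf("sim_%04d", i), label = labels[i],
        mirna_id = sprintf("mir_%04d", i), mirna = mirna,
        target_id = sprintf("tgt_%04d", i),
        target = paste0(flank5, site, flank3),
        site_start = at + 1L, site_end = at + cfg$mirna_length)
    })
  })
}

#' Generate a labelled feature table end to end
#'
#' Composes [generate_pairs()], [align_duplex()] and
#' [extract_features()]: each pair's best accepted binding site yields
#' one feature row. Pairs with no accepted alignment are dropped with a
#' message.
#'
#' @param cfg A [synthetic_config()].
#' @param align_cfg An [align_config()].
#' @param model An [energy_model()].
#' @return A labelled feature table (`pair_id`, 34 features, `label`).
#' @export
generate_feature_table <- function(cfg = synthetic_config(),
                                   align_cfg = align_config(),
                                   model = energy_model()) {
  pairs <- generate_pairs(cfg)
  rows <- purrr::pmap(pairs, function(pair_id, label, mirna_id, mirna,
                                      target_id, target, ...) {
    hits <- align_duplex(mirna, target, align_cfg, model,
                         mirna_id = mirna_id, target_id = target_id)
    if (length(hits) == 0L) return(NULL)
    feats <- extract_features(hits[[1L]], model)
    dplyr::bind_cols(tibble::tibble(pair_id = pair_id), feats,
                     tibble::tibble(label = label))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L) {
    message(dropped, " of ", nrow(pairs),
            " pairs had no accepted alignment and were dropped")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop("no pair produced an accepted alignment; relax the score or ",
         "energy thresholds", call. = FALSE)
  }
  out$label <- factor(out$label, levels = c("NON_TARGET", "TARGET"))
  out
}
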