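# Performance assessment: confusion-matrix metrics, ROC/AUC, and the
# significance tests used around them. Counts may be fractional --
# fold-averaged confusion matrices are the norm in repeated
# cross-validation reporting.

#' Confusion matrix
#'
#' @param tp,tn,fp,fn Non-negative counts (fractional values allowed,
#'   e.g. fold averages).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + tn + fp + fn == 0) stop("all-zero confusion matrix")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("NON_TARGET", "TARGET"),
                              real = c("NON_TARGET", "TARGET")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN) x 100, SEN = TP/(TP+FN) x 100,
#' SPE = TN/(TN+FP) x 100, and Matthews' correlation coefficient
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Per-class error rates (100 - SEN, 100 - SPE recomputed from the
#' counts) are included for convenience. A metric whose denominator is
#' zero is reported as `NA`.
#'
#' Full precision is kept internally; use [truncate_digits()] to
#' reproduce printed-table values (reporting truncates toward zero
#' rather than rounding).
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: `acc`, `sen`, `spe` (percent), `mcc`,
#'   `err_pos`, `err_neg` (percent).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  tibble::tibble(
    acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    sen = 100 * safe_div(tp, tp + fn),
    spe = 100 * safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    err_pos = 100 * safe_div(fn, tp + fn),
    err_neg = 100 * safe_div(fp, tn + fp))
}

#' Truncate values to a fixed number of decimals
#'
#' Printed-precision reporting truncates toward zero rather than
#' rounding (87.208...% prints as 87.20, not 87.21).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` truncated toward zero at `digits` decimals.
#' @export
truncate_digits <- function(x, digits) {
  scale <- 10^digits
  trunc(x * scale + sign(x) * 1e-9) / scale
}

#' ROC curve and AUC
#'
#' Sweeps every decision threshold, accumulating the true- and
#' false-positive rates, and integrates the curve by trapezoids. Tied
#' scores are collapsed into single curve vertices, so the AUC equals
#' the probability that a randomly chosen positive scores higher than a
#' randomly chosen negative, with ties counted 1/2.
#'
#' @param scores Numeric vector: predicted probability of TARGET.
#' @param labels Vector coercible to TARGET/NON_TARGET (or a factor /
#'   logical, TRUE = positive).
#' @return A list with `auc` and `curve` (tibble of `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied run
  tpr <- cumsum(p)[keep] / sum(pos)
  fpr <- cumsum(!p)[keep] / sum(!pos)
  curve <- tibble::tibble(threshold = c(Inf, s[keep]),
                          fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  list(auc = auc, curve = curve)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("TARGET", "NON_TARGET"))) {
    stop("labels must be TARGET / NON_TARGET", call. = FALSE)
  }
  lab == "TARGET"
}

#' Label-permutation significance test for an AUC
#'
#' Permutes the labels `n_perm` times, recomputing the AUC each time;
#' the p-value is the fraction of permutations in which the permuted
#' AUC is at least the observed one. The plain fraction matches the
#' protocol's definition; `corrected = TRUE` applies the (r+1)/(n+1)
#' variant.
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param corrected Use the (r+1)/(n+1) estimator.
#' @return A list with `p_value`, `observed_auc`, `n_perm` and the
#'   vector of permuted AUCs.
#' @export
permutation_test_auc <- function(scores, labels, n_perm = 2000, seed = 1,
                                 corrected = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  pos <- as_positive(labels)
  observed <- roc_auc(scores, pos)$auc
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      roc_auc(scores, sample(pos))$auc
    }, 0)
  })
  r <- sum(perm >= observed)
  p <- if (corrected) (r + 1) / (n_perm + 1) else r / n_perm
  list(p_value = p, observed_auc = observed, n_perm = n_perm,
       permuted_auc = perm)
}

#' Compare two probability vectors (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a location shift
#' between two vectors of predicted probabilities.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A tibble with `statistic` (U) and `p_value`.
#' @export
compare_probability_vectors <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Paired t-test on per-resample AUC differences
#'
#' @param aucs_a,aucs_b Equal-length vectors of per-resample AUCs.
#' @return A tibble with `statistic` (t) and `p_value`; both `NA` when
#'   the paired differences have zero variance.
#' @export
paired_resample_test <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) == length(aucs_b), length(aucs_a) > 1)
  d <- aucs_a - aucs_b
  if (stats::sd(d) == 0) {
    message("paired differences have zero variance; test undefined")
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_))
  }
  tt <- stats::t.test(aucs_a, aucs_b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
}
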