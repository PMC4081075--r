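#' Element count table for knockdown comparisons
#'
#' Per-regulatory-element read counts under control and knockdown
#' conditions, with the element's occupancy signature and the two library
#' sizes used for depth normalisation.
#'
#' @param elements data frame with `element_id`, `signature`, `control`,
#'   `kd` (non-negative counts).
#' @param lib_control,lib_kd library sizes (totals used for CPM-style
#'   normalisation); default to the respective count sums.
#' @return an `element_count_table` (data frame subclass with library sizes
#'   as attributes).
#' @export
element_count_table <- function(elements, lib_control = NULL, lib_kd = NULL) {
  elements <- as.data.frame(elements)
  need <- c("element_id", "signature", "control", "kd")
  miss <- setdiff(need, names(elements))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(elements)) stopf("empty element table")
  if (any(elements$control < 0 | elements$kd < 0)) stopf("counts must be >= 0")
  lib_control <- lib_control %||% sum(elements$control)
  lib_kd <- lib_kd %||% sum(elements$kd)
  if (lib_control <= 0 || lib_kd <= 0) stopf("library sizes must be > 0")
  structure(elements, lib_control = lib_control, lib_kd = lib_kd,
            class = c("element_count_table", "data.frame"))
}

#' Knockdown differential occupancy per signature class
#'
#' Per-element log2 fold change of depth-normalised, pseudocounted counts,
#' `log2(((kd + pc) / lib_kd) / ((control + pc) / lib_control))`, summarised
#' per occupancy-signature class (median and interquartile range) with
#' two-sided Mann-Whitney rank-sum tests between every pair of classes.
#'
#' @param table an [element_count_table()].
#' @param pseudocount added to both counts before normalisation (default 1;
#'   0 is allowed when all counts are positive).
#' @return list with `elements` (input plus `log2fc`), `class_summary`
#'   (`signature`, `n`, `median`, `q25`, `q75`) and `class_tests`
#'   (`class_a`, `class_b`, `p_value`).
#' @export
differential_occupancy <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "element_count_table"))
  lc <- attr(table, "lib_control")
  lk <- attr(table, "lib_kd")
  el <- as.data.frame(table)
  if (pseudocount == 0 && any(el$control == 0 | el$kd == 0))
    stopf("pseudocount 0 requires strictly positive counts")
  el$log2fc <- log2(((el$kd + pseudocount) / lk) /
                    ((el$control + pseudocount) / lc))
  grp <- split(el$log2fc, el$signature)
  empty <- names(grp)[lengths(grp) == 0]
  if (length(empty)) {
    warnf("empty class(es) excluded: %s", paste(empty, collapse = ", "))
    grp <- grp[lengths(grp) > 0]
  }
  class_summary <- data.frame(
    signature = names(grp),
    n = lengths(grp),
    median = vapply(grp, median, numeric(1)),
    q25 = vapply(grp, quantile, numeric(1), probs = 0.25, names = FALSE),
    q75 = vapply(grp, quantile, numeric(1), probs = 0.75, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- if (length(grp) >= 2) utils::combn(names(grp), 2) else
    matrix(character(), 2, 0)
  class_tests <- data.frame(
    class_a = pairs[1, ], class_b = pairs[2, ],
    p_value = vapply(seq_len(ncol(pairs)), function(j)
      suppressWarnings(wilcox.test(grp[[pairs[1, j]]],
                                   grp[[pairs[2, j]]])$p.value),
      numeric(1)),
    stringsAsFactors = FALSE)
  list(elements = el, class_summary = class_summary, class_tests = class_tests)
}

#' Enrichment of a signature among knockdown-stable elements
#'
#' The stable subset contains elements whose occupancy changes less than
#' `fc_threshold`-fold in either direction on knockdown
#' (`max(FC, 1/FC) < fc_threshold` on the linear scale). Enrichment of the
#' focal occupancy signature among stable elements, relative to all
#' elements, is scored with the exact hypergeometric over tail.
#'
#' @param table an [element_count_table()].
#' @param fc_threshold linear fold-change cutoff defining "stable"
#'   (default 1.4; must exceed 1).
#' @param focus_signature signature label whose over-representation among
#'   stable elements is tested.
#' @param pseudocount see [differential_occupancy()].
#' @return one-row data frame as from [hypergeometric_counts()], plus
#'   `stable_fraction` (share of all elements that are stable) and
#'   `focus_fraction_stable` (share of stable elements with the focal
#'   signature).
#' @export
stable_subset_enrichment <- function(table, fc_threshold = 1.4,
                                     focus_signature, pseudocount = 1) {
  if (fc_threshold <= 1) stopf("fc_threshold must be > 1")
  do <- differential_occupancy(table, pseudocount = pseudocount)
  el <- do$elements
  stable <- abs(el$log2fc) < log2(fc_threshold)
  focus <- el$signature == focus_signature
  res <- hypergeometric_counts(k = sum(stable & focus), n = sum(stable),
                               K = sum(focus), N = nrow(el), tail = "over")
  res$stable_fraction <- mean(stable)
  res$focus_fraction_stable <- if (sum(stable)) mean(focus[stable]) else 0
  res
}
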