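#' Exact hypergeometric set enrichment
#'
#' Tests the overlap `k` between a query set of size `n` and an annotation
#' set of size `K` inside a universe of size `N`. The over tail is
#' `P(X >= k)` and the under tail `P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`, evaluated exactly via [stats::phyper()]
#' (log-space internally, numerically stable).
#'
#' @param query,annotation,universe character vectors of gene ids; query and
#'   annotation are intersected with the universe before counting.
#' @param tail `"over"` or `"under"`.
#' @return one-row data frame: `k`, `n`, `K`, `N`, `p_value`, `direction`.
#' @export
hypergeometric_test <- function(query, annotation, universe,
                                tail = c("over", "under")) {
  tail <- match.arg(tail)
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- intersect(unique(query), universe)
  annotation <- intersect(unique(annotation), universe)
  hypergeometric_counts(k = length(intersect(query, annotation)),
                        n = length(query), K = length(annotation),
                        N = length(universe), tail = tail)
}

#' @rdname hypergeometric_test
#' @param k,n,K,N overlap, query size, annotation size, universe size.
#' @export
hypergeometric_counts <- function(k, n, K, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (k > min(n, K) || n > N || K > N) stopf("inconsistent counts")
  p <- if (n == 0L) {
    1
  } else if (tail == "over") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  expected <- n * K / N
  data.frame(k = k, n = n, K = K, N = N, p_value = p,
             direction = if (k >= expected) "enriched" else "depleted",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values via [stats::p.adjust()]; order-invariant, bounded by 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`, no missing values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stopf("NA p-values not allowed")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bootstrap category enrichment z-scores
#'
#' For each category of genes (e.g. the B-cell / activated B-cell /
#' plasmablast / plasma-cell stages of an in vitro differentiation course),
#' compares the observed overlap with a query gene list against a null built
#' by drawing query-sized gene sets uniformly without replacement from the
#' universe. Reports `z = (obs - mean_null) / sd_null` and a two-sided
#' empirical p with the `(r + 1) / (n_iter + 1)` correction. Because the
#' draws are without replacement the null is exactly hypergeometric, so
#' the null moments can be audited in closed form.
#'
#' @param query character vector, subset of `universe`.
#' @param category_map named character vector, gene -> category label; the
#'   categorised genes must be a subset of the universe.
#' @param universe character vector of all eligible genes.
#' @param n_iter number of random draws (default 1e7; analyses in this
#'   package's tests use 1e5-1e6).
#' @param seed RNG seed.
#' @return data frame per category: `category`, `k` (observed), `n`, `K`,
#'   `N`, `mean_null`, `sd_null`, `z`, `p_value` (empirical two-sided),
#'   `direction`, `degenerate` (TRUE when `sd_null` is 0).
#' @export
bootstrap_category_zscore <- function(query, category_map, universe,
                                      n_iter = 1e7, seed = NULL) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stopf("query must be a subset of the universe")
  cat_genes <- names(category_map)
  if (!all(cat_genes %in% universe))
    stopf("categorised genes must be a subset of the universe")
  cats <- sort(unique(unname(category_map)))
  code <- integer(length(universe))                      # 0 = uncategorised
  code[match(cat_genes, universe)] <- match(unname(category_map), cats)
  N <- length(universe)
  n <- length(query)
  ncat <- length(cats)
  obs <- tabulate(code[match(query, universe)], nbins = ncat)
  n_iter <- as.integer(n_iter)
  null_counts <- with_seed(seed, {
    out <- matrix(0L, n_iter, ncat)
    for (i in seq_len(n_iter)) {
      out[i, ] <- tabulate(code[sample.int(N, n)], nbins = ncat)
    }
    out
  })
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2, sd)
  K <- tabulate(code, nbins = ncat)
  res <- lapply(seq_len(ncat), function(j) {
    degenerate <- sdv[j] == 0
    z <- if (degenerate) NA_real_ else (obs[j] - mu[j]) / sdv[j]
    r <- sum(abs(null_counts[, j] - mu[j]) >= abs(obs[j] - mu[j]))
    data.frame(category = cats[j], k = obs[j], n = n, K = K[j], N = N,
               mean_null = mu[j], sd_null = sdv[j], z = z,
               p_value = (r + 1) / (n_iter + 1),
               direction = if (obs[j] >= mu[j]) "enriched" else "depleted",
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hypergeometric enrichment across a signature collection
#'
#' Applies [hypergeometric_test()] (over tail) to every gene set in a
#' collection, after excluding sets of `max_set_size` or more genes
#' (the size filter applies to the raw set, before universe intersection),
#' then adjusts the batch with [bh_fdr()] and sorts by q.
#'
#' @param query character vector of gene ids.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @param max_set_size sets with `size >= max_set_size` are excluded
#'   (default 1000, i.e. only sets of fewer than 1000 genes are tested).
#' @return data frame sorted by `q_value` then `p_value`:
#'   `set`, `set_size`, `k`, `n`, `K`, `N`, `p_value`, `q_value`, `direction`.
#' @export
signature_collection_enrichment <- function(query, collection, universe,
                                            max_set_size = 1000) {
  if (!length(collection)) stopf("empty signature collection")
  sizes <- lengths(collection)
  keep <- sizes < max_set_size
  collection <- collection[keep]
  sizes <- sizes[keep]
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- lapply(seq_along(collection), function(i) {
    ann <- intersect(unique(collection[[i]]), universe)
    if (!length(ann)) {
      warnf("signature '%s' has no genes in the universe; skipped",
            names(collection)[i])
      return(NULL)
    }
    r <- hypergeometric_counts(k = length(intersect(query, ann)),
                               n = length(query), K = length(ann),
                               N = length(universe), tail = "over")
    cbind(data.frame(set = names(collection)[i], set_size = sizes[i],
                     stringsAsFactors = FALSE), r)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("no testable signatures after filtering")
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "set_size", "k", "n", "K", "N", "p_value", "q_value", "direction")]
}

#' Pearson chi-squared comparison of two proportions
#'
#' 2x2 Pearson chi-squared (df = 1), without continuity correction by
#' default, for comparing `a_successes / a_total` against
#' `b_successes / b_total`.
#'
#' @param a_successes,a_total,b_successes,b_total non-negative counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `df`, `table`.
#' @export
proportion_chisq <- function(a_successes, a_total, b_successes, b_total,
                             correct = FALSE) {
  if (a_total <= 0 || b_total <= 0) stopf("totals must be positive")
  tab <- rbind(a = c(a_successes, a_total - a_successes),
               b = c(b_successes, b_total - b_successes))
  if (any(tab < 0)) stopf("successes exceed totals")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 1))
    warnf("expected cell count < 1; consider an exact test")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), table = tab)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("%s line %d: fewer than 3 fields", path, bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
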