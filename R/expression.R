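#' Expression cohort container
#'
#' One cohort's normalised log2 expression matrix (genes x samples) together
#' with per-sample annotations: cell-of-origin `class` (e.g. ABC, GCB,
#' other), overall survival (`os_time` in months, `os_event` 1 = death,
#' 0 = censored) and mutation status (`myd88` in wild_type / L265P / other /
#' unknown).
#'
#' @param dataset_id cohort label.
#' @param matrix numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param annotations data frame with column `sample` matching the matrix
#'   columns; `class`, `os_time`, `os_event`, `myd88` are optional and
#'   filled with defaults (`class = "ABC"`, survival/mutation NA).
#' @return an `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, annotations = NULL) {
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stopf("matrix must have unique gene-id rownames")
  if (is.null(colnames(matrix))) stopf("matrix must have sample colnames")
  if (is.null(annotations))
    annotations <- data.frame(sample = colnames(matrix))
  annotations <- as.data.frame(annotations)
  if (!"sample" %in% names(annotations)) stopf("annotations need a 'sample' column")
  if (!setequal(annotations$sample, colnames(matrix)))
    stopf("annotation samples do not match matrix columns")
  annotations <- annotations[match(colnames(matrix), annotations$sample), , drop = FALSE]
  if (is.null(annotations$class)) annotations$class <- "ABC"
  for (col in c("os_time", "os_event")) if (is.null(annotations[[col]]))
    annotations[[col]] <- NA_real_
  if (is.null(annotations$myd88)) annotations$myd88 <- NA_character_
  rownames(annotations) <- NULL
  structure(list(dataset_id = dataset_id, matrix = matrix,
                 annotations = annotations),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Split samples into marker-gene quadrants
#'
#' Within the selected class, samples are split at the median of each of two
#' marker genes (rank-based: the top 50% of ranks are "high"; with an odd
#' number of samples the middle rank goes to "low", and ties are broken by
#' stable sample order). The quadrant is the intersection of the two labels,
#' e.g. `SPIBhigh_BATFlow`.
#'
#' @param dataset an [expression_dataset()].
#' @param gene_a,gene_b marker genes (defaults SPIB and BATF).
#' @param class_filter keep only samples of this class (`NULL` = all).
#' @return data frame `sample`, `quadrant`, plus the two marker levels; the
#'   quadrant labels are recorded in `attr(, "levels")`.
#' @export
assign_quadrants <- function(dataset, gene_a = "SPIB", gene_b = "BATF",
                             class_filter = "ABC") {
  stopifnot(inherits(dataset, "expression_dataset"))
  for (g in c(gene_a, gene_b)) if (!g %in% rownames(dataset$matrix))
    stopf("marker gene '%s' absent from dataset %s", g, dataset$dataset_id)
  keep <- if (is.null(class_filter)) rep(TRUE, ncol(dataset$matrix)) else
    dataset$annotations$class %in% class_filter
  if (sum(keep) < 4) stopf("fewer than 4 samples after class filtering")
  m <- dataset$matrix[, keep, drop = FALSE]
  half_split <- function(v) {
    # rank > ceiling(n/2) is "high": strictly the top half, middle rank low
    r <- rank(v, ties.method = "first")
    r > ceiling(length(v) / 2)
  }
  hi_a <- half_split(m[gene_a, ])
  hi_b <- half_split(m[gene_b, ])
  lab_a <- paste0(gene_a, ifelse(hi_a, "high", "low"))
  lab_b <- paste0(gene_b, ifelse(hi_b, "high", "low"))
  out <- data.frame(sample = colnames(m),
                    quadrant = paste(lab_a, lab_b, sep = "_"),
                    stringsAsFactors = FALSE)
  out[[paste0(gene_a, "_level")]] <- ifelse(hi_a, "high", "low")
  out[[paste0(gene_b, "_level")]] <- ifelse(hi_b, "high", "low")
  levels <- as.vector(outer(paste0(gene_a, c("high", "low")),
                            paste0(gene_b, c("high", "low")), paste, sep = "_"))
  structure(out, levels = levels,
            extremes = c(paste0(gene_a, "high_", gene_b, "low"),
                         paste0(gene_a, "low_", gene_b, "high")))
}

# vectorised per-row Welch t-test (cross-checked against stats::t.test in
# the test suite); zero-variance rows with equal means get p = 1 (degenerate)
row_welch <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & (mx == my)] <- 1
  p[degenerate & (mx != my)] <- 0
  list(log2fc = mx - my, p = p, degenerate = degenerate)
}

#' Per-gene differential expression between two sample groups
#'
#' log2 fold change is `mean(group_x) - mean(group_y)` on the log2 scale
#' (positive = higher in `group_x`). The default test is Welch's t-test;
#' a Mann-Whitney rank-sum alternative is available.
#'
#' @param dataset an [expression_dataset()].
#' @param group_x,group_y character vectors of sample ids, each >= 3.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param alpha significance cutoff for the `significant` flag.
#' @return data frame `gene`, `log2fc`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
differential_expression <- function(dataset, group_x, group_y,
                                    test = c("welch", "wilcoxon"),
                                    alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$matrix
  for (g in list(group_x, group_y)) {
    if (length(g) < 3) stopf("each group needs >= 3 samples")
    if (!all(g %in% colnames(m))) stopf("unknown sample id(s)")
  }
  x <- m[, group_x, drop = FALSE]
  y <- m[, group_y, drop = FALSE]
  if (test == "welch") {
    r <- row_welch(x, y)
  } else {
    p <- vapply(seq_len(nrow(m)), function(i)
      suppressWarnings(wilcox.test(x[i, ], y[i, ])$p.value), numeric(1))
    deg <- apply(x, 1, var) == 0 & apply(y, 1, var) == 0 &
      rowMeans(x) == rowMeans(y)
    p[deg] <- 1
    r <- list(log2fc = rowMeans(x) - rowMeans(y), p = p, degenerate = deg)
  }
  data.frame(gene = rownames(m), log2fc = r$log2fc, p_value = r$p,
             significant = r$p < alpha, degenerate = r$degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus meta-profile across cohorts
#'
#' A gene enters a direction's meta-profile when it is differentially
#' expressed with that sign (unadjusted p below the per-cohort cutoff) in at
#' least `min_support` cohorts. Genes qualifying in both directions are
#' excluded from both and reported as conflicts. Support is counted over the
#' intersection of the cohorts' gene universes so all genes share a
#' denominator.
#'
#' @param per_dataset_de list of [differential_expression()] tables, one per
#'   cohort, computed with a common sign convention (x = first extreme
#'   quadrant).
#' @param min_support minimum number of supporting cohorts (default 4).
#' @return list with two data frames `up_in_x` and `up_in_y` (`gene`,
#'   `support`, `mean_log2fc`, sorted by support then |log2fc|), `conflicts`
#'   (character), and `universe`.
#' @export
consensus_meta_profile <- function(per_dataset_de, min_support = 4) {
  if (length(per_dataset_de) < min_support)
    stopf("need at least min_support = %d cohorts, got %d", min_support,
          length(per_dataset_de))
  universes <- lapply(per_dataset_de, function(d) d$gene)
  universe <- Reduce(intersect, universes)
  if (!all(lengths(universes) == length(universe)))
    warnf("cohorts disagree on the gene universe; using the %d-gene intersection",
          length(universe))
  if (!length(universe)) stopf("empty common gene universe")
  sig_up <- sapply(per_dataset_de, function(d) {
    i <- match(universe, d$gene); d$significant[i] & d$log2fc[i] > 0
  })
  sig_dn <- sapply(per_dataset_de, function(d) {
    i <- match(universe, d$gene); d$significant[i] & d$log2fc[i] < 0
  })
  fc <- sapply(per_dataset_de, function(d) d$log2fc[match(universe, d$gene)])
  sup_up <- rowSums(sig_up)
  sup_dn <- rowSums(sig_dn)
  in_up <- sup_up >= min_support
  in_dn <- sup_dn >= min_support
  conflicts <- universe[in_up & in_dn]
  if (length(conflicts))
    warnf("%d gene(s) met the support threshold in both directions; excluded",
          length(conflicts))
  profile <- function(sel, sig, sup) {
    sel <- sel & !(in_up & in_dn)
    mean_fc <- vapply(which(sel), function(i) mean(fc[i, sig[i, ]]), numeric(1))
    out <- data.frame(gene = universe[sel], support = sup[sel],
                      mean_log2fc = mean_fc, stringsAsFactors = FALSE)
    out[order(-out$support, -abs(out$mean_log2fc), out$gene), ]
  }
  list(up_in_x = profile(in_up, sig_up, sup_up),
       up_in_y = profile(in_dn, sig_dn, sup_dn),
       conflicts = conflicts, universe = universe,
       min_support = min_support)
}

#' Knockdown differential-expression gene lists at two stringencies
#'
#' Per-gene Welch test between control and knockdown replicate arms with
#' Benjamini-Hochberg adjustment. List A contains genes with adjusted
#' p < `fdr_alpha`; list B further requires a linear fold change of at least
#' `fc_threshold` in either direction.
#'
#' @param control,knockdown numeric matrices (genes x replicates, same
#'   rownames), >= 2 replicates each.
#' @param fdr_alpha adjusted-p cutoff (default 0.05).
#' @param fc_threshold linear fold-change cutoff for list B (default 1.5).
#' @return list with `table` (gene, log2fc, p_value, q_value, direction),
#'   `list_a`, `list_b` (character vectors).
#' @export
knockdown_de <- function(control, knockdown, fdr_alpha = 0.05,
                         fc_threshold = 1.5) {
  if (ncol(control) < 2 || ncol(knockdown) < 2)
    stopf("need >= 2 replicates per arm for a variance estimate")
  if (!identical(rownames(control), rownames(knockdown)))
    stopf("control and knockdown matrices must share rownames")
  r <- row_welch(knockdown, control)   # positive log2fc = up on knockdown
  q <- bh_fdr(r$p)
  tab <- data.frame(gene = rownames(control), log2fc = r$log2fc,
                    p_value = r$p, q_value = q,
                    direction = ifelse(r$log2fc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  list_a <- tab$gene[tab$q_value < fdr_alpha]
  list_b <- tab$gene[tab$q_value < fdr_alpha &
                     2^abs(tab$log2fc) >= fc_threshold]
  list(table = tab, list_a = list_a, list_b = list_b)
}

#' Expression summaries per occupancy group
#'
#' Median and interquartile range of expression for genes in each occupancy
#' group, next to the all-genes baseline ("Total").
#'
#' @param expression named numeric vector of per-gene expression (e.g. one
#'   cell line profile or per-gene medians).
#' @param occupancy_map named character vector, gene -> occupancy group.
#' @return data frame `group`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_expression_by_occupancy <- function(expression, occupancy_map) {
  if (is.null(names(expression))) stopf("expression must be a named vector")
  groups <- c(list(Total = names(expression)),
              split(names(occupancy_map), unname(occupancy_map)))
  rows <- lapply(names(groups), function(g) {
    v <- expression[intersect(groups[[g]], names(expression))]
    if (!length(v)) {
      warnf("occupancy group '%s' has no measured genes; omitted", g)
      return(NULL)
    }
    data.frame(group = g, n = length(v), median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Marker-gene correlations across cohorts
#'
#' Pairwise Spearman (default) correlation of marker genes within each
#' cohort's filtered samples, with the unweighted mean and sd across
#' cohorts per gene pair.
#'
#' @param datasets list of [expression_dataset()]s.
#' @param genes marker genes (default SPIB, BATF, IRF4).
#' @param method correlation method (default `"spearman"`).
#' @param class_filter keep only samples of this class (`NULL` = all).
#' @return list with `per_dataset` (dataset, gene_a, gene_b, rho, n) and
#'   `summary` (gene_a, gene_b, mean_rho, sd_rho, n_datasets).
#' @export
marker_correlations <- function(datasets, genes = c("SPIB", "BATF", "IRF4"),
                                method = "spearman", class_filter = "ABC") {
  pairs <- utils::combn(genes, 2)
  rows <- list()
  for (d in datasets) {
    stopifnot(inherits(d, "expression_dataset"))
    keep <- if (is.null(class_filter)) rep(TRUE, ncol(d$matrix)) else
      d$annotations$class %in% class_filter
    if (sum(keep) < 4) {
      warnf("dataset %s has fewer than 4 samples after filtering; skipped",
            d$dataset_id)
      next
    }
    m <- d$matrix[, keep, drop = FALSE]
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (!all(c(a, b) %in% rownames(m))) next
      if (var(m[a, ]) == 0 || var(m[b, ]) == 0) {
        warnf("constant marker in dataset %s; pair %s-%s skipped",
              d$dataset_id, a, b)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d$dataset_id, gene_a = a, gene_b = b,
        rho = cor(m[a, ], m[b, ], method = method), n = ncol(m),
        stringsAsFactors = FALSE)
    }
  }
  per_dataset <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(), gene_a = character(),
               gene_b = character(), rho = numeric(), n = integer())
  sp <- split(per_dataset$rho, paste(per_dataset$gene_a, per_dataset$gene_b))
  summary <- data.frame(
    pair = names(sp),
    mean_rho = vapply(sp, mean, numeric(1)),
    sd_rho = vapply(sp, function(v) if (length(v) > 1) sd(v) else NA_real_,
                    numeric(1)),
    n_datasets = lengths(sp), row.names = NULL, stringsAsFactors = FALSE)
  list(per_dataset = per_dataset, summary = summary)
}

#' Collapse probe-level rows to genes by maximal mean
#'
#' Keeps, for each gene, the probe row with the largest mean expression.
#'
#' @param matrix probes x samples numeric matrix.
#' @param probe_to_gene named character vector probe -> gene id.
#' @return genes x samples matrix.
#' @export
collapse_probes_max_mean <- function(matrix, probe_to_gene) {
  gene <- probe_to_gene[rownames(matrix)]
  if (any(is.na(gene))) stopf("unmapped probe(s)")
  mu <- rowMeans(matrix)
  keep <- unlist(lapply(split(seq_len(nrow(matrix)), gene),
                        function(ii) ii[which.max(mu[ii])]))
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out)), , drop = FALSE]
}
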