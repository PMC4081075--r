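#' Greedy peak-centre overlap clustering across cistromes
#'
#' Pools peaks from all supplied cistromes and merges them into overlap
#' clusters (regulatory elements): scanning in (chrom, centre, -score, label)
#' order, a peak whose centre is strictly less than `radius` bp from the
#' open cluster's index-peak centre joins that cluster; otherwise it founds
#' a new cluster and becomes its index peak. A centre exactly `radius` bp
#' away starts a new cluster. The result is a partition of the pooled peaks.
#'
#' @param cistromes a list of [cistrome()] objects (or a single cistrome).
#' @param radius clustering radius in bp (default 250).
#' @return A data frame of class `overlap_clusters` with one row per peak:
#'   `cluster_id`, `label` (source cistrome), `chrom`, `start`, `end`,
#'   `centre`, `score`, `name`, `is_index`, and per cluster the attached
#'   `signature` (factor labels present, in the order cistromes were
#'   supplied, joined by "_"). Cluster-level summaries are available via
#'   [cluster_table()].
#' @export
cluster_peaks <- function(cistromes, radius = 250) {
  if (inherits(cistromes, "cistrome")) cistromes <- list(cistromes)
  if (!length(cistromes)) stopf("at least one cistrome required")
  if (!is.numeric(radius) || radius <= 0) stopf("radius must be > 0")
  labels <- vapply(cistromes, function(x) attr(x, "factor"), character(1))
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "#")
  pooled <- do.call(rbind, lapply(seq_along(cistromes), function(i) {
    x <- as.data.frame(cistromes[[i]])
    if (!nrow(x)) return(NULL)
    x$label <- labels[i]
    x
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    out <- data.frame(cluster_id = integer(), label = character(),
                      chrom = character(), start = integer(), end = integer(),
                      centre = integer(), score = numeric(), name = character(),
                      is_index = logical())
    return(structure(out, radius = radius, factor_order = labels,
                     class = c("overlap_clusters", "data.frame")))
  }
  ord <- order(pooled$chrom, pooled$centre, -pooled$score, pooled$label)
  pooled <- pooled[ord, ]
  # single left-to-right scan per chromosome: centres are ascending, so the
  # distance to the open index is centre - index_centre
  cid <- integer(nrow(pooled))
  next_id <- 0L
  idx_centre <- NA_integer_
  idx_chrom <- ""
  is_index <- logical(nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    if (!identical(pooled$chrom[i], idx_chrom) ||
        (pooled$centre[i] - idx_centre) >= radius) {
      next_id <- next_id + 1L
      idx_centre <- pooled$centre[i]
      idx_chrom <- pooled$chrom[i]
      is_index[i] <- TRUE
    }
    cid[i] <- next_id
  }
  pooled$cluster_id <- cid
  pooled$is_index <- is_index
  rownames(pooled) <- NULL
  out <- pooled[, c("cluster_id", "label", "chrom", "start", "end",
                    "centre", "score", "name", "is_index")]
  structure(out, radius = radius, factor_order = labels,
            class = c("overlap_clusters", "data.frame"))
}

#' One-row-per-cluster summary of an overlap clustering
#'
#' @param clusters result of [cluster_peaks()].
#' @return data frame with `cluster_id`, `chrom`, `span_start`, `span_end`,
#'   `index_centre`, `n_peaks`, `signature` (member factor labels in the
#'   order the cistromes were supplied, joined by "_") and `members`
#'   (peak names, comma-separated).
#' @export
cluster_table <- function(clusters) {
  stopifnot(inherits(clusters, "overlap_clusters"))
  if (!nrow(clusters)) {
    return(data.frame(cluster_id = integer(), chrom = character(),
                      span_start = integer(), span_end = integer(),
                      index_centre = integer(), n_peaks = integer(),
                      signature = character(), members = character()))
  }
  forder <- attr(clusters, "factor_order")
  sp <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  rows <- lapply(sp, function(ii) {
    m <- clusters[ii, ]
    labs <- unique(m$label)
    labs <- forder[forder %in% labs]
    data.frame(cluster_id = m$cluster_id[1], chrom = m$chrom[1],
               span_start = min(m$start), span_end = max(m$end),
               index_centre = m$centre[m$is_index][1],
               n_peaks = nrow(m),
               signature = paste(labs, collapse = "_"),
               members = paste(m$name, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id), ]
  rownames(out) <- NULL
  out
}

#' Count clusters per occupancy signature
#'
#' Each cluster is counted once under its exact factor-set signature (the
#' set of cistrome labels contributing at least one member peak). Counts
#' over all signatures sum to the number of clusters.
#'
#' @param clusters result of [cluster_peaks()].
#' @return named integer vector, signature -> count.
#' @export
occupancy_signature_counts <- function(clusters) {
  tab <- cluster_table(clusters)
  if (!nrow(tab)) return(setNames(integer(), character()))
  cnt <- table(tab$signature)
  setNames(as.integer(cnt), names(cnt))
}

#' Signed centre-distance profile between two cistromes
#'
#' For every reference peak, the signed distance (query minus reference
#' centre) to the nearest query peak centre on the same chromosome.
#' Distances beyond `window` are dropped from the profile; the fraction of
#' reference peaks with a query centre within `near` bp (default 50) is
#' reported over all reference peaks.
#'
#' @param reference,query [cistrome()] objects, both non-empty.
#' @param window half-width of the reported profile in bp.
#' @param near distance defining the "tightly co-centred" fraction.
#' @return list with `distances` (numeric, within `window`),
#'   `fraction_within` (share of reference peaks with |d| <= `near`),
#'   `near`, `window`, `n_reference`.
#' @export
centre_distance_profile <- function(reference, query, window = 500, near = 50) {
  stopifnot(inherits(reference, "cistrome"), inherits(query, "cistrome"))
  if (!nrow(reference) || !nrow(query)) stopf("both cistromes must be non-empty")
  d <- rep(NA_real_, nrow(reference))
  for (ch in unique(reference$chrom)) {
    ri <- which(reference$chrom == ch)
    qc <- sort(query$centre[query$chrom == ch])
    if (!length(qc)) next
    rc <- reference$centre[ri]
    pos <- findInterval(rc, qc)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(qc))
    dl <- qc[lo] - rc
    dh <- qc[hi] - rc
    d[ri] <- ifelse(abs(dl) <= abs(dh), dl, dh)
  }
  list(distances = d[!is.na(d) & abs(d) <= window],
       fraction_within = mean(!is.na(d) & abs(d) <= near),
       near = near, window = window, n_reference = nrow(reference))
}
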