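#' Bin peak occupancy at fixed genomic resolution
#'
#' Divides each chromosome into `bin_size` bp bins (bin index
#' `floor(pos / bin_size)`). In `peak` mode a bin overlapped by any peak
#' interval gets value 1; in `signal` mode the peak scores of all peaks
#' overlapping the bin are summed. Only non-zero bins are stored.
#'
#' @param cistrome a [cistrome()].
#' @param bin_size bin width in bp (default 100).
#' @param mode `"peak"` (binary presence) or `"signal"` (summed score).
#' @param chrom_lengths optional named vector of contig lengths; required
#'   later for correlation over the `all_bins` domain.
#' @return a `binned_track`: list with `label`, `bin_size`, `bins`
#'   (data frame `chrom`, `bin`, `value`) and `chrom_lengths`.
#' @export
bin_occupancy <- function(cistrome, bin_size = 100, mode = c("peak", "signal"),
                          chrom_lengths = NULL) {
  mode <- match.arg(mode)
  if (bin_size <= 0) stopf("bin_size must be > 0")
  pk <- as.data.frame(cistrome)
  label <- attr(cistrome, "factor") %||% "track"
  if (!nrow(pk)) {
    bins <- data.frame(chrom = character(), bin = integer(), value = numeric())
  } else {
    first <- pk$start %/% bin_size
    last <- (pk$end - 1L) %/% bin_size
    reps <- last - first + 1L
    chrom <- rep(pk$chrom, reps)
    bin <- unlist(lapply(seq_len(nrow(pk)),
                         function(i) seq.int(first[i], last[i])))
    val <- rep(if (mode == "peak") rep(1, nrow(pk)) else pk$score, reps)
    key <- paste(chrom, bin)
    if (mode == "peak") {
      keep <- !duplicated(key)
      bins <- data.frame(chrom = chrom[keep], bin = bin[keep], value = 1)
    } else {
      agg <- rowsum(val, key)
      ks <- strsplit(rownames(agg), " ", fixed = TRUE)
      bins <- data.frame(chrom = vapply(ks, `[`, "", 1),
                         bin = as.integer(vapply(ks, `[`, "", 2)),
                         value = agg[, 1])
    }
    bins <- bins[bins$value != 0, ]
    bins <- bins[order(bins$chrom, bins$bin), ]
    rownames(bins) <- NULL
  }
  structure(list(label = label, bin_size = bin_size, bins = bins,
                 chrom_lengths = chrom_lengths),
            class = "binned_track")
}

#' Pairwise Pearson correlation of binned occupancy tracks
#'
#' Correlation is computed over a shared bin domain: either the union of
#' bins occupied by at least one track (`union_occupied`, the default —
#' avoids inflation from the shared empty genome) or every genomic bin
#' (`all_bins`, requires `chrom_lengths` on the tracks).
#'
#' @param tracks list of `binned_track`s with a common `bin_size`.
#' @param domain `"union_occupied"` or `"all_bins"`.
#' @return symmetric correlation matrix with unit diagonal; a zero-variance
#'   track yields `NA` entries and a warning, never a silent 0.
#' @export
occupancy_correlation_matrix <- function(tracks,
                                         domain = c("union_occupied", "all_bins")) {
  domain <- match.arg(domain)
  if (length(tracks) < 2L) stopf("need at least two tracks")
  bs <- unique(vapply(tracks, function(t) t$bin_size, numeric(1)))
  if (length(bs) != 1L) stopf("tracks disagree on bin_size")
  labels <- vapply(tracks, function(t) t$label, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "#")
  if (domain == "union_occupied") {
    keys <- unique(unlist(lapply(tracks, function(t)
      paste(t$bins$chrom, t$bins$bin))))
  } else {
    cl <- tracks[[1]]$chrom_lengths
    if (is.null(cl)) stopf("all_bins domain requires chrom_lengths on the tracks")
    keys <- unlist(lapply(names(cl), function(ch)
      paste(ch, seq.int(0L, (cl[[ch]] - 1L) %/% bs))))
  }
  m <- vapply(tracks, function(t) {
    v <- numeric(length(keys))
    v[match(paste(t$bins$chrom, t$bins$bin), keys)] <- t$bins$value
    v
  }, numeric(length(keys)))
  colnames(m) <- labels
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warnf("zero-variance track(s) over the %s domain: %s (correlations set to NA)",
          domain, paste(labels[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(m))
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  r
}

#' Hierarchical ordering of tracks from a correlation matrix
#'
#' Agglomerates on distance `1 - r` with the chosen linkage; merge order is
#' deterministic (ties broken by index as in [stats::hclust()]).
#'
#' @param corr symmetric correlation matrix, no missing values.
#' @param linkage `"average"` or `"complete"`.
#' @return list with `order` (leaf labels), `merge`, `height`, and the
#'   underlying `hclust` object.
#' @export
hierarchical_order <- function(corr, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (any(!is.finite(corr))) stopf("correlation matrix contains missing values")
  if (!isSymmetric(unname(corr))) stopf("matrix must be symmetric")
  hc <- hclust(as.dist(1 - corr), method = linkage)
  list(order = rownames(corr)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}
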