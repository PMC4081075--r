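#' Gene model table
#'
#' Validates a data frame of gene models: `gene_id`, `symbol`, `chrom`,
#' `strand` ("+"/"-"), `tss`, `body_start`, `body_end` (0-based half-open
#' body interval). The TSS is the body start on "+" and `body_end - 1` on
#' "-".
#'
#' @param genes data frame; `symbol` defaults to `gene_id`, `tss` is derived
#'   from strand when missing.
#' @return validated data frame of class `gene_models`.
#' @export
gene_models <- function(genes) {
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "strand", "body_start", "body_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("gene table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(genes$body_start >= genes$body_end)) stopf("body_start must be < body_end")
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$body_start, genes$body_end - 1L)
  ok <- (genes$strand == "+" & genes$tss == genes$body_start) |
        (genes$strand == "-" & genes$tss == genes$body_end - 1L)
  if (!all(ok)) stopf("tss inconsistent with strand/body at row %d", which(!ok)[1])
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene_id")
  genes <- genes[, c("gene_id", "symbol", "chrom", "strand", "tss",
                     "body_start", "body_end")]
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Assign peaks to genes
#'
#' Two geometries are supported. `upstream5kb_intragenic`: a peak belongs to
#' a gene when its centre lies within 5 kb upstream of the TSS (strand-aware:
#' coordinates below the TSS for "+" genes, above it for "-" genes) or
#' anywhere inside the gene body. `tss_flank`: the centre lies within
#' `tss +/- flank` (inclusive), strand-ignorant. A peak may map to several
#' genes.
#'
#' @param cistrome a [cistrome()] or [cluster_peaks()] result (any data frame
#'   with `chrom` and `centre`).
#' @param genes a [gene_models()] table.
#' @param mode `"upstream5kb_intragenic"` or `"tss_flank"`.
#' @param flank half-width in bp for `tss_flank` mode.
#' @param upstream upstream reach in bp for the upstream/intragenic mode.
#' @return data frame `gene_id`, `peak_name`, `chrom`, `centre`.
#' @export
assign_peaks_to_genes <- function(cistrome, genes,
                                  mode = c("upstream5kb_intragenic", "tss_flank"),
                                  flank = 2000, upstream = 5000) {
  mode <- match.arg(mode)
  genes <- gene_models(genes)
  pk <- as.data.frame(cistrome)
  if (is.null(pk$name)) pk$name <- as.character(seq_len(nrow(pk)))
  if (mode == "tss_flank") {
    win_lo <- genes$tss - flank
    win_hi <- genes$tss + flank    # inclusive
    hits <- match_windows(pk, genes, win_lo, win_hi)
  } else {
    up_lo <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss + 1L)
    up_hi <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + upstream)
    hits <- rbind(match_windows(pk, genes, up_lo, up_hi),
                  match_windows(pk, genes, genes$body_start, genes$body_end - 1L))
    hits <- unique(hits)
  }
  rownames(hits) <- NULL
  hits[order(hits$gene_id, hits$centre), ]
}

# inclusive window membership of peak centres, per chromosome
match_windows <- function(pk, genes, lo, hi) {
  out <- list()
  for (ch in intersect(unique(pk$chrom), unique(genes$chrom))) {
    gi <- which(genes$chrom == ch)
    pi <- which(pk$chrom == ch)
    if (!length(gi) || !length(pi)) next
    for (g in gi) {
      sel <- pi[pk$centre[pi] >= lo[g] & pk$centre[pi] <= hi[g]]
      if (length(sel))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], peak_name = pk$name[sel],
          chrom = ch, centre = pk$centre[sel])
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), peak_name = character(),
                      chrom = character(), centre = integer()))
  do.call(rbind, out)
}

#' Fraction of peaks at promoters
#'
#' Share of peaks whose centre lies within `tss +/- promoter_flank`
#' (inclusive) of any gene.
#'
#' @param cistrome a [cistrome()] or any data frame with `chrom` and `centre`.
#' @param genes a [gene_models()] table.
#' @param promoter_flank promoter half-width in bp (default 2 kb).
#' @return numeric fraction in `[0, 1]`.
#' @export
promoter_fraction <- function(cistrome, genes, promoter_flank = 2000) {
  genes <- gene_models(genes)
  pk <- as.data.frame(cistrome)
  if (!nrow(pk)) stopf("empty peak set")
  at_prom <- logical(nrow(pk))
  for (ch in unique(pk$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(pk$chrom == ch)
    if (!length(gi)) next
    lo <- genes$tss[gi] - promoter_flank
    hi <- genes$tss[gi] + promoter_flank
    at_prom[pi] <- vapply(pk$centre[pi],
                          function(c) any(c >= lo & c <= hi), logical(1))
  }
  mean(at_prom)
}
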