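IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Consensus motif pattern
#'
#' A named IUPAC consensus scanned for exact (ambiguity-aware) matches.
#' Ambiguity codes in the pattern match their base sets; any non-ACGT base
#' in the scanned sequence counts as a mismatch.
#'
#' @param name pattern label.
#' @param iupac consensus string over ACGTRYSWKMBDHVN.
#' @param both_strands also scan the reverse strand (default TRUE).
#' @return a `motif_pattern` object.
#' @export
motif_pattern <- function(name, iupac, both_strands = TRUE) {
  iupac <- toupper(iupac)
  if (!nzchar(iupac)) stopf("empty pattern")
  bad <- setdiff(strsplit(iupac, "")[[1]], names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC letter(s): %s", paste(bad, collapse = ""))
  structure(list(name = name, iupac = iupac, both_strands = both_strands),
            class = "motif_pattern")
}

#' Default composite-element consensi
#'
#' The composite elements through which IRF4 binds with its cofactors:
#' EICE (ETS/IRF composite), the two AICE (AP1/IRF composite) variants, the
#' AP1 heptamer and a generic ETS core. Editable defaults; consensus
#' matching only (no position-weight scoring).
#'
#' @return named list of [motif_pattern()]s.
#' @export
default_motif_patterns <- function() {
  list(EICE  = motif_pattern("EICE",  "GGAARTGAAAC"),
       AICE1 = motif_pattern("AICE1", "TTTCNNNNTGASTCA"),
       AICE2 = motif_pattern("AICE2", "GAAATGASTCA"),
       AP1   = motif_pattern("AP1",   "TGASTCA"),
       ETS   = motif_pattern("ETS",   "RGGAAR"))
}

revcomp <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Scan one sequence for a consensus pattern
#'
#' @param seq character scalar (DNA, case-insensitive).
#' @param pattern a [motif_pattern()].
#' @return data frame `start` (1-based), `end` (inclusive), `strand`.
#' @export
scan_sequence <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- toupper(seq)
  L <- nchar(pattern$iupac)
  if (nchar(seq) < L)
    return(data.frame(start = integer(), end = integer(), strand = character()))
  hit_starts <- function(pat) {
    sets <- IUPAC_SETS[strsplit(pat, "")[[1]]]
    sv <- strsplit(seq, "")[[1]]
    n <- length(sv) - L + 1L
    ok <- rep(TRUE, n)
    for (j in seq_len(L)) {
      ok <- ok & sv[seq_len(n) + j - 1L] %in% sets[[j]]
      if (!any(ok)) break
    }
    which(ok)
  }
  fwd <- hit_starts(pattern$iupac)
  out <- data.frame(start = fwd, end = fwd + L - 1L,
                    strand = rep("+", length(fwd)))
  if (isTRUE(pattern$both_strands)) {
    rev <- hit_starts(revcomp(pattern$iupac))
    out <- rbind(out, data.frame(start = rev, end = rev + L - 1L,
                                 strand = rep("-", length(rev))))
    # a palindromic consensus matches the same interval on both strands;
    # count each interval once (forward strand reported)
    out <- out[order(out$start, out$strand), , drop = FALSE]
    out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Count consensus-motif matches around peak centres
#'
#' Extracts `[centre - window, centre + window]` around each region centre
#' from the genome and counts ambiguity-aware consensus matches per pattern,
#' on both strands where the pattern allows. Optionally suppresses hits of
#' one pattern that overlap hits of another in the same window (e.g. ETS
#' cores lying inside an EICE).
#'
#' @param regions a [cistrome()] or data frame with `chrom` and `centre`.
#' @param genome named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param patterns list of [motif_pattern()]s (default
#'   [default_motif_patterns()]).
#' @param window half-width around the centre in bp (default 100).
#' @param suppress_within named character vector: for each entry, hits of
#'   pattern `names(x)[i]` overlapping a hit of pattern `x[i]` are dropped,
#'   e.g. `c(ETS = "EICE")`.
#' @return integer matrix, regions x patterns.
#' @export
count_motif_matches <- function(regions, genome,
                                patterns = default_motif_patterns(),
                                window = 100, suppress_within = NULL) {
  genome <- as_genome_strings(genome)
  pk <- as.data.frame(regions)
  stopifnot(!is.null(pk$chrom), !is.null(pk$centre))
  pnames <- vapply(patterns, function(p) p$name, character(1))
  counts <- matrix(0L, nrow(pk), length(patterns),
                   dimnames = list(pk$name %||% NULL, pnames))
  for (i in seq_len(nrow(pk))) {
    ctg <- genome[[pk$chrom[i]]]
    if (is.null(ctg)) stopf("contig %s absent from genome", pk$chrom[i])
    lo <- pk$centre[i] - window + 1L   # 1-based substring coordinates
    hi <- pk$centre[i] + window + 1L
    if (lo < 1L || hi > nchar(ctg))
      stopf("region %d window [%d,%d] exceeds contig %s bounds", i,
            lo - 1L, hi - 1L, pk$chrom[i])
    sub <- substr(ctg, lo, hi)
    hits <- lapply(patterns, function(p) scan_sequence(sub, p))
    names(hits) <- pnames
    if (!is.null(suppress_within)) {
      for (q in names(suppress_within)) {
        host <- hits[[suppress_within[[q]]]]
        h <- hits[[q]]
        if (nrow(h) && nrow(host)) {
          keep <- vapply(seq_len(nrow(h)), function(j)
            !any(h$start[j] <= host$end & h$end[j] >= host$start), logical(1))
          hits[[q]] <- h[keep, , drop = FALSE]
        }
      }
    }
    counts[i, ] <- vapply(hits, nrow, integer(1))
  }
  counts
}

as_genome_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- setNames(as.character(genome), nm)
  }
  if (!is.character(genome) || is.null(names(genome)))
    stopf("genome must be a FASTA path, DNAStringSet or named character vector")
  as.list(genome)
}
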