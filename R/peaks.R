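#' Construct a cistrome from a peak table
#'
#' A cistrome is the genome-wide peak set of one transcription factor in one
#' condition. It is stored as a data frame with columns `chrom`, `start`,
#' `end` (0-based half-open, BED convention), `centre` (absolute bp; must lie
#' inside the interval), `score` and `name`, sorted by (chrom, centre), with
#' the factor and condition attached as attributes.
#'
#' @param peaks data frame with at least `chrom`, `start`, `end`; `centre`,
#'   `score`, `name` are filled with defaults when absent (centre = interval
#'   midpoint, floor).
#' @param factor factor (antibody target) label, non-empty.
#' @param condition condition label, e.g. cell line or treatment.
#' @return A `cistrome` object (data frame subclass).
#' @export
cistrome <- function(peaks, factor, condition = "default") {
  if (!is.character(factor) || length(factor) != 1L || !nzchar(factor))
    stopf("'factor' must be a non-empty string")
  peaks <- as.data.frame(peaks)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stopf("peak table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(peaks$centre)) peaks$centre <- (peaks$start + peaks$end) %/% 2L
  if (is.null(peaks$score)) peaks$score <- rep(0, nrow(peaks))
  if (is.null(peaks$name)) peaks$name <- sprintf("%s_peak_%d", factor, seq_len(nrow(peaks)))
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  peaks$centre <- as.integer(peaks$centre)
  validate_peaks(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$centre, -peaks$score, peaks$name),
                 c("chrom", "start", "end", "centre", "score", "name")]
  rownames(peaks) <- NULL
  structure(peaks, factor = factor, condition = condition,
            class = c("cistrome", "data.frame"))
}

validate_peaks <- function(p) {
  bad <- which(!(p$start >= 0L & p$start < p$end))
  if (length(bad)) stopf("invalid interval at row %d: start=%d end=%d",
                         bad[1], p$start[bad[1]], p$end[bad[1]])
  bad <- which(!(p$centre >= p$start & p$centre < p$end))
  if (length(bad)) stopf("centre outside interval at row %d: centre=%d not in [%d,%d)",
                         bad[1], p$centre[bad[1]], p$start[bad[1]], p$end[bad[1]])
  invisible(p)
}

#' @export
print.cistrome <- function(x, ...) {
  cat(sprintf("<cistrome> factor=%s condition=%s peaks=%d\n",
              attr(x, "factor"), attr(x, "condition"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read peak calls from BED6 or ENCODE narrowPeak
#'
#' For narrowPeak the summit offset (column 10) gives the absolute centre
#' `start + offset`; an offset of -1 means no summit was called and the
#' interval midpoint is used. For BED6 the centre is the midpoint
#' `floor((start + end)/2)`.
#'
#' @param path file path.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @param factor,condition labels for the resulting cistrome; `factor`
#'   defaults to the file base name.
#' @return A [cistrome()].
#' @export
read_peaks <- function(path, dialect = c("bed6", "narrowPeak"),
                       factor = NULL, condition = "default") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  ncol_needed <- if (dialect == "bed6") 6L else 10L
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    tab <- data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < ncol_needed)
    if (length(bad))
      stopf("%s line %d: expected >= %d fields, found %d", path, bad[1],
            ncol_needed, nf[bad[1]])
    m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) stopf("%s line %d: non-integer coordinates", path, bad[1])
    score <- suppressWarnings(as.numeric(m[, 5]))
    score[is.na(score)] <- 0
    if (dialect == "narrowPeak") {
      # column 7 is signalValue; prefer it as the peak score when present
      sv <- suppressWarnings(as.numeric(m[, 7]))
      score <- ifelse(is.na(sv), score, sv)
      offset <- suppressWarnings(as.integer(m[, 10]))
      bad <- which(is.na(offset))
      if (length(bad)) stopf("%s line %d: malformed summit offset", path, bad[1])
      centre <- ifelse(offset < 0L, (start + end) %/% 2L, start + offset)
    } else {
      centre <- (start + end) %/% 2L
    }
    tab <- data.frame(chrom = m[, 1], start = start, end = end,
                      centre = as.integer(centre), score = score,
                      name = m[, 4], stringsAsFactors = FALSE)
  }
  cistrome(tab, factor = factor %||% sub("\\.[^.]*$", "", basename(path)),
           condition = condition)
}

#' Write a cistrome as BED6 or narrowPeak
#'
#' Round-trips with [read_peaks()]: the summit offset written for narrowPeak
#' is `centre - start`, so the centre is reproduced exactly.
#'
#' @param x a [cistrome()].
#' @param path output file.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @export
write_peaks <- function(x, path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "cistrome"))
  if (dialect == "bed6") {
    out <- data.frame(x$chrom, x$start, x$end, x$name, x$score, ".")
  } else {
    out <- data.frame(x$chrom, x$start, x$end, x$name, 0L, ".",
                      x$score, -1, -1, x$centre - x$start)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
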