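# Independent brute-force oracles used to cross-check the package
# implementations. They follow the documented rules literally and slowly,
# sharing no code with the implementations they verify.

# Greedy overlap clustering: naive walk over the pooled peak list in
# (chrom, centre, -score, label) order, comparing the absolute distance to
# the open cluster's index-peak centre.
oracle_cluster <- function(pooled, radius) {
  ord <- order(pooled$chrom, pooled$centre, -pooled$score, pooled$label)
  pooled <- pooled[ord, ]
  cid <- integer(nrow(pooled))
  cur <- 0L
  cur_chrom <- NULL
  cur_index_centre <- NULL
  for (i in seq_len(nrow(pooled))) {
    joins <- !is.null(cur_chrom) &&
      pooled$chrom[i] == cur_chrom &&
      abs(pooled$centre[i] - cur_index_centre) < radius
    if (!joins) {
      cur <- cur + 1L
      cur_chrom <- pooled$chrom[i]
      cur_index_centre <- pooled$centre[i]
    }
    cid[i] <- cur
  }
  split(pooled$name, cid)
}

# Exact hypergeometric tail by summation of choose() products. For N <= 25
# every product is an exact integer below 2^53, so this is exact rational
# arithmetic carried in doubles.
oracle_hyper <- function(k, n, K, N, tail = "over") {
  ks <- max(0, n + K - N):min(n, K)
  sel <- if (tail == "over") ks >= k else ks <= k
  sum(choose(K, ks[sel]) * choose(N - K, n - ks[sel])) / choose(N, n)
}

# One-sided (enrichment) Fisher p for a 2x2 table by enumeration of all
# tables with the same margins.
oracle_fisher_greater <- function(tab) {
  k <- tab[1, 1]
  n <- sum(tab[1, ])
  K <- sum(tab[, 1])
  N <- sum(tab)
  oracle_hyper(k, n, K, N, tail = "over")
}

# Pearson chi-squared from the textbook formula sum (O - E)^2 / E.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# IUPAC consensus scan via regex expansion; overlapping matches counted with
# a lookahead, both-strand hits deduplicated on the matched interval.
iupac_regex <- function(iupac) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
               H = "ACT", V = "ACG", N = "ACGT")
  paste0(vapply(strsplit(iupac, "")[[1]],
                function(ch) paste0("[", sets[[ch]], "]"), character(1)),
         collapse = "")
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")

oracle_motif_count <- function(seq, iupac, both_strands = TRUE) {
  starts_of <- function(pat) {
    m <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  hits <- starts_of(iupac)
  if (both_strands) hits <- union(hits, starts_of(oracle_revcomp(iupac)))
  length(hits)
}

# O(peaks x genes) interval-membership scan for gene assignment.
oracle_assign <- function(pk, genes, mode, flank = 2000, upstream = 5000) {
  hits <- list()
  for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(genes))) {
    if (pk$chrom[i] != genes$chrom[j]) next
    c <- pk$centre[i]
    inside <- if (mode == "tss_flank") {
      abs(c - genes$tss[j]) <= flank
    } else {
      in_body <- c >= genes$body_start[j] && c < genes$body_end[j]
      in_up <- if (genes$strand[j] == "+")
        c >= genes$tss[j] - upstream && c < genes$tss[j]
      else
        c > genes$tss[j] && c <= genes$tss[j] + upstream
      in_body || in_up
    }
    if (inside)
      hits[[length(hits) + 1L]] <- c(genes$gene_id[j], pk$name[i])
  }
  if (!length(hits)) return(character())
  sort(vapply(hits, paste, character(1), collapse = ":"))
}

# Dense per-base binning on a toy genome.
oracle_bin_dense <- function(pk, bin_size, chrom_len) {
  cov <- setNames(lapply(unique(pk$chrom), function(ch) logical(chrom_len)),
                  unique(pk$chrom))
  for (i in seq_len(nrow(pk)))
    cov[[pk$chrom[i]]][(pk$start[i] + 1):pk$end[i]] <- TRUE
  out <- list()
  for (ch in names(cov)) {
    idx <- which(cov[[ch]]) - 1L
    bins <- sort(unique(idx %/% bin_size))
    if (length(bins))
      out[[ch]] <- data.frame(chrom = ch, bin = bins, value = 1)
  }
  do.call(rbind, out)
}

# Product-limit estimate computed directly from its definition.
oracle_km <- function(time, event) {
  ord <- order(time, -event)   # events before censorings at tied times
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# random multi-factor peak fixture with mixed spacings including exact-radius
# gaps, for clustering stress tests
random_peak_instance <- function(seed, n_peaks = 200, n_factors = 3,
                                 radius = 250) {
  set.seed(seed)
  labels <- LETTERS[seq_len(n_factors)]
  gaps <- sample(c(0, 1, 50, 249, 250, 251, 400, 1000), n_peaks, replace = TRUE)
  centre <- 500 + cumsum(gaps)
  chrom <- sample(c("chr1", "chr2"), n_peaks, replace = TRUE)
  data.frame(chrom = chrom, centre = as.integer(centre),
             start = as.integer(centre - 50), end = as.integer(centre + 50),
             score = round(runif(n_peaks, 1, 100), 2),
             label = sample(labels, n_peaks, replace = TRUE),
             name = sprintf("p%03d", seq_len(n_peaks)),
             stringsAsFactors = FALSE)
}
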