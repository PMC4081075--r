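#' Simulate sequences with embedded consensus motifs
#'
#' Background bases are i.i.d. with the requested GC content. Each embedded
#' occurrence is a literal instantiation of its IUPAC pattern (ambiguity
#' codes resolved uniformly at random), written at the stated 1-based
#' position on a randomly chosen strand (reverse-strand embeddings are
#' written as the reverse complement).
#'
#' @param patterns named list of [motif_pattern()]s.
#' @param n_seq number of sequences.
#' @param seq_length sequence length (bp).
#' @param embed data frame with columns `seq` (1-based sequence index),
#'   `pattern` (name in `patterns`), `pos` (1-based start); optional
#'   `strand` ("+"/"-", randomised when absent). NULL embeds nothing.
#' @param gc background GC fraction (default 0.4).
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector, names seq_0001...)
#'   and `truth` (the embed table with the realised strand and instance).
#' @export
gen_motif_sequences <- function(patterns, n_seq, seq_length, embed = NULL,
                                gc = 0.4, seed = 1) {
  with_seed(seed, {
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n_seq), function(i)
      paste(sample(names(prob), seq_length, replace = TRUE, prob = prob),
            collapse = ""), character(1))
    names(seqs) <- sprintf("seq_%04d", seq_len(n_seq))
    truth <- data.frame(seq = integer(), pattern = character(),
                        pos = integer(), strand = character(),
                        instance = character())
    if (!is.null(embed) && nrow(embed)) {
      if (is.null(embed$strand))
        embed$strand <- sample(c("+", "-"), nrow(embed), replace = TRUE)
      embed$instance <- NA_character_
      for (i in seq_len(nrow(embed))) {
        p <- patterns[[embed$pattern[i]]]
        if (is.null(p)) stopf("unknown pattern '%s'", embed$pattern[i])
        L <- nchar(p$iupac)
        if (embed$pos[i] < 1 || embed$pos[i] + L - 1 > seq_length)
          stopf("embedding %d does not fit: pattern %s (%d bp) at pos %d in %d bp",
                i, p$name, L, embed$pos[i], seq_length)
        inst <- paste(vapply(strsplit(p$iupac, "")[[1]],
                             function(ch) sample(IUPAC_SETS[[ch]], 1),
                             character(1)), collapse = "")
        written <- if (embed$strand[i] == "-") revcomp(inst) else inst
        s <- seqs[[embed$seq[i]]]
        substr(s, embed$pos[i], embed$pos[i] + L - 1) <- written
        seqs[[embed$seq[i]]] <- s
        embed$instance[i] <- inst
      }
      truth <- embed
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
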