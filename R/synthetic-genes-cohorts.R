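#' Simulate non-overlapping gene models
#'
#' Places `n_genes` gene bodies (lengths log-uniform between 2 and 20 kb)
#' on both strands without overlap, uniformly across the supplied
#' chromosomes. The TSS is the body start on "+" and the body end - 1 on
#' "-". Fails explicitly when the genome cannot hold the requested genes.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param seed RNG seed.
#' @param min_len,max_len gene-body length range in bp.
#' @return a [gene_models()] table.
#' @export
gen_gene_models <- function(n_genes, chrom_lengths, seed = 1,
                            min_len = 2000, max_len = 20000) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  with_seed(seed, {
    len <- as.integer(round(exp(runif(n_genes, log(min_len), log(max_len)))))
    # allocate genes to chromosomes proportionally to length, then place the
    # bodies with uniform gaps (stick-breaking), which guarantees disjointness
    chrom_of <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
    rows <- list()
    for (ch in unique(chrom_of)) {
      ii <- which(chrom_of == ch)
      total <- sum(len[ii]) + length(ii)          # >= 1 bp gap between bodies
      slack <- chrom_lengths[[ch]] - total
      if (slack < 0)
        stopf("genome too small to place %d genes without overlap on %s",
              length(ii), ch)
      gaps <- floor(slack * diff(c(0, sort(runif(length(ii))), 1)))
      starts <- cumsum(gaps[-length(gaps)] + c(0L, len[ii[-length(ii)]] + 1L))
      rows[[ch]] <- data.frame(
        gene_id = sprintf("gene_%05d", ii), chrom = ch,
        strand = sample(c("+", "-"), length(ii), replace = TRUE),
        body_start = as.integer(starts),
        body_end = as.integer(starts + len[ii]), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$gene_id), ]
    rownames(out) <- NULL
    gene_models(out)
  })
}

#' Simulation design for expression cohorts
#'
#' Describes a multi-cohort expression study with two marker genes whose
#' relative expression defines quadrants: planted differential genes get a
#' mean shift in one extreme quadrant, survival hazard and mutation odds are
#' modified in the `SPIBhigh_BATFlow`-type quadrant.
#'
#' @param n_datasets number of cohorts (default 9).
#' @param n_samples samples per cohort (all of the selected class).
#' @param n_genes genes per cohort (marker genes included in the count).
#' @param n_planted_per_direction planted differential genes per direction
#'   (must be <= n_genes / 2).
#' @param effect_size planted mean shift, log2 units.
#' @param noise_sd residual sd of log2 expression, > 0.
#' @param hazard_ratio hazard multiplier applied to the marker-A-high /
#'   marker-B-low quadrant (< 1 = better survival there).
#' @param baseline_hazard exponential event rate per month for the other
#'   quadrants (default log(2)/40: 40-month median survival, typical of
#'   an aggressive lymphoma cohort).
#' @param censor_time administrative censoring horizon in months (Inf = no
#'   censoring).
#' @param mutation_enrichment_odds odds multiplier for mutation in the
#'   marker-A-high / marker-B-low quadrant.
#' @param baseline_mutation_rate mutation probability elsewhere, in `[0,1]`.
#' @param gene_a,gene_b marker gene names (default SPIB, BATF).
#' @param seed RNG seed.
#' @return a `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_datasets = 9, n_samples = 50, n_genes = 10000,
                            n_planted_per_direction = 50, effect_size = 1.5,
                            noise_sd = 0.7, hazard_ratio = 1,
                            baseline_hazard = log(2) / 40, censor_time = 120,
                            mutation_enrichment_odds = 1,
                            baseline_mutation_rate = 0.2,
                            gene_a = "SPIB", gene_b = "BATF", seed = 1) {
  if (n_planted_per_direction > n_genes / 2)
    stopf("n_planted_per_direction must be <= n_genes / 2")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (hazard_ratio <= 0) stopf("hazard_ratio must be > 0")
  if (baseline_mutation_rate < 0 || baseline_mutation_rate > 1)
    stopf("baseline_mutation_rate must lie in [0, 1]")
  structure(as.list(environment()), class = "cohort_sim_spec")
}

#' Simulate expression cohorts with planted quadrant structure
#'
#' For each cohort: marker genes A and B are drawn independently per sample,
#' quadrants follow from their median split; genes planted as
#' "up in Ahigh/Blow" get `+effect_size` in that quadrant, genes planted for
#' the reciprocal direction get `+effect_size` in the Alow/Bhigh quadrant;
#' survival is exponential with the hazard ratio applied to the Ahigh/Blow
#' quadrant (administrative censoring at `censor_time`); mutation status is
#' Bernoulli with the odds multiplied in that quadrant.
#'
#' @param spec a [cohort_sim_spec()].
#' @param on_small_quadrant `"regenerate"` (redraw marker values until every
#'   quadrant has >= 3 samples, up to 50 attempts) or `"error"`.
#' @return list with `datasets` (list of [expression_dataset()]s), `truth`
#'   (list `up_in_a_high`, `up_in_b_high`: planted gene ids) and `spec`.
#' @export
gen_expression_cohorts <- function(spec,
                                   on_small_quadrant = c("regenerate", "error")) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  on_small_quadrant <- match.arg(on_small_quadrant)
  with_seed(spec$seed, {
    ids <- sprintf("gene_%05d", seq_len(spec$n_genes - 2L))
    genes <- c(spec$gene_a, spec$gene_b, ids)
    up_a <- ids[seq_len(spec$n_planted_per_direction)]
    up_b <- ids[spec$n_planted_per_direction +
                  seq_len(spec$n_planted_per_direction)]
    datasets <- lapply(seq_len(spec$n_datasets), function(d) {
      n <- spec$n_samples
      samples <- sprintf("ds%02d_s%03d", d, seq_len(n))
      for (attempt in seq_len(50L)) {
        a_val <- rnorm(n, 8, 1)
        b_val <- rnorm(n, 8, 1)
        hi_a <- rank(a_val, ties.method = "first") > ceiling(n / 2)
        hi_b <- rank(b_val, ties.method = "first") > ceiling(n / 2)
        sizes <- table(factor(paste0(ifelse(hi_a, "A", "a"),
                                     ifelse(hi_b, "B", "b")),
                              levels = c("AB", "Ab", "aB", "ab")))
        if (min(sizes) >= 3) break
        if (on_small_quadrant == "error")
          stopf("cohort %d: a quadrant has fewer than 3 samples", d)
        if (attempt == 50L)
          stopf("cohort %d: could not populate all quadrants in 50 attempts", d)
      }
      m <- matrix(rnorm(length(genes) * n, 6, spec$noise_sd),
                  length(genes), n, dimnames = list(genes, samples))
      m[spec$gene_a, ] <- a_val
      m[spec$gene_b, ] <- b_val
      q_ab <- hi_a & !hi_b      # Ahigh_Blow: the focal quadrant
      q_ba <- !hi_a & hi_b
      m[up_a, q_ab] <- m[up_a, q_ab] + spec$effect_size
      m[up_b, q_ba] <- m[up_b, q_ba] + spec$effect_size
      hazard <- spec$baseline_hazard * ifelse(q_ab, spec$hazard_ratio, 1)
      t_true <- rexp(n, hazard)
      os_time <- pmin(t_true, spec$censor_time)
      os_event <- as.numeric(t_true <= spec$censor_time)
      base_odds <- spec$baseline_mutation_rate /
        (1 - spec$baseline_mutation_rate)
      odds <- base_odds * ifelse(q_ab, spec$mutation_enrichment_odds, 1)
      myd88 <- ifelse(rbinom(n, 1, odds / (1 + odds)) == 1, "L265P",
                      "wild_type")
      expression_dataset(
        dataset_id = sprintf("synthetic_cohort_%02d", d),
        matrix = round(m, 4),
        annotations = data.frame(sample = samples, class = "ABC",
                                 os_time = round(os_time, 3),
                                 os_event = os_event, myd88 = myd88,
                                 stringsAsFactors = FALSE))
    })
    list(datasets = datasets,
         truth = list(up_in_a_high = up_a, up_in_b_high = up_b),
         spec = spec)
  })
}
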