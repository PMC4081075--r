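test_that("gene models are reproducible and fit the genome", {
  g1 <- gen_gene_models(1, c(chr1 = 10000), seed = 1)
  expect_equal(nrow(g1), 1)
  expect_gte(g1$body_start, 0)
  expect_lte(g1$body_end, 10000)
  expect_identical(gen_gene_models(50, c(chr1 = 2e6), seed = 4),
                   gen_gene_models(50, c(chr1 = 2e6), seed = 4))
  expect_error(gen_gene_models(1000, c(chr1 = 1e5), seed = 1), "too small")
})

test_that("gene bodies are pairwise disjoint (brute-force scan)", {
  g <- gen_gene_models(500, c(chrA = 3e7, chrB = 2e7), seed = 7)
  expect_equal(nrow(g), 500)
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      others <- sub[-i, ]
      expect_false(any(sub$body_start[i] < others$body_end &
                       sub$body_end[i] > others$body_start),
                   label = sprintf("%s gene %d", ch, i))
    }
  }
  expect_true(all(g$tss[g$strand == "+"] == g$body_start[g$strand == "+"]))
  expect_true(all(g$tss[g$strand == "-"] == g$body_end[g$strand == "-"] - 1))
})

test_that("full sharing with zero jitter gives identical centres", {
  spec <- cistrome_sim_spec(c("A", "B"), n_elements_per_factor = 50,
                            shared_fraction = 1, centre_jitter_sd = 0, seed = 2)
  g <- gen_cistromes(spec)
  expect_equal(g$cistromes$A$centre, g$cistromes$B$centre)
})

test_that("zero sharing with wide spacing yields no mixed clusters", {
  spec <- cistrome_sim_spec(c("A", "B"), n_elements_per_factor = 200,
                            shared_fraction = 0, centre_jitter_sd = 10,
                            min_spacing = 1000, seed = 3)
  g <- gen_cistromes(spec)
  sig <- occupancy_signature_counts(cluster_peaks(g$cistromes, 250))
  expect_false("A_B" %in% names(sig))
  expect_equal(sum(sig), 400)
})

test_that("empirical sharing fraction matches the design within binomial error", {
  spec <- cistrome_sim_spec(c("A", "B"), n_elements_per_factor = 1000,
                            shared_fraction = 0.8, centre_jitter_sd = 20,
                            seed = 5)
  g <- gen_cistromes(spec)
  a_owned <- g$truth[g$truth$owner == "A", ]
  # fraction of A-owned elements with a B peak within 250 bp
  b <- g$cistromes$B
  near <- vapply(seq_len(nrow(a_owned)), function(i)
    any(b$chrom == a_owned$chrom[i] &
        abs(b$centre - a_owned$centre[i]) < 250), logical(1))
  expect_equal(mean(near), 0.8, tolerance = 0.05)
  # and against the truth table directly
  expect_equal(mean(a_owned$B), 0.8, tolerance = 0.05)
})

test_that("cistrome generation is deterministic and round-trips through BED", {
  spec <- cistrome_sim_spec(c("A", "B"), n_elements_per_factor = 100, seed = 11)
  g1 <- gen_cistromes(spec)
  g2 <- gen_cistromes(spec)
  expect_identical(g1, g2)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(g1$cistromes$A, f, "narrowPeak")
  back <- read_peaks(f, "narrowPeak", factor = "A", condition = "simulated")
  expect_equal(as.data.frame(back), as.data.frame(g1$cistromes$A))
})

test_that("element counts follow the planted retained fractions", {
  spec <- cistrome_sim_spec(c("A", "B"), n_elements_per_factor = 800,
                            shared_fraction = 0.5, seed = 6)
  truth <- gen_cistromes(spec)$truth
  # no depletion: log2 fold changes centre on zero
  ec0 <- gen_element_counts(truth, c(A_B = 1.0), seed = 8)
  d0 <- differential_occupancy(ec0)
  expect_lt(max(abs(d0$class_summary$median)), 0.05)
  # halved signal: median log2FC near -1 for the depleted class only
  ec <- gen_element_counts(truth, c(A_B = 0.5), seed = 8)
  d <- differential_occupancy(ec)
  med <- setNames(d$class_summary$median, d$class_summary$signature)
  expect_equal(unname(med["A_B"]), -1, tolerance = 0.1)
  expect_lt(max(abs(med[c("A", "B")])), 0.05)
  expect_error(gen_element_counts(truth[0, ], c(A = 1), seed = 1), "empty")
})

test_that("expression cohorts carry the planted effect size and survival shift", {
  spec <- cohort_sim_spec(n_datasets = 1, n_samples = 50, n_genes = 400,
                          n_planted_per_direction = 20, effect_size = 3,
                          noise_sd = 0.5, hazard_ratio = 0.3,
                          censor_time = Inf, seed = 12)
  co <- gen_expression_cohorts(spec)
  d <- co$datasets[[1]]
  q <- assign_quadrants(d)
  ext <- attr(q, "extremes")
  gx <- q$sample[q$quadrant == ext[1]]
  gy <- q$sample[q$quadrant == ext[2]]
  diffs <- rowMeans(d$matrix[co$truth$up_in_a_high, gx]) -
    rowMeans(d$matrix[co$truth$up_in_a_high, gy])
  expect_equal(mean(diffs), 3, tolerance = 0.3)
  # exponential survival: median time scales as 1/hazard
  ann <- d$annotations
  med_focal <- median(ann$os_time[q$quadrant == ext[1]])
  med_rest <- median(ann$os_time[q$quadrant != ext[1]])
  expect_gt(med_focal, med_rest)
  expect_identical(gen_expression_cohorts(spec), co)
})

test_that("null cohorts plant nothing", {
  spec <- cohort_sim_spec(n_datasets = 5, n_samples = 40, n_genes = 2000,
                          n_planted_per_direction = 0, effect_size = 0,
                          hazard_ratio = 1, mutation_enrichment_odds = 1,
                          seed = 13)
  co <- gen_expression_cohorts(spec)
  de <- lapply(co$datasets, function(d) {
    q <- assign_quadrants(d)
    ext <- attr(q, "extremes")
    differential_expression(d, q$sample[q$quadrant == ext[1]],
                            q$sample[q$quadrant == ext[2]])
  })
  mp <- consensus_meta_profile(de, min_support = 4)
  # false-positive expectation: P(sig same sign in >=4 of 5) under the null
  # is ~ choose(5,4) * 0.025^4, i.e. well below one gene in 2000
  expect_lte(nrow(mp$up_in_x) + nrow(mp$up_in_y), 2)
})

test_that("motif sequences respect GC content and truth positions", {
  pats <- default_motif_patterns()
  sim <- gen_motif_sequences(pats, n_seq = 100, seq_length = 500, gc = 0.6,
                             seed = 14)
  gc <- mean(strsplit(paste(sim$sequences, collapse = ""), "")[[1]] %in% c("C", "G"))
  expect_equal(gc, 0.6, tolerance = 0.01)
  emb <- gen_motif_sequences(pats, 1, 60,
                             embed = data.frame(seq = 1, pattern = "AP1",
                                                pos = 10, strand = "+"),
                             seed = 15)
  hits <- scan_sequence(emb$sequences[[1]], pats$AP1)
  expect_true(any(hits$start == 10 & hits$end == 16))
  expect_error(gen_motif_sequences(pats, 1, 10,
                                   embed = data.frame(seq = 1, pattern = "AICE1",
                                                      pos = 1, strand = "+"),
                                   seed = 1),
               "does not fit")
})
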