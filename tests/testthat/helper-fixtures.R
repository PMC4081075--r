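# Builds a complete synthetic study on disk and drives both workflows
# through the configuration layer.
build_fixture <- function(dir, seed = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cistrome_sim_spec(c("IRF4", "SPIB", "PU1"),
                            n_elements_per_factor = 120,
                            shared_fraction = matrix(c(1, .7, .4,
                                                       .7, 1, .5,
                                                       .4, .5, 1), 3, 3),
                            chrom_lengths = c(chrSim1 = 5e6), seed = seed)
  g <- gen_cistromes(spec)
  peak_files <- list()
  for (f in names(g$cistromes)) {
    p <- file.path(dir, paste0(f, ".narrowPeak"))
    write_peaks(g$cistromes[[f]], p, "narrowPeak")
    peak_files[[f]] <- p
  }
  genes <- gen_gene_models(80, c(chrSim1 = 5e6), seed = seed + 1)
  gene_path <- file.path(dir, "genes.tsv")
  write_gene_models(genes, gene_path)
  ec <- gen_element_counts(g$truth, c(IRF4_SPIB = 0.5), seed = seed + 2)
  ec_path <- file.path(dir, "element_counts.tsv")
  write.table(as.data.frame(ec), ec_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  co <- gen_expression_cohorts(cohort_sim_spec(
    n_datasets = 4, n_samples = 40, n_genes = 600,
    n_planted_per_direction = 15, effect_size = 2, noise_sd = 0.6,
    hazard_ratio = 0.4, mutation_enrichment_odds = 5, seed = seed + 3))
  expr_inputs <- list()
  for (i in seq_along(co$datasets)) {
    mp <- file.path(dir, sprintf("expr%02d.tsv", i))
    ap <- file.path(dir, sprintf("ann%02d.tsv", i))
    write_expression_dataset(co$datasets[[i]], mp, ap)
    expr_inputs[[sprintf("cohort%02d", i)]] <- list(matrix = mp,
                                                    annotations = ap)
  }
  stage_path <- file.path(dir, "stages.tsv")
  genes_all <- rownames(co$datasets[[1]]$matrix)
  write.table(data.frame(gene_id = genes_all[3:202],
                         stage = rep(c("BC", "AB", "PB", "PC"), each = 50)),
              stage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gmt_path <- file.path(dir, "signatures.gmt")
  write_gmt(list(planted_up = co$truth$up_in_a_high,
                 unrelated = genes_all[400:450]), gmt_path)
  occ_path <- file.path(dir, "occupancy.tsv")
  write.table(data.frame(gene_id = c(co$truth$up_in_a_high, genes_all[500:539]),
                         group = "SPIB_occupied"),
              occ_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(peaks = peak_files, genes = gene_path, element_counts = ec_path,
       expression = expr_inputs, stage_map = stage_path,
       signatures = gmt_path, occupancy_map = occ_path, truth = co$truth)
}
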