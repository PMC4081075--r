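#' Read and validate a pipeline configuration
#'
#' YAML configuration with an `inputs` block (file paths per data kind), a
#' `params` block (clustering radius, bin size, meta-profile support, test
#' cutoffs, bootstrap iterations, seed) and an `out_dir`. Defaults mirror
#' the canonical analysis values: radius 250 bp, bins 100 bp, near-distance
#' 50 bp, motif window 100 bp, promoter flank 2 kb, upstream reach 5 kb,
#' per-cohort p < 0.05, consensus support >= 4, knockdown FDR < 0.05 with
#' fold change >= 1.5, stable subset fold change < 1.4, signature sets
#' < 1000 genes, bootstrap 1e7 draws.
#'
#' @param path YAML file, or a list with the same structure.
#' @param check_files verify that referenced input files exist
#'   (default TRUE).
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, check_files = TRUE) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(radius = 250, bin_size = 100, near = 50,
                   motif_window = 100, promoter_flank = 2000,
                   upstream = 5000, tss_flank = 2000,
                   de_alpha = 0.05, min_support = 4,
                   fdr_alpha = 0.05, fc_threshold = 1.5,
                   stable_fc = 1.4, max_set_size = 1000,
                   n_iter = 1e7, pseudocount = 1, seed = 1,
                   gene_a = "SPIB", gene_b = "BATF", class_filter = "ABC")
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  cfg$inputs <- cfg$inputs %||% list()
  if (is.null(cfg$out_dir)) stopf("config must set out_dir")
  with(cfg$params, {
    if (radius <= 0 || bin_size <= 0) stopf("radius and bin_size must be > 0")
    if (min_support < 1) stopf("min_support must be >= 1")
    if (stable_fc <= 1 || fc_threshold < 1) stopf("fold-change cutoffs out of range")
    if (de_alpha <= 0 || de_alpha >= 1 || fdr_alpha <= 0 || fdr_alpha >= 1)
      stopf("alpha cutoffs must lie in (0, 1)")
  })
  if (check_files) {
    path_keys <- c("peaks", "expression", "gene_models", "genome",
                   "element_counts", "occupancy_map", "stage_map",
                   "signatures_gmt")
    paths <- unlist(cfg$inputs[intersect(names(cfg$inputs), path_keys)],
                    use.names = FALSE)
    paths <- as.character(paths)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stopf("config references missing file(s): %s",
            paste(missing, collapse = ", "))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

# stable content hash of the parameter block, for the manifest
params_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(params), vapply(params, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"), tmp)
  unname(tools::md5sum(tmp))
}

manifest_init <- function(cfg, workflow) {
  list(workflow = workflow,
       package_version = as.character(utils::packageVersion("cofbal")),
       seed = cfg$params$seed,
       params = cfg$params,
       params_hash = params_hash(cfg$params),
       stages = list())
}

manifest_add <- function(manifest, stage, files, out_dir) {
  rel <- files
  hashes <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest$stages[[stage]] <- list(stage = stage, files = as.list(rel),
                                   md5 = as.list(hashes))
  manifest
}

manifest_write <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the co-occupancy workflow
#'
#' Reads per-factor peak files, clusters them into regulatory elements,
#' and emits: the cluster table, occupancy-signature counts, centre-distance
#' profiles of every other factor against the first (reference) factor,
#' promoter fractions per factor (when gene models are supplied), motif
#' counts around cluster index centres (when a genome FASTA is supplied),
#' the binned occupancy correlation matrix with its hierarchical leaf
#' order, and knockdown differential occupancy (when an element count table
#' is supplied). Every emitted table is listed, with its md5, in
#' `manifest.json`.
#'
#' @param config a [read_pipeline_config()] result, path, or list.
#' @return invisibly, the manifest list.
#' @export
run_cooccupancy <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  p <- cfg$params
  if (is.null(cfg$inputs$peaks) || !length(cfg$inputs$peaks))
    stopf("co-occupancy workflow requires inputs$peaks (named list of files)")
  if (isTRUE(cfg$inputs$motifs_enabled %||% FALSE) && is.null(cfg$inputs$genome))
    stopf("motif counting enabled but no inputs$genome FASTA configured")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest_init(cfg, "cooccupancy")
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (outputs are partial)", stage,
            conditionMessage(e)))
  }

  cists <- run_stage("read_peaks", {
    dialect <- cfg$inputs$dialect %||% "bed6"
    lapply(seq_along(cfg$inputs$peaks), function(i)
      read_peaks(cfg$inputs$peaks[[i]], dialect = dialect,
                 factor = names(cfg$inputs$peaks)[i]))
  })

  clusters <- run_stage("cluster_peaks", cluster_peaks(cists, radius = p$radius))
  tab <- cluster_table(clusters)
  write_tsv(tab, file.path(cfg$out_dir, "clusters.tsv"))
  man <- manifest_add(man, "cluster_peaks", "clusters.tsv", cfg$out_dir)

  sig <- occupancy_signature_counts(clusters)
  write_tsv(data.frame(signature = names(sig), count = as.integer(sig)),
            file.path(cfg$out_dir, "signature_counts.tsv"))
  man <- manifest_add(man, "occupancy_signatures", "signature_counts.tsv",
                      cfg$out_dir)

  if (length(cists) >= 2) {
    prof <- run_stage("centre_distance", {
      do.call(rbind, lapply(cists[-1], function(q) {
        pr <- centre_distance_profile(cists[[1]], q, near = p$near)
        data.frame(reference = attr(cists[[1]], "factor"),
                   query = attr(q, "factor"),
                   fraction_within = pr$fraction_within,
                   near = pr$near, n_reference = pr$n_reference)
      }))
    })
    write_tsv(prof, file.path(cfg$out_dir, "centre_distance.tsv"))
    man <- manifest_add(man, "centre_distance", "centre_distance.tsv", cfg$out_dir)
  }

  if (!is.null(cfg$inputs$gene_models)) {
    genes <- read_gene_models(cfg$inputs$gene_models)
    pf <- run_stage("promoter_fraction", {
      data.frame(factor = vapply(cists, attr, "", "factor"),
                 promoter_fraction = vapply(cists, promoter_fraction,
                                            numeric(1), genes = genes,
                                            promoter_flank = p$promoter_flank))
    })
    write_tsv(pf, file.path(cfg$out_dir, "promoter_fraction.tsv"))
    man <- manifest_add(man, "promoter_fraction", "promoter_fraction.tsv",
                        cfg$out_dir)
  }

  if (!is.null(cfg$inputs$genome)) {
    counts <- run_stage("motif_counts", {
      idx <- tab[, c("cluster_id", "chrom", "index_centre")]
      names(idx)[3] <- "centre"
      count_motif_matches(idx, cfg$inputs$genome, window = p$motif_window)
    })
    write_tsv(data.frame(cluster_id = tab$cluster_id, counts),
              file.path(cfg$out_dir, "motif_counts.tsv"))
    man <- manifest_add(man, "motif_counts", "motif_counts.tsv", cfg$out_dir)
  }

  if (length(cists) >= 2) {
    corr <- run_stage("occupancy_correlation", {
      tracks <- lapply(cists, bin_occupancy, bin_size = p$bin_size)
      occupancy_correlation_matrix(tracks)
    })
    write_tsv(data.frame(label = rownames(corr), corr),
              file.path(cfg$out_dir, "correlation_matrix.tsv"))
    ord <- hierarchical_order(corr)
    writeLines(paste(ord$order, collapse = "\t"),
               file.path(cfg$out_dir, "correlation_leaf_order.txt"))
    man <- manifest_add(man, "occupancy_correlation",
                        c("correlation_matrix.tsv", "correlation_leaf_order.txt"),
                        cfg$out_dir)
  }

  if (!is.null(cfg$inputs$element_counts)) {
    res <- run_stage("differential_occupancy", {
      ec <- read.delim(cfg$inputs$element_counts)
      differential_occupancy(element_count_table(ec),
                             pseudocount = p$pseudocount)
    })
    write_tsv(res$class_summary, file.path(cfg$out_dir, "kd_class_summary.tsv"))
    write_tsv(res$class_tests, file.path(cfg$out_dir, "kd_class_tests.tsv"))
    man <- manifest_add(man, "differential_occupancy",
                        c("kd_class_summary.tsv", "kd_class_tests.tsv"),
                        cfg$out_dir)
  }

  manifest_write(man, cfg$out_dir)
  invisible(man)
}

#' Run the subgroup / clinical workflow
#'
#' For each expression cohort: quadrant assignment by the two marker genes,
#' differential expression between the two extreme quadrants; then the
#' cross-cohort consensus meta-profiles, optional occupancy enrichment of
#' the profiles (hypergeometric, given a gene -> occupancy map TSV),
#' optional differentiation-stage bootstrap z-scores (given a gene -> stage
#' map TSV), optional signature-collection enrichment (given a GMT),
#' Kaplan-Meier / log-rank comparison of the extreme quadrants and mutation
#' association per quadrant, for cohorts carrying the annotations.
#'
#' @param config a [read_pipeline_config()] result, path, or list.
#' @return invisibly, the manifest list.
#' @export
run_subgroups <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  p <- cfg$params
  exprs <- cfg$inputs$expression
  if (is.null(exprs) || length(exprs) < p$min_support)
    stopf("subgroup workflow requires >= min_support (%d) expression cohorts",
          p$min_support)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest_init(cfg, "subgroups")

  datasets <- lapply(seq_along(exprs), function(i) {
    e <- exprs[[i]]
    if (!is.list(e)) e <- list(matrix = e)
    read_expression_dataset(e$matrix, e$annotations,
                            dataset_id = names(exprs)[i])
  })

  quads <- lapply(datasets, assign_quadrants, gene_a = p$gene_a,
                  gene_b = p$gene_b, class_filter = p$class_filter)
  qtab <- do.call(rbind, lapply(seq_along(quads), function(i)
    cbind(dataset = datasets[[i]]$dataset_id, quads[[i]])))
  write_tsv(qtab, file.path(cfg$out_dir, "quadrants.tsv"))
  man <- manifest_add(man, "assign_quadrants", "quadrants.tsv", cfg$out_dir)

  extremes <- attr(quads[[1]], "extremes")
  de <- lapply(seq_along(datasets), function(i) {
    q <- quads[[i]]
    differential_expression(datasets[[i]],
                            group_x = q$sample[q$quadrant == extremes[1]],
                            group_y = q$sample[q$quadrant == extremes[2]],
                            alpha = p$de_alpha)
  })
  meta <- consensus_meta_profile(de, min_support = p$min_support)
  write_tsv(cbind(direction = paste0("up_in_", extremes[1]), meta$up_in_x),
            file.path(cfg$out_dir, "meta_profile_x.tsv"))
  write_tsv(cbind(direction = paste0("up_in_", extremes[2]), meta$up_in_y),
            file.path(cfg$out_dir, "meta_profile_y.tsv"))
  write_gmt(setNames(list(meta$up_in_x$gene, meta$up_in_y$gene),
                     paste0("up_in_", extremes)),
            file.path(cfg$out_dir, "meta_profiles.gmt"))
  man <- manifest_add(man, "consensus_meta_profile",
                      c("meta_profile_x.tsv", "meta_profile_y.tsv",
                        "meta_profiles.gmt"), cfg$out_dir)

  if (!is.null(cfg$inputs$occupancy_map)) {
    om <- read.delim(cfg$inputs$occupancy_map)   # columns: gene_id, group
    rows <- list()
    for (grp in unique(om$group)) {
      ann <- om$gene_id[om$group == grp]
      for (dir_name in c("x", "y")) {
        prof <- if (dir_name == "x") meta$up_in_x$gene else meta$up_in_y$gene
        r <- hypergeometric_test(prof, ann, meta$universe)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(occupancy = grp, profile = paste0("up_in_", dir_name)), r)
      }
    }
    enr <- do.call(rbind, rows)
    enr$q_value <- bh_fdr(enr$p_value)
    write_tsv(enr, file.path(cfg$out_dir, "occupancy_enrichment.tsv"))
    man <- manifest_add(man, "occupancy_enrichment", "occupancy_enrichment.tsv",
                        cfg$out_dir)
  }

  if (!is.null(cfg$inputs$stage_map)) {
    sm <- read.delim(cfg$inputs$stage_map)       # columns: gene_id, stage
    cmap <- setNames(sm$stage, sm$gene_id)
    cmap <- cmap[names(cmap) %in% meta$universe]
    bz <- do.call(rbind, lapply(c(x = "x", y = "y"), function(d) {
      prof <- if (d == "x") meta$up_in_x$gene else meta$up_in_y$gene
      cbind(profile = paste0("up_in_", d),
            bootstrap_category_zscore(prof, cmap, meta$universe,
                                      n_iter = p$n_iter, seed = p$seed))
    }))
    write_tsv(bz, file.path(cfg$out_dir, "stage_bootstrap.tsv"))
    man <- manifest_add(man, "stage_bootstrap", "stage_bootstrap.tsv",
                        cfg$out_dir)
  }

  if (!is.null(cfg$inputs$signatures_gmt)) {
    coll <- read_gmt(cfg$inputs$signatures_gmt)
    se <- signature_collection_enrichment(meta$up_in_x$gene, coll,
                                          meta$universe,
                                          max_set_size = p$max_set_size)
    write_tsv(se, file.path(cfg$out_dir, "signature_enrichment.tsv"))
    man <- manifest_add(man, "signature_enrichment", "signature_enrichment.tsv",
                        cfg$out_dir)
  }

  surv_rows <- list(); mut_rows <- list()
  for (i in seq_along(datasets)) {
    ann <- datasets[[i]]$annotations
    q <- quads[[i]]
    ann <- ann[match(q$sample, ann$sample), ]
    ext <- q$quadrant %in% extremes
    if (all(is.finite(ann$os_time[ext])) && sum(ann$os_event[ext]) >= 1 &&
        length(unique(q$quadrant[ext])) == 2) {
      lr <- logrank_test(ann$os_time[ext], ann$os_event[ext], q$quadrant[ext])
      surv_rows[[length(surv_rows) + 1L]] <- data.frame(
        dataset = datasets[[i]]$dataset_id, statistic = lr$statistic,
        df = lr$df, p_value = lr$p_value)
      for (g in extremes) {
        sel <- ext & q$quadrant == g
        km <- km_estimate(ann$os_time[sel], ann$os_event[sel])
        write_tsv(cbind(group = g, as.data.frame(km)),
                  file.path(cfg$out_dir,
                            sprintf("km_%s_%s.tsv", datasets[[i]]$dataset_id, g)))
      }
    }
    if (!all(is.na(ann$myd88))) {
      ma <- mutation_association(q, setNames(ann$myd88, ann$sample))
      mut_rows[[length(mut_rows) + 1L]] <-
        cbind(dataset = datasets[[i]]$dataset_id, ma)
    }
  }
  if (length(surv_rows)) {
    write_tsv(do.call(rbind, surv_rows), file.path(cfg$out_dir, "logrank.tsv"))
    km_files <- list.files(cfg$out_dir, pattern = "^km_.*\\.tsv$")
    man <- manifest_add(man, "survival", c("logrank.tsv", km_files), cfg$out_dir)
  }
  if (length(mut_rows)) {
    write_tsv(do.call(rbind, mut_rows),
              file.path(cfg$out_dir, "mutation_association.tsv"))
    man <- manifest_add(man, "mutation_association", "mutation_association.tsv",
                        cfg$out_dir)
  }

  manifest_write(man, cfg$out_dir)
  invisible(man)
}
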