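mk_dataset <- function(m, class = "ABC", id = "ds") {
  expression_dataset(id, m, data.frame(sample = colnames(m), class = class))
}

test_that("quadrant assignment follows the rank-based median split", {
  m <- rbind(SPIB = c(1, 2, 3, 4), BATF = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  q <- assign_quadrants(mk_dataset(m))
  expect_equal(q$quadrant[q$sample == "s1"], "SPIBlow_BATFhigh")
  expect_equal(q$quadrant[q$sample == "s4"], "SPIBhigh_BATFlow")
  expect_equal(sort(unique(q$quadrant)),
               c("SPIBhigh_BATFlow", "SPIBlow_BATFhigh"))
})

test_that("quadrant partition is exhaustive, exclusive and balanced", {
  set.seed(61)
  m <- rbind(SPIB = rnorm(25), BATF = rnorm(25),
             matrix(rnorm(50), 2, 25, dimnames = list(c("g1", "g2"), NULL)))
  colnames(m) <- sprintf("s%02d", 1:25)
  q <- assign_quadrants(mk_dataset(m))
  expect_equal(nrow(q), 25)
  expect_equal(anyDuplicated(q$sample), 0)
  # per marker, high gets floor(n/2), the middle rank goes low
  expect_equal(sum(q$SPIB_level == "high"), 12)
  expect_equal(sum(q$BATF_level == "low"), 13)
})

test_that("median ties resolve deterministically by stable sample order", {
  m <- rbind(SPIB = c(5, 5, 5, 1, 9), BATF = c(1, 2, 3, 4, 5))
  colnames(m) <- paste0("s", 1:5)
  q1 <- assign_quadrants(mk_dataset(m))
  q2 <- assign_quadrants(mk_dataset(m))
  expect_identical(q1, q2)
  # ties at 5,5,5 with ranks by first occurrence: s1 gets the lower rank
  expect_equal(q1$SPIB_level, c("low", "low", "high", "low", "high"))
})

test_that("missing marker genes are named in the error", {
  m <- matrix(rnorm(8), 2, 4, dimnames = list(c("SPIB", "g"), paste0("s", 1:4)))
  expect_error(assign_quadrants(mk_dataset(m)), "BATF")
})

test_that("differential expression recovers a planted shift and is antisymmetric", {
  set.seed(62)
  m <- matrix(rnorm(100 * 50, 6, 0.5), 100, 50,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:50)))
  gx <- colnames(m)[1:25]; gy <- colnames(m)[26:50]
  m["g001", gx] <- m["g001", gx] + 3
  d <- mk_dataset(m)
  de <- differential_expression(d, gx, gy)
  expect_true(de$significant[de$gene == "g001"])
  expect_equal(de$log2fc[de$gene == "g001"], 3, tolerance = 0.45)
  de_sw <- differential_expression(d, gy, gx)
  expect_equal(de$log2fc, -de_sw$log2fc)
  expect_equal(de$p_value, de_sw$p_value)
})

test_that("row-wise Welch matches stats::t.test", {
  set.seed(63)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  d <- mk_dataset(m)
  de <- differential_expression(d, colnames(m)[1:6], colnames(m)[7:12])
  for (i in 1:10) {
    tt <- t.test(m[i, 1:6], m[i, 7:12])
    expect_equal(de$p_value[i], tt$p.value)
  }
})

test_that("degenerate zero-variance genes get p = 1, not NaN", {
  m <- matrix(5, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  m[2, 1:4] <- 7   # zero variance but different means
  de <- differential_expression(mk_dataset(m), paste0("s", 1:4),
                                paste0("s", 5:8))
  expect_equal(de$p_value[c(1, 3)], c(1, 1))
  expect_true(all(de$degenerate))
})

test_that("consensus meta-profile applies the support threshold and conflicts rule", {
  mk_de <- function(sig_up, sig_dn) {
    genes <- sprintf("g%02d", 1:10)
    data.frame(gene = genes,
               log2fc = ifelse(genes %in% sig_up, 1,
                               ifelse(genes %in% sig_dn, -1, 0.01)),
               p_value = ifelse(genes %in% c(sig_up, sig_dn), 0.001, 0.5),
               significant = genes %in% c(sig_up, sig_dn),
               degenerate = FALSE)
  }
  # g01 up in 4/9, g02 up in 3/9, g03 up in 4 and down in 4
  de <- c(lapply(1:4, function(i) mk_de(c("g01", "g03"), character())),
          lapply(1:4, function(i) mk_de("g02", "g03")),
          list(mk_de(character(), character())))
  de[[6]] <- mk_de(character(), "g03")   # g02 supported in only 3 cohorts
  expect_warning(mp <- consensus_meta_profile(de, min_support = 4), "both")
  expect_true("g01" %in% mp$up_in_x$gene)
  expect_false("g02" %in% mp$up_in_x$gene)
  expect_equal(mp$conflicts, "g03")
  expect_false("g03" %in% c(mp$up_in_x$gene, mp$up_in_y$gene))
  expect_equal(mp$up_in_x$support[mp$up_in_x$gene == "g01"], 4)
})

test_that("meta-profiles are monotone in min_support", {
  spec <- cohort_sim_spec(n_datasets = 6, n_samples = 40, n_genes = 1000,
                          n_planted_per_direction = 20, seed = 64)
  co <- gen_expression_cohorts(spec)
  de <- lapply(co$datasets, function(d) {
    q <- assign_quadrants(d)
    ext <- attr(q, "extremes")
    differential_expression(d, q$sample[q$quadrant == ext[1]],
                            q$sample[q$quadrant == ext[2]])
  })
  sizes <- vapply(4:6, function(ms) {
    mp <- consensus_meta_profile(de, min_support = ms)
    nrow(mp$up_in_x) + nrow(mp$up_in_y)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("knockdown gene lists respect the two stringency tiers", {
  set.seed(65)
  n <- 500
  genes <- sprintf("g%03d", 1:n)
  ctl <- matrix(rnorm(n * 4, 8, 0.03), n, 4, dimnames = list(genes, NULL))
  kd <- matrix(rnorm(n * 4, 8, 0.03), n, 4, dimnames = list(genes, NULL))
  kd["g001", ] <- kd["g001", ] - log2(1.6)   # strong fold change
  kd["g002", ] <- kd["g002", ] - log2(1.2)   # significant but small FC
  res <- knockdown_de(ctl, kd)
  expect_true("g001" %in% res$list_a)
  expect_true("g001" %in% res$list_b)
  expect_true("g002" %in% res$list_a)
  expect_false("g002" %in% res$list_b)
  expect_equal(res$table$direction[res$table$gene == "g001"], "down")
  expect_error(knockdown_de(ctl[, 1, drop = FALSE], kd), "replicates")
})

test_that("null knockdown yields an empty strict list", {
  empties <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 1000
    ctl <- matrix(rnorm(n * 3, 8, 0.5), n, 3,
                  dimnames = list(sprintf("g%d", 1:n), NULL))
    kd <- matrix(rnorm(n * 3, 8, 0.5), n, 3,
                 dimnames = list(sprintf("g%d", 1:n), NULL))
    length(knockdown_de(ctl, kd)$list_b) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.95)
})

test_that("expression-by-occupancy summaries track planted shifts", {
  set.seed(66)
  expr <- setNames(rnorm(1000, 6, 1), sprintf("g%04d", 1:1000))
  occ <- setNames(rep("bound", 200), names(expr)[1:200])
  expr[names(occ)] <- expr[names(occ)] + 2
  s <- summarize_expression_by_occupancy(expr, occ)
  expect_equal(s$group, c("Total", "bound"))
  expect_equal(s$median[s$group == "bound"] - s$median[s$group == "Total"], 2,
               tolerance = 0.3)
  # all genes in one group: group median equals the global median
  all_map <- setNames(rep("all", 1000), names(expr))
  s2 <- summarize_expression_by_occupancy(expr, all_map)
  expect_equal(s2$median[1], s2$median[2])
  # empty map: baseline only
  s3 <- summarize_expression_by_occupancy(expr, setNames(character(), character()))
  expect_equal(s3$group, "Total")
})

test_that("marker correlations recover a planted Spearman structure", {
  set.seed(67)
  mk <- function(id, rho = 0.5, n = 100) {
    z <- rnorm(n)
    m <- rbind(SPIB = z, BATF = rho * z + sqrt(1 - rho^2) * rnorm(n),
               IRF4 = rnorm(n))
    colnames(m) <- sprintf("%s_s%03d", id, 1:n)
    mk_dataset(m, id = id)
  }
  res <- marker_correlations(lapply(1:6, function(i) mk(paste0("d", i))))
  sb <- res$summary[res$summary$pair == "SPIB BATF", ]
  expect_equal(sb$mean_rho, 0.48, tolerance = 0.15)   # Spearman of 0.5 Pearson
  si <- res$summary[res$summary$pair == "SPIB IRF4", ]
  expect_lt(abs(si$mean_rho), 0.2)
  # perfectly monotone pair
  m <- rbind(SPIB = 1:10, BATF = (1:10)^2, IRF4 = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  one <- marker_correlations(list(mk_dataset(m)))
  expect_equal(one$per_dataset$rho[one$per_dataset$gene_a == "SPIB" &
                                   one$per_dataset$gene_b == "BATF"], 1)
})

test_that("probe collapse keeps the max-mean probe per gene", {
  m <- matrix(c(1, 1, 5, 5, 2, 8), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_probes_max_mean(m, map)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(out["gA", ], c(s1 = 5, s2 = 5))
})
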