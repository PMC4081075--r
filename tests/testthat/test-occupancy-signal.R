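mk_track_cistrome <- function(intervals, factor) {
  cistrome(data.frame(chrom = intervals$chrom, start = intervals$start,
                      end = intervals$end), factor = factor)
}

test_that("binning sets every bin a peak interval overlaps", {
  x <- mk_track_cistrome(data.frame(chrom = "chr1", start = 100, end = 300), "A")
  tr <- bin_occupancy(x, 100)
  expect_equal(tr$bins$bin, c(1, 2))
  expect_equal(tr$bins$value, c(1, 1))
  e <- cistrome(data.frame(chrom = character(), start = integer(),
                           end = integer()), factor = "E")
  expect_equal(nrow(bin_occupancy(e, 100)$bins), 0)
})

test_that("sparse binning equals dense per-base binning on a toy genome", {
  set.seed(31)
  n <- 150
  start <- sample(0:990000, n)
  pk <- data.frame(chrom = "chr1", start = start,
                   end = start + sample(50:3000, n, replace = TRUE))
  tr <- bin_occupancy(mk_track_cistrome(pk, "A"), 100)
  dense <- oracle_bin_dense(pk, 100, 1e6)
  expect_equal(tr$bins[, c("chrom", "bin", "value")],
               dense[, c("chrom", "bin", "value")],
               ignore_attr = TRUE)
})

test_that("signal mode sums scores across overlapping peaks", {
  x <- cistrome(data.frame(chrom = "chr1", start = c(100, 150), end = c(250, 260),
                           score = c(2, 3)), factor = "A")
  tr <- bin_occupancy(x, 100, mode = "signal")
  expect_equal(tr$bins$value[tr$bins$bin == 1], 5)
  expect_equal(tr$bins$value[tr$bins$bin == 2], 5)
})

test_that("correlation matrix has exact unit diagonal and [-1,1] range", {
  spec <- cistrome_sim_spec(c("A", "B", "C"), n_elements_per_factor = 200,
                            shared_fraction = 0.5, seed = 41)
  tracks <- lapply(gen_cistromes(spec)$cistromes, bin_occupancy)
  r <- occupancy_correlation_matrix(tracks)
  expect_equal(diag(r), setNames(rep(1, 3), c("A", "B", "C")))
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(r, t(r))
  # relabeling does not change values
  tracks2 <- tracks
  tracks2[[1]]$label <- "Z"
  r2 <- occupancy_correlation_matrix(tracks2)
  expect_equal(unname(r2), unname(r))
})

test_that("disjoint equal-occupancy binary tracks correlate at -1", {
  a <- mk_track_cistrome(data.frame(chrom = "chr1",
                                    start = seq(0, 900, 200),
                                    end = seq(0, 900, 200) + 100), "A")
  b <- mk_track_cistrome(data.frame(chrom = "chr1",
                                    start = seq(100, 1000, 200),
                                    end = seq(100, 1000, 200) + 100), "B")
  r <- occupancy_correlation_matrix(list(bin_occupancy(a, 100),
                                         bin_occupancy(b, 100)))
  expect_equal(r["A", "B"], -1)
})

test_that("zero-variance tracks are flagged, never silently zero", {
  a <- mk_track_cistrome(data.frame(chrom = "chr1", start = 0, end = 100), "A")
  covers_all <- mk_track_cistrome(data.frame(chrom = "chr1", start = 0,
                                             end = 1000), "B")
  # over the union-occupied domain B is constant 1
  expect_warning(
    r <- occupancy_correlation_matrix(list(bin_occupancy(a, 100),
                                           bin_occupancy(covers_all, 100))),
    "zero-variance")
  expect_true(is.na(r["A", "B"]))
})

test_that("hierarchical order puts planted blocks together and rejects NaN", {
  r <- matrix(c(1, .9, .1, .15,
                .9, 1, .12, .1,
                .1, .12, 1, .85,
                .15, .1, .85, 1), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  ord <- hierarchical_order(r)$order
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)
  expect_equal(abs(diff(match(c("C", "D"), ord))), 1)
  r[1, 2] <- r[2, 1] <- NaN
  expect_error(hierarchical_order(r), "missing")
  # identical rows merge first at height 0
  r2 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
               dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  hc <- hierarchical_order(r2)
  expect_equal(hc$height[1], 0)
})

test_that("log2 fold changes are antisymmetric and normalization-invariant", {
  set.seed(51)
  el <- data.frame(element_id = sprintf("e%03d", 1:200),
                   signature = sample(c("X", "Y"), 200, replace = TRUE),
                   control = rpois(200, 100) + 1L,
                   kd = rpois(200, 60) + 1L)
  t1 <- element_count_table(el, lib_control = 1e6, lib_kd = 1e6)
  f1 <- differential_occupancy(t1, pseudocount = 0)$elements$log2fc
  swapped <- element_count_table(
    data.frame(el[c("element_id", "signature")], control = el$kd,
               kd = el$control), lib_control = 1e6, lib_kd = 1e6)
  f2 <- differential_occupancy(swapped, pseudocount = 0)$elements$log2fc
  expect_equal(f1, -f2)
  scaled <- element_count_table(
    data.frame(el[c("element_id", "signature")], control = el$control * 7,
               kd = el$kd), lib_control = 7e6, lib_kd = 1e6)
  f3 <- differential_occupancy(scaled, pseudocount = 0)$elements$log2fc
  expect_equal(f1, f3)
})

test_that("equal counts and libraries give exactly zero fold change", {
  el <- data.frame(element_id = c("a", "b"), signature = "S",
                   control = c(10, 20), kd = c(10, 20))
  t1 <- element_count_table(el, lib_control = 100, lib_kd = 100)
  expect_equal(differential_occupancy(t1)$elements$log2fc, c(0, 0))
})

test_that("stable-subset enrichment hits closed-form edge cases", {
  el <- data.frame(element_id = sprintf("e%d", 1:10),
                   signature = rep(c("F", "G"), each = 5),
                   control = rep(100, 10),
                   kd = c(rep(100, 5), rep(25, 5)))
  tab <- element_count_table(el, lib_control = 1000, lib_kd = 1000)
  res <- stable_subset_enrichment(tab, 1.4, focus_signature = "F")
  # stable set is exactly the focus set: minimal p for the margins
  expect_equal(res$k, 5)
  expect_equal(res$n, 5)
  expect_equal(res$p_value, oracle_hyper(5, 5, 5, 10))
  # everything stable: p = 1
  allst <- element_count_table(data.frame(el[1:2], control = rep(100, 10),
                                          kd = rep(100, 10)),
                               lib_control = 1000, lib_kd = 1000)
  expect_equal(stable_subset_enrichment(allst, 1.4, "F")$p_value, 1)
})
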