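test_that("pearson_cor matches the closed form and rejects degenerate input", {
  expect_equal(pearson_cor(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(1:3, c(6, 4, 2))$r, -1)
  pc <- pearson_cor(1:4, c(1, 3, 2, 4))
  expect_equal(pc$r, 0.8)
  or <- oracle_pearson(1:4, c(1, 3, 2, 4))
  expect_equal(pc$r, or$r)
  expect_equal(pc$p, or$p)
  set.seed(2)
  for (i in 1:10) {
    x <- stats::rnorm(7); y <- stats::rnorm(7)
    expect_equal(pearson_cor(x, y)$p, oracle_pearson(x, y)$p)
  }
  expect_error(pearson_cor(rep(1, 5), stats::rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "3 observations")
})

test_that("exact WMW p-values equal exhaustive enumeration", {
  w <- wmw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  expect_equal(w$p, 0.1)  # 2/20 extreme splits
  expect_equal(oracle_wmw_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(5)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- stats::rnorm(na); b <- stats::rnorm(nb)
    expect_equal(wmw_test(a, b)$p, oracle_wmw_exact(a, b),
                 tolerance = 1e-12, label = sprintf("sizes %d+%d", na, nb))
  }
})

test_that("WMW handles ties, symmetry and degenerate input", {
  a <- c(1, 2, 3, 3, 5, 8, 9)
  b <- c(1, 2, 3, 4, 4, 7, 7)
  expect_equal(wmw_test(a, b)$p, wmw_test(b, a)$p)  # two-sided symmetry
  expect_equal(wmw_test(a, a)$p, 1)                 # elementwise-tied groups
  expect_equal(wmw_test(rep(2, 10), rep(2, 12))$p, 1)  # zero rank variance
  p <- wmw_test(stats::rnorm(20), stats::rnorm(25))$p
  expect_true(p >= 0 && p <= 1)
  expect_error(wmw_test(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.04)), c(0.002, 0.04))
  set.seed(6)
  for (i in 1:50) {
    p <- stats::runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # permutation equivariance
  p <- stats::runif(20); perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

noise_free_tc <- function(...) {
  simulate_timecourse(sim_config(noise_sd_log2 = 0, tissue_sd_log2 = 0, ...),
                      seed = 21L)
}

test_that("correlation screen calls classes correctly on noise-free data", {
  tc <- noise_free_tc(n_resilient = 10L, n_sensitive = 5L, n_artifact = 5L,
                      n_dna_background = 0L)
  norm <- glog_normalize(tc$expression, calibrate = FALSE)
  scr <- correlation_screen(norm, tc$meta, "rin")
  k <- tc$truth$klass[match(scr$mirna_id, tc$truth$mirna_id)]
  expect_true(all(scr$call[k == "artifact"] == "negative"))
  expect_true(all(scr$call[k == "sensitive"] == "positive"))
  expect_true(all(scr$call[k == "resilient"] == "ns"))  # constant rows -> ns
  expect_true(all(scr$p_adj >= scr$p))
})

test_that("correlation screen recovers artifacts on the default simulation", {
  tc <- simulate_timecourse(sim_config(), seed = 22L)
  norm <- detection_filter(glog_normalize(tc$expression, calibrate = FALSE), 5)
  scr <- correlation_screen(norm, tc$meta, "rin")
  k <- tc$truth$klass[match(scr$mirna_id, tc$truth$mirna_id)]
  expect_gte(mean(scr$call[k == "artifact"] == "negative"), 0.9)
  # time screens restrict to one temperature arm
  rt <- correlation_screen(norm, tc$meta, "time_RT")
  expect_identical(unique(rt$covariate), "time_RT")
  expect_gt(mean(rt$r[k == "artifact"] > 0, na.rm = TRUE), 0.5)
})

test_that("differential expression applies the fold-change and p-value rules", {
  tc <- noise_free_tc(n_resilient = 6L, n_sensitive = 4L, n_artifact = 4L,
                      n_dna_background = 0L)
  norm <- glog_normalize(tc$expression, calibrate = FALSE)
  liver <- tc$meta$sample_id[tc$meta$tissue == "liver"]
  sub <- norm[, colnames(norm$values) %in% liver]
  de <- differential_expression(sub, tc$meta, rin_cutoff = 6)
  k <- tc$truth$klass[match(de$mirna_id, tc$truth$mirna_id)]
  e <- tc$truth$effect_log2[match(de$mirna_id, tc$truth$mirna_id)]
  expect_true(all(!de$significant[k == "resilient"]))
  expect_true(all(de$log2fc[k == "resilient"] == 0))
  strong <- k == "sensitive" & e <= -2
  expect_true(all(de$significant[strong] & de$log2fc[strong] < 0))
  expect_true(all(de$log2fc[k == "artifact"] > 0))
})

test_that("differential expression sign flips when groups are swapped", {
  tc <- simulate_timecourse(sim_config(n_resilient = 20L, n_sensitive = 10L,
                                       n_artifact = 10L, n_dna_background = 0L),
                            seed = 23L)
  norm <- glog_normalize(tc$expression, calibrate = FALSE)
  meta <- tc$meta
  de1 <- differential_expression(norm, meta, rin_cutoff = 6)
  flipped <- meta
  flipped$rin <- ifelse(meta$rin <= 6, 10, 1)  # invert group membership
  de2 <- differential_expression(norm, flipped, rin_cutoff = 6)
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p, de2$p)
})

test_that("differential expression demands two samples per group", {
  tc <- noise_free_tc(n_resilient = 4L, n_sensitive = 1L, n_artifact = 1L,
                      n_dna_background = 0L)
  norm <- glog_normalize(tc$expression, calibrate = FALSE)
  meta <- tc$meta
  meta$rin <- c(2, rep(9, nrow(meta) - 1))
  expect_error(differential_expression(norm, meta), "low-integrity")
})

test_that("era counts partition each sample's detected total", {
  ann <- toy_annotation(c("ACGTACGTACGTACGTAC", "TTTTCCCCGGGGAAAATT",
                          "ACACACACACACACACAC"), versions = c(2L, 17L, 21L))
  v <- matrix(2^c(1, 9, 9, 9, 1, 9), 3, 2,
              dimnames = list(ann$mirna_id, c("s1", "s2")))
  d <- v >= 2^5
  m <- expression_matrix(v, d)
  bins <- list("1-3" = c(1L, 3L), "4-15" = c(4L, 15L), "16-21" = c(16L, 21L))
  counts <- detected_counts_by_era(m, ann, bins)
  expect_equal(unname(counts[, "s1"]), c(0L, 0L, 2L))
  expect_equal(unname(counts[, "s2"]), c(1L, 0L, 1L))
  expect_equal(colSums(counts), colSums(d))
  # all-undetected sample gives an all-zero column
  m0 <- expression_matrix(v, matrix(FALSE, 3, 2, dimnames = dimnames(v)))
  expect_true(all(detected_counts_by_era(m0, ann, bins) == 0))
  rownames(v)[1] <- "mystery-mir"
  dimnames(d) <- dimnames(v)
  expect_error(detected_counts_by_era(expression_matrix(v, d), ann, bins),
               "unannotated")
})

test_that("recent-era detections rise with degradation in the default simulation", {
  tc <- simulate_timecourse(sim_config(), seed = 24L)
  counts <- detected_counts_by_era(tc$expression, tc$annotation,
                                   samples = c("RT_liver_0h", "RT_liver_96h"))
  gain <- counts[, "RT_liver_96h"] - counts[, "RT_liver_0h"]
  expect_gt(gain["16-21"], gain["1-3"])
})
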