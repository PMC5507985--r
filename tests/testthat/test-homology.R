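revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
revseq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

test_that("best_window finds exact containments and obeys orientation", {
  set.seed(41)
  mir <- random_seq(22)
  tx <- paste0(random_seq(80), mir, random_seq(80))
  bw <- best_window(mir, tx, 1)
  expect_equal(bw$length, 22L)
  expect_equal(bw$mismatches, 0L)
  expect_equal(substr(tx, bw$tstart + 1, bw$tstart + bw$length), mir)
  # sense-only: the reverse complement does not produce a long window
  bw_rc <- best_window(mir, paste0(random_seq(80), revcomp(mir), random_seq(80)), 1)
  expect_lt(bw_rc$length, 20L)
  expect_error(best_window("", tx), "non-empty")
})

test_that("best_window is symmetric under reversal of both sequences", {
  set.seed(42)
  for (i in 1:10) {
    mir <- random_seq(20)
    tx <- random_seq(120)
    expect_equal(best_window(mir, tx, 1)$length,
                 best_window(revseq(mir), revseq(tx), 1)$length)
  }
})

test_that("the flagging boundary follows ceil(min_frac * length)", {
  set.seed(43)
  # 20-nt miRNA, transcript carries 18 of it with 1 internal mismatch:
  # 18 >= ceil(0.9 * 20) = 18 -> flagged
  mir20 <- random_seq(20)
  frag18 <- substr(mir20, 2, 19)
  substr(frag18, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(frag18, 9, 9))[1]
  tx <- paste0(random_seq(60), frag18, random_seq(60))
  scr <- homology_screen(toy_annotation(mir20), c(t1 = tx), min_frac = 0.9,
                         max_mismatch = 1)
  expect_true(scr$flags[[1]])
  # random flanks can extend the window beyond the planted 18-mer
  expect_equal(scr$hits$window_length, oracle_best_window(mir20, tx, 1))
  expect_gte(scr$hits$window_length, 18L)

  # 22-nt miRNA with a best window of 19 < ceil(0.9 * 22) = 20 -> not flagged
  mir22 <- random_seq(22)
  frag19 <- substr(mir22, 2, 20)
  substr(frag19, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(frag19, 10, 10))[1]
  tx2 <- paste0(random_seq(60), frag19, random_seq(60))
  # guard: the embedded fragment must really be the best window
  if (oracle_best_window(mir22, tx2, 1) == 19) {
    scr2 <- homology_screen(toy_annotation(mir22), c(t1 = tx2), min_frac = 0.9,
                            max_mismatch = 1)
    expect_false(scr2$flags[[1]])
    expect_equal(nrow(scr2$hits), 0L)
  }
  expect_identical(sum(homology_screen(toy_annotation(mir20),
                                       character(0))$flags), 0L)
})

test_that("screen and best_window agree with the exhaustive oracle", {
  set.seed(44)
  for (i in 1:30) {
    mir <- random_seq(sample(18:24, 1))
    tx <- random_seq(sample(150:400, 1))
    if (i %% 3 == 0) {  # plant a partial match so positives occur
      frag <- substr(mir, 3, nchar(mir) - 1)
      pos <- sample(nchar(tx) - nchar(frag), 1)
      substr(tx, pos, pos + nchar(frag) - 1) <- frag
    }
    expect_equal(best_window(mir, tx, 1)$length, oracle_best_window(mir, tx, 1),
                 label = sprintf("case %d", i))
    scr <- homology_screen(toy_annotation(mir), c(t1 = tx), 0.9, 1)
    expect_identical(unname(scr$flags[1]), oracle_homology_flag(mir, tx, 0.9, 1),
                     label = sprintf("flag %d", i))
  }
})

test_that("flags are monotone in the mismatch budget and overlap fraction", {
  set.seed(45)
  mirs <- replicate(15, random_seq(21))
  tx <- replicate(5, random_seq(300))
  names(tx) <- paste0("t", 1:5)
  frag <- substr(mirs[1], 2, 20)
  tx[1] <- paste0(substr(tx[1], 1, 50), frag, substr(tx[1], 70, 300))
  ann <- toy_annotation(mirs)
  f1 <- homology_screen(ann, tx, min_frac = 0.9, max_mismatch = 0)$flags
  f2 <- homology_screen(ann, tx, min_frac = 0.9, max_mismatch = 2)$flags
  expect_true(all(f2[f1]))
  f3 <- homology_screen(ann, tx, min_frac = 0.8, max_mismatch = 1)$flags
  f4 <- homology_screen(ann, tx, min_frac = 0.95, max_mismatch = 1)$flags
  expect_true(all(f3[f4]))
})

test_that("group homology fractions count planted artifact homology", {
  expect_equal(unname(group_homology_fraction(
    stats::setNames(rep(c(TRUE, FALSE), c(3, 7)), paste0("m", 1:10)),
    stats::setNames(rep("g", 10), paste0("m", 1:10)))), 0.3)
  sim <- sim_config(n_resilient = 20L, n_sensitive = 10L, n_artifact = 15L,
                    n_dna_background = 5L)
  truth <- simulate_truth(sim, seed = 46L)
  ann <- truth[, c("mirna_id", "mature_sequence", "first_version")]
  tx <- simulate_transcripts(ann, embed_ids = truth$mirna_id[truth$klass == "artifact"],
                             seed = 46L)
  scr <- homology_screen(ann, tx)
  fr <- group_homology_fraction(scr$flags,
                                stats::setNames(truth$klass, truth$mirna_id))
  expect_equal(unname(fr["artifact"]), 1)       # planted as exact substrings
  expect_lt(mean(fr[c("resilient", "sensitive")], na.rm = TRUE), 0.5)
  # empty groups give NA
  g <- factor(rep("a", 10), levels = c("a", "b"))
  names(g) <- paste0("m", 1:10)
  fr2 <- group_homology_fraction(stats::setNames(rep(TRUE, 10), paste0("m", 1:10)), g)
  expect_true(is.na(fr2[["b"]]))
})
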