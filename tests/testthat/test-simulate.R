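noise_free_sim <- function(...) {
  sim_config(noise_sd_log2 = 0, tissue_sd_log2 = 0, ...)
}

test_that("RIN decay curves hit their anchor values and stay in range", {
  for (shape in c("linear", "two_phase", "hyperbolic")) {
    m <- decay_model("liver", "RT", shape, noise_sd = 0)
    expect_equal(simulate_rin(m, 0), 10)  # intact at harvest
  }
  # liver at RT: hyperbolic drop to RIN 4 after 6 h
  liv <- decay_model("liver", "RT", "hyperbolic", tau = 3, noise_sd = 0)
  expect_equal(simulate_rin(liv, 6), 4)
  # brain at 4C: slow linear decay keeps RIN above 7 through 96 h
  expect_gt(simulate_rin(default_decay_models(noise_sd = 0)$brain_4C, 96), 7)
  expect_error(simulate_rin(liv, -1), "non-negative")
  # noise-free curves are non-increasing and clamped to [1, 10]
  tgrid <- seq(0, 300, by = 1)
  for (m in default_decay_models(noise_sd = 0)) {
    r <- simulate_rin(m, tgrid)
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r >= 1 & r <= 10))
  }
})

test_that("noise-free time-course signals follow baseline + effect * D exactly", {
  sim <- noise_free_sim(n_resilient = 3L, n_sensitive = 0L, n_artifact = 2L,
                        n_dna_background = 0L)
  # linear decay reaching RIN 1 at 96 h gives D = 0 at t = 0 and D = 1 at 96 h
  slope <- 9 / 96
  models <- lapply(default_decay_models(noise_sd = 0), function(m) {
    decay_model(m$tissue, m$temperature, "linear", slope = slope, noise_sd = 0)
  })
  tc <- simulate_timecourse(sim, models, seed = 5L)
  lg <- log2(tc$expression$values)
  res_ids <- tc$truth$mirna_id[tc$truth$klass == "resilient"]
  for (id in res_ids) {
    expect_equal(unname(lg[id, ]), rep(tc$truth$baseline_log2[tc$truth$mirna_id == id], 48))
  }
  art <- tc$truth[tc$truth$klass == "artifact", ][1, ]
  s0 <- tc$meta$sample_id[tc$meta$time_h == 0][1]
  s96 <- tc$meta$sample_id[tc$meta$time_h == 96 &
                             tc$meta$tissue == tc$meta$tissue[tc$meta$sample_id == s0]][1]
  expect_equal(lg[art$mirna_id, s96] - lg[art$mirna_id, s0], art$effect_log2)
})

test_that("time-course output is deterministic under a fixed seed", {
  sim <- sim_config(n_resilient = 20L, n_sensitive = 10L, n_artifact = 10L,
                    n_dna_background = 5L)
  a <- simulate_timecourse(sim, seed = 9L)
  b <- simulate_timecourse(sim, seed = 9L)
  expect_identical(a, b)
  c <- simulate_timecourse(sim, seed = 10L)
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("generated classes correlate with RIN in the expected direction", {
  tc <- simulate_timecourse(sim_config(), seed = 3L)
  rin <- tc$meta$rin[match(colnames(tc$expression$values), tc$meta$sample_id)]
  lg <- log2(tc$expression$values)
  r <- apply(lg, 1, function(row) stats::cor(row, rin))
  k <- tc$truth$klass
  # recomputed directly from the generated matrix (independent of the screen)
  expect_gte(mean(r[k == "sensitive"] > 0), 0.95)
  expect_gte(mean(r[k == "artifact"] < 0), 0.95)
})

test_that("the control experiment design and signal rules are honored", {
  expect_equal(nrow(control_meta <- simulate_control_experiment(sim_config(
    n_resilient = 2L, n_sensitive = 2L, n_artifact = 2L, n_dna_background = 1L
  ))$meta), 24L)  # 8 conditions x 3 replicates

  sim <- noise_free_sim()
  ctrl <- simulate_control_experiment(sim, seed = 4L)
  lg <- log2(ctrl$expression$values)
  meta <- ctrl$meta
  truth <- ctrl$truth
  high <- meta$sample_id[meta$rnase_units == "0.67"]
  art <- truth[truth$klass == "artifact", ][1, ]
  # artifact in fully RNase-degraded depleted RNA: baseline + effect, detected
  expect_equal(unname(lg[art$mirna_id, high]),
               rep(art$baseline_log2 + art$effect_log2, length(high)))
  expect_true(all(ctrl$expression$detected[art$mirna_id, high]))
  # sensitive miRNAs vanish from every depleted arm
  depl <- meta$sample_id[meta$rna_fraction == "depleted"]
  sens_ids <- truth$mirna_id[truth$klass == "sensitive"]
  expect_false(any(ctrl$expression$detected[sens_ids, depl]))
  # DNase contrast equals the dna_background effect exactly
  dna <- truth[truth$klass == "dna_background", ][1, ]
  nod <- meta$sample_id[meta$time_h == 96 & meta$dnase == "no"]
  dnase <- meta$sample_id[meta$time_h == 96 & meta$dnase == "yes"]
  expect_equal(mean(lg[dna$mirna_id, nod]) - mean(lg[dna$mirna_id, dnase]),
               dna$effect_log2)
})

test_that("detected counts per sample never decrease when artifacts are added", {
  base <- sim_config(n_artifact = 0L, n_dna_background = 0L,
                     n_resilient = 100L, n_sensitive = 50L)
  more <- sim_config(n_artifact = 150L, n_dna_background = 0L,
                     n_resilient = 100L, n_sensitive = 50L)
  a <- simulate_timecourse(base, seed = 8L)
  b <- simulate_timecourse(more, seed = 8L)
  expect_true(all(colSums(b$expression$detected) >= colSums(a$expression$detected)))
})

test_that("transcript simulation plants mature sequences as exact substrings", {
  sim <- sim_config(n_resilient = 5L, n_sensitive = 5L, n_artifact = 10L,
                    n_dna_background = 0L)
  truth <- simulate_truth(sim, seed = 2L)
  ann <- truth[, c("mirna_id", "mature_sequence", "first_version")]
  ids <- truth$mirna_id[truth$klass == "artifact"]
  tx <- simulate_transcripts(ann, embed_ids = ids, seed = 2L)
  joined <- paste(tx, collapse = "|")
  for (s in truth$mature_sequence[truth$klass == "artifact"]) {
    expect_true(grepl(s, joined, fixed = TRUE))
  }
  expect_error(simulate_transcripts(ann, embed_ids = "nope"), "embed_ids")
})

test_that("degenerate simulator configurations are rejected", {
  expect_error(sim_config(n_resilient = 0L, n_sensitive = 0L, n_artifact = 0L,
                          n_dna_background = 0L), "non-empty")
  expect_error(sim_config(effect_sensitive = c(1, 2)), "negative")
  expect_error(simulate_timecourse(sim_config(), decay_models = list()),
               "missing decay model")
})
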