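test_that("evidence medians equal brute-force group medians", {
  sim <- sim_config(n_resilient = 15L, n_sensitive = 10L, n_artifact = 10L,
                    n_dna_background = 5L)
  ctrl <- simulate_control_experiment(sim, seed = 31L)
  norm <- glog_normalize(ctrl$expression, calibrate = FALSE)
  ev <- build_evidence(norm, ctrl$meta)
  meta <- ctrl$meta
  v <- norm$values; d <- norm$detected
  med <- function(i, sel) {
    x <- v[i, sel][d[i, sel]]
    if (length(x)) stats::median(x) else NA_real_
  }
  small <- meta$rna_fraction == "with_small_rna"
  for (i in sample(nrow(v), 10)) {
    expect_equal(ev$delta_degraded[i],
                 med(i, small & meta$time_h > 0) - med(i, small & meta$time_h == 0))
    expect_equal(ev$dnase_delta[i],
                 med(i, small & meta$time_h > 0 & meta$dnase == "no") -
                   med(i, small & meta$time_h > 0 & meta$dnase == "yes"))
  }
})

mk_evidence <- function(delta = 0, dnase = 0, dep_deg = FALSE, dep_int = FALSE,
                        intact = TRUE, id = "m1") {
  data.frame(mirna_id = id, delta_degraded = delta, dnase_delta = dnase,
             detected_intact = intact, detected_depleted_intact = dep_int,
             detected_depleted_degraded = dep_deg, stringsAsFactors = FALSE)
}

test_that("classification rules fire in their stated priority order", {
  expect_equal(classify_mirnas(mk_evidence(delta = 2, dep_deg = TRUE))$label,
               "likely_artifact")  # up in degraded tissue + depleted signal
  expect_equal(classify_mirnas(mk_evidence(delta = 2, dep_deg = FALSE))$label,
               "degradation_associated_unexplained")
  expect_equal(classify_mirnas(mk_evidence(delta = -2))$label, "sensitive")
  expect_equal(classify_mirnas(mk_evidence(delta = 0.2))$label, "resilient")
  # the DNase contrast outranks the artifact rule
  expect_equal(classify_mirnas(mk_evidence(delta = 2, dnase = 1.5, dep_deg = TRUE))$label,
               "dna_background")
  # absent evidence falls through to unclassified
  expect_equal(classify_mirnas(mk_evidence(delta = NA, dnase = NA, intact = FALSE))$label,
               "unclassified")
  # threshold is log2(fold_change)
  expect_equal(classify_mirnas(mk_evidence(delta = 1.2), fold_change = 2)$label,
               "degradation_associated_unexplained")
  expect_equal(classify_mirnas(mk_evidence(delta = 1.2), fold_change = 4)$label,
               "resilient")
})

test_that("classification is deterministic and order-independent", {
  ev <- do.call(rbind, lapply(1:20, function(i) {
    mk_evidence(delta = stats::rnorm(1, 0, 2), dnase = stats::rnorm(1, 0, 1),
                dep_deg = i %% 2 == 0, id = sprintf("m%02d", i))
  }))
  a <- classify_mirnas(ev)
  perm <- sample(nrow(ev))
  b <- classify_mirnas(ev[perm, ])
  expect_identical(a$label[perm], b$label)
  expect_identical(a$label, classify_mirnas(ev)$label)
})

test_that("raising the fold-change threshold shrinks the artifact set monotonically", {
  sim <- sim_config(n_resilient = 50L, n_sensitive = 30L, n_artifact = 60L,
                    n_dna_background = 10L)
  ctrl <- simulate_control_experiment(sim, seed = 32L)
  ev <- build_evidence(glog_normalize(ctrl$expression, calibrate = FALSE), ctrl$meta)
  fcs <- c(1.5, 2, 3, 5)
  # the artifact criterion is monotone in t = log2(fold_change); restrict to
  # miRNAs whose DNA-background rule outcome is stable across the grid, since
  # that higher-priority rule can otherwise release members as t rises
  stable <- ev$mirna_id[is.na(ev$dnase_delta) | ev$dnase_delta < log2(min(fcs))]
  sets <- lapply(fcs, function(fc) {
    cl <- classify_mirnas(ev, fold_change = fc)
    intersect(cl$mirna_id[cl$label == "likely_artifact"], stable)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("version-bias summaries separate artifact from genuine eras", {
  ann <- toy_annotation(replicate(8, random_seq(20)),
                        versions = c(1L, 2L, 3L, 2L, 18L, 19L, 20L, 21L))
  ev <- do.call(rbind, lapply(1:8, function(i) {
    mk_evidence(delta = if (i <= 4) -2 else 2, dep_deg = i > 4,
                id = ann$mirna_id[i])
  }))
  cl <- classify_mirnas(ev, annotation = ann)
  vb <- version_bias_summary(cl)
  expect_equal(unname(vb$table["sensitive", "1-3"]), 4)
  expect_equal(unname(vb$table["likely_artifact", "16-21"]), 4)
  expect_lt(vb$kruskal$p, 0.05)
  # a single label yields an undefined association statistic
  one <- classify_mirnas(ev[1:4, ], annotation = ann)
  expect_true(is.na(version_bias_summary(one)$kruskal$statistic))
})

test_that("classifier recovers latent classes on a mid-sized simulation", {
  sim <- sim_config(n_resilient = 100L, n_sensitive = 70L, n_artifact = 100L,
                    n_dna_background = 30L)
  truth <- simulate_truth(sim, seed = 33L)
  ctrl <- simulate_control_experiment(sim, truth = truth, seed = 33L)
  ev <- build_evidence(glog_normalize(ctrl$expression, calibrate = FALSE), ctrl$meta)
  cl <- classify_mirnas(ev, annotation = ctrl$annotation)
  m <- recovery_metrics(cl, truth)
  expect_gte(m$balanced_accuracy, 0.85)
  expect_gte(m$artifact_sensitivity, 0.85)
  expect_lte(m$false_artifact_rate, 0.05)
})
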