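# Integration of time-course and control-experiment evidence into per-miRNA
# degradation labels.

mirna_labels <- c("resilient", "sensitive", "likely_artifact",
                  "degradation_associated_unexplained", "dna_background",
                  "unclassified")

group_median <- function(vals, flags) {
  # medians use detected values only; a group with no detected signal has no
  # defined expression level (absent, not imputed)
  v <- vals[flags]
  if (length(v) == 0L) NA_real_ else stats::median(v)
}

#' Assemble per-miRNA degradation evidence
#'
#' From the normalized control-experiment matrix, computes for every miRNA
#' present in both experiments:
#' \itemize{
#'   \item \code{delta_degraded}: median log2 expression in degraded
#'     small-RNA samples minus the intact small-RNA median;
#'   \item \code{dnase_delta}: median in degraded samples without DNase
#'     digestion minus the median with DNase;
#'   \item detection booleans for the intact small-RNA arm, the depleted
#'     0 U arm and the depleted RNase-treated arms (>= 1 replicate).
#' }
#' Group medians are taken over detected values only; a group with no
#' detected value yields an absent (NA) delta rather than an imputed one.
#'
#' @param control Normalized control-experiment \code{ExpressionMatrix}.
#' @param control_meta Metadata for the control samples.
#' @param timecourse Optional normalized time-course matrix; when given, the
#'   evidence is restricted to miRNAs present in both matrices.
#' @return Data.frame with one row per miRNA: \code{mirna_id},
#'   \code{delta_degraded}, \code{dnase_delta}, \code{detected_intact},
#'   \code{detected_depleted_intact}, \code{detected_depleted_degraded}.
#' @export
build_evidence <- function(control, control_meta, timecourse = NULL) {
  validate_expression_matrix(control)
  if (control$state != "normalized") fail("build_evidence expects normalized matrices")
  meta <- validate_sample_meta(control_meta)
  meta <- meta[match(colnames(control$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) fail("control metadata is missing some samples")
  ids <- rownames(control$values)
  if (!is.null(timecourse)) {
    validate_expression_matrix(timecourse)
    ids <- intersect(ids, rownames(timecourse$values))
  }
  small <- meta$rna_fraction == "with_small_rna"
  g_intact <- small & meta$time_h == 0
  g_degr <- small & meta$time_h > 0
  g_degr_nod <- g_degr & meta$dnase == "no"
  g_degr_dn <- g_degr & meta$dnase == "yes"
  depleted <- meta$rna_fraction == "depleted"
  g_dep_intact <- depleted & meta$rnase_units == "0"
  g_dep_rnase <- depleted & meta$rnase_units %in% c("0.027", "0.67")
  v <- control$values[ids, , drop = FALSE]
  d <- control$detected[ids, , drop = FALSE]
  ev <- data.frame(
    mirna_id = ids,
    delta_degraded = NA_real_, dnase_delta = NA_real_,
    detected_intact = FALSE, detected_depleted_intact = FALSE,
    detected_depleted_degraded = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ids)) {
    m_int <- group_median(v[i, g_intact], d[i, g_intact])
    m_deg <- group_median(v[i, g_degr], d[i, g_degr])
    m_nod <- group_median(v[i, g_degr_nod], d[i, g_degr_nod])
    m_dn <- group_median(v[i, g_degr_dn], d[i, g_degr_dn])
    ev$delta_degraded[i] <- m_deg - m_int
    ev$dnase_delta[i] <- m_nod - m_dn
    ev$detected_intact[i] <- any(d[i, g_intact])
    ev$detected_depleted_intact[i] <- any(d[i, g_dep_intact])
    ev$detected_depleted_degraded[i] <- any(d[i, g_dep_rnase])
  }
  ev
}

#' Classify miRNAs from degradation evidence
#'
#' Deterministic first-matching-rule assignment with threshold
#' \code{t = log2(fold_change)}:
#' \enumerate{
#'   \item \code{dnase_delta >= t} -> \code{dna_background} (the DNase
#'     contrast discriminates DNA fragments, which also rise in degraded
#'     tissue, so this rule fires first);
#'   \item \code{delta_degraded >= t} and detected in an RNase-fragmented
#'     depleted arm -> \code{likely_artifact} (signal reproducible from
#'     small-RNA-free fragmented RNA: cross-hybridization);
#'   \item \code{delta_degraded >= t} without depleted signal ->
#'     \code{degradation_associated_unexplained};
#'   \item \code{delta_degraded <= -t} -> \code{sensitive};
#'   \item detected in intact RNA with \code{|delta_degraded| < t} ->
#'     \code{resilient};
#'   \item otherwise (including absent evidence) -> \code{unclassified}.
#' }
#'
#' @param evidence Evidence table from \code{\link{build_evidence}}.
#' @param fold_change Fold-change threshold; \code{t = log2(fold_change)}
#'   (default 2, i.e. t = 1).
#' @param annotation Optional annotation supplying \code{first_version}.
#' @return Data.frame of class \code{mirna_classification}: the evidence
#'   columns plus \code{label} (and \code{first_version} when annotated).
#' @export
classify_mirnas <- function(evidence, fold_change = 2, annotation = NULL) {
  if (fold_change < 1) fail("fold_change must be >= 1")
  t <- log2(fold_change)
  ge <- function(x, thr) !is.na(x) & x >= thr
  label <- rep("unclassified", nrow(evidence))
  dd <- evidence$delta_degraded
  rule1 <- ge(evidence$dnase_delta, t)
  rule2 <- !rule1 & ge(dd, t) & evidence$detected_depleted_degraded
  rule3 <- !rule1 & !rule2 & ge(dd, t)
  rule4 <- !rule1 & !rule2 & !rule3 & ge(-dd, t)
  rule5 <- !rule1 & !rule2 & !rule3 & !rule4 &
    evidence$detected_intact & !is.na(dd) & abs(dd) < t
  label[rule1] <- "dna_background"
  label[rule2] <- "likely_artifact"
  label[rule3] <- "degradation_associated_unexplained"
  label[rule4] <- "sensitive"
  label[rule5] <- "resilient"
  out <- cbind(evidence, label = label, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    annotation <- validate_mirbase_annotation(annotation)
    out$first_version <- annotation$first_version[match(out$mirna_id,
                                                        annotation$mirna_id)]
  }
  class(out) <- c("mirna_classification", "data.frame")
  out
}

#' @export
print.mirna_classification <- function(x, ...) {
  cat(sprintf("miRNA classification (%d miRNAs):\n", nrow(x)))
  tab <- table(factor(x$label, levels = mirna_labels))
  for (l in names(tab)) cat(sprintf("  %-36s %d\n", l, tab[[l]]))
  invisible(x)
}

#' Label-by-annotation-era summary
#'
#' Cross-tabulates classification labels against miRBase version eras and
#' reports a Kruskal-Wallis statistic of first version across labels
#' (NA when fewer than two labels are present).
#'
#' @param classification A \code{\link{classify_mirnas}} result carrying
#'   \code{first_version}.
#' @param era_bins Named list of inclusive version ranges.
#' @return List with \code{table} (labels x eras contingency matrix) and
#'   \code{kruskal} (list with \code{statistic}, \code{p}).
#' @export
version_bias_summary <- function(classification, era_bins = default_era_bins()) {
  if (is.null(classification$first_version)) {
    fail("classification carries no first_version; pass an annotation to classify_mirnas")
  }
  validate_era_bins(era_bins)
  era <- era_of_version(classification$first_version, era_bins)
  lab <- factor(classification$label, levels = mirna_labels)
  tab <- table(label = lab, era = era)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  kw <- if (nrow(tab) >= 2L) {
    t <- stats::kruskal.test(classification$first_version, droplevels(lab))
    list(statistic = unname(t$statistic), p = t$p.value)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  list(table = tab, kruskal = kw)
}

#' Recovery metrics against simulated ground truth
#'
#' Compares predicted labels with latent simulation classes (truth classes
#' map onto labels as resilient -> resilient, sensitive -> sensitive,
#' artifact -> likely_artifact, dna_background -> dna_background) and
#' reports per-class recall, balanced accuracy (mean recall over truth
#' classes present), the sensitivity of the \code{likely_artifact} call and
#' the false-artifact rate among truly resilient miRNAs.
#'
#' @param classification A \code{\link{classify_mirnas}} result.
#' @param truth Truth table from \code{\link{simulate_truth}}.
#' @return List with \code{recall} (named vector), \code{balanced_accuracy},
#'   \code{artifact_sensitivity}, \code{false_artifact_rate}.
#' @export
recovery_metrics <- function(classification, truth) {
  map <- c(resilient = "resilient", sensitive = "sensitive",
           artifact = "likely_artifact", dna_background = "dna_background")
  idx <- match(classification$mirna_id, truth$mirna_id)
  if (anyNA(idx)) fail("classification contains miRNAs absent from truth")
  klass <- truth$klass[idx]
  expected <- map[klass]
  classes <- intersect(names(map), unique(klass))
  recall <- vapply(classes, function(k) {
    mean(classification$label[klass == k] == map[[k]])
  }, numeric(1))
  list(
    recall = recall,
    balanced_accuracy = mean(recall),
    artifact_sensitivity = if ("artifact" %in% classes) recall[["artifact"]] else NA_real_,
    false_artifact_rate = if ("resilient" %in% classes) {
      mean(classification$label[klass == "resilient"] == "likely_artifact")
    } else NA_real_
  )
}
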