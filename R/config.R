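#' Analysis configuration
#'
#' Bundles every tunable threshold of the analysis pipeline. Defaults follow
#' the degradation-bias screening protocol: miRNAs detected in fewer than
#' \code{min_detect_samples} samples are dropped; a correlation is called when
#' \eqn{|r| > r^*} and the BH-adjusted p-value is below \code{alpha};
#' differential expression between integrity groups (split at
#' \code{rin_cutoff}, low group = RIN \eqn{\le} cutoff) requires at least a
#' \code{fold_change}-fold difference of group centers and a raw
#' Wilcoxon-Mann-Whitney p-value below \code{alpha}.
#'
#' @param min_detect_samples Minimum number of samples a miRNA must be
#'   detected in to be retained (default 5).
#' @param corr_threshold Absolute Pearson correlation needed for a
#'   positive/negative call (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param rin_cutoff RIN threshold splitting low- from high-integrity samples;
#'   the low group is RIN \eqn{\le} cutoff (default 6).
#' @param fold_change Minimum fold change for differential expression
#'   (default 2).
#' @param n_clusters Number of clusters cut from the miRNA dendrogram of the
#'   control experiment (default 8).
#' @param top_variance_n Number of highest-variance miRNAs used for
#'   tissue-separation clustering (default 50).
#' @param homology_min_frac Minimum fraction of the mature miRNA length that
#'   must match a transcript window (default 0.9).
#' @param homology_max_mismatch Mismatches tolerated inside the window
#'   (default 1).
#' @param era_bins Named list of inclusive miRBase version ranges, each a
#'   length-2 integer vector; must partition 1..21.
#' @param de_center Group center for fold changes: "median" (default) or
#'   "mean".
#' @param exclude_samples Character vector of sample IDs removed before
#'   analysis (quality exclusions are always explicit, never inferred).
#' @param detect_quantile Fallback detection rule when no flags are supplied:
#'   a value is "detected" when it exceeds this quantile of the whole matrix
#'   (default 0.25).
#' @param calibrate_timecourse,calibrate_control Apply the per-sample
#'   median/MAD calibration step of \code{\link{glog_normalize}} to the
#'   time-course / control matrices (both default \code{FALSE}). Calibration
#'   corrects array-level location/scale effects under the assumption that
#'   most probes are unchanged between samples; in degradation designs that
#'   assumption is violated by construction (bulk degradation and small-RNA
#'   depletion shift a majority of probes), so calibration converts
#'   composition shifts into spurious per-miRNA differences. Enable it for
#'   arrays with real labeling/scanner effects.
#' @param seed Integer seed used by pipeline stages that randomize.
#'
#' @return An object of class \code{analysis_config} (a validated list).
#' @examples
#' cfg <- analysis_config(rin_cutoff = 7)
#' cfg$fold_change
#' @export
analysis_config <- function(min_detect_samples = 5L,
                            corr_threshold = 0.5,
                            alpha = 0.05,
                            rin_cutoff = 6,
                            fold_change = 2,
                            n_clusters = 8L,
                            top_variance_n = 50L,
                            homology_min_frac = 0.9,
                            homology_max_mismatch = 1L,
                            era_bins = default_era_bins(),
                            de_center = c("median", "mean"),
                            exclude_samples = character(0),
                            detect_quantile = 0.25,
                            calibrate_timecourse = FALSE,
                            calibrate_control = FALSE,
                            seed = 1L) {
  de_center <- match.arg(de_center)
  if (!(homology_min_frac > 0 && homology_min_frac <= 1)) {
    fail("homology_min_frac must be in (0, 1]")
  }
  if (fold_change < 1) fail("fold_change must be >= 1")
  if (!(alpha > 0 && alpha < 1)) fail("alpha must be in (0, 1)")
  if (min_detect_samples < 0) fail("min_detect_samples must be >= 0")
  validate_era_bins(era_bins)
  structure(list(
    min_detect_samples = as.integer(min_detect_samples),
    corr_threshold = corr_threshold,
    alpha = alpha,
    rin_cutoff = rin_cutoff,
    fold_change = fold_change,
    n_clusters = as.integer(n_clusters),
    top_variance_n = as.integer(top_variance_n),
    homology_min_frac = homology_min_frac,
    homology_max_mismatch = as.integer(homology_max_mismatch),
    era_bins = era_bins,
    de_center = de_center,
    exclude_samples = exclude_samples,
    detect_quantile = detect_quantile,
    calibrate_timecourse = isTRUE(calibrate_timecourse),
    calibrate_control = isTRUE(calibrate_control),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Default miRBase version eras
#'
#' The annotation-era bins used throughout: versions 1-3 (the founding,
#' Northern-blot-validated era), 4-9, 10-15 and 16-21 (the NGS era).
#'
#' @return Named list of length-2 integer vectors (inclusive ranges).
#' @export
default_era_bins <- function() {
  list("1-3" = c(1L, 3L), "4-9" = c(4L, 9L),
       "10-15" = c(10L, 15L), "16-21" = c(16L, 21L))
}

validate_era_bins <- function(bins) {
  if (!is.list(bins) || length(bins) == 0L) fail("era_bins must be a non-empty list")
  covered <- integer(0)
  for (b in bins) {
    if (length(b) != 2L || b[1] > b[2]) fail("each era bin must be an inclusive (lo, hi) pair")
    covered <- c(covered, seq.int(b[1], b[2]))
  }
  if (anyDuplicated(covered)) fail("era_bins overlap")
  if (!all(1:21 %in% covered)) fail("era_bins must cover miRBase versions 1..21")
  invisible(bins)
}

# map versions to era labels
era_of_version <- function(version, era_bins) {
  labs <- names(era_bins)
  out <- rep(NA_character_, length(version))
  for (i in seq_along(era_bins)) {
    b <- era_bins[[i]]
    out[version >= b[1] & version <= b[2]] <- labs[i]
  }
  factor(out, levels = labs)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  cat(sprintf("  detection filter  : >= %d samples\n", x$min_detect_samples))
  cat(sprintf("  correlation call  : |r| > %.2f, BH p < %.3g\n",
              x$corr_threshold, x$alpha))
  cat(sprintf("  DE call           : >= %.3g-fold (%s), WMW p < %.3g, low RIN <= %.3g\n",
              x$fold_change, x$de_center, x$alpha, x$rin_cutoff))
  cat(sprintf("  clustering        : k = %d (miRNA), top-%d variance (tissue)\n",
              x$n_clusters, x$top_variance_n))
  cat(sprintf("  homology          : >= %.0f%% overlap, <= %d mismatch\n",
              100 * x$homology_min_frac, x$homology_max_mismatch))
  invisible(x)
}
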