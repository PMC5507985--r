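# Per-miRNA statistics: Pearson screens against RIN/storage time,
# high- vs low-integrity differential expression, BH control.

#' Pearson correlation with t-distribution p-value
#'
#' Thin wrapper around \code{stats::cor.test} that enforces the
#' preconditions (equal lengths of at least 3, non-constant vectors) and
#' returns just the coefficient and the two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with elements \code{r} and \code{p}.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) fail("x and y must have equal length")
  if (length(x) < 3L) fail("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fail("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided WMW test of two independent groups. With a combined size of at
#' most 12 and no ties the exact null distribution of U is used; otherwise a
#' midrank normal approximation with tie correction (no continuity
#' correction). U is the number of (a, b) pairs with a > b (ties counted
#' half). Fully degenerate inputs (zero rank variance) give p = 1.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max Total size up to which the exact distribution is used
#'   when there are no ties (default 12).
#' @return List with elements \code{U} and \code{p}.
#' @export
wmw_test <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) fail("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && N <= exact_max) {
    p_low <- stats::pwilcox(U, na, nb)
    p_high <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - na * nb / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via \code{stats::p.adjust}), with input
#' validation; output order matches input order and is permutation
#' equivariant.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    fail("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-miRNA correlation screen against RIN or storage time
#'
#' Computes the Pearson correlation of every miRNA's normalized expression
#' with a sample covariate: the RIN value (all samples), or the storage time
#' within one temperature arm (\code{time_4C}, \code{time_RT}). A miRNA is
#' called \code{positive} when \code{r > corr_threshold} with BH-adjusted
#' \code{p < alpha}, \code{negative} when \code{r < -corr_threshold} with
#' adjusted \code{p < alpha}, otherwise \code{ns}. Constant miRNA rows (no
#' expression variation) have an undefined coefficient and are reported as
#' \code{r = NA, p = 1, ns}.
#'
#' @param m A normalized \code{ExpressionMatrix}.
#' @param meta Sample metadata covering the matrix columns.
#' @param covariate One of \code{"rin"}, \code{"time_4C"}, \code{"time_RT"}.
#' @param cfg An \code{\link{analysis_config}} (thresholds
#'   \code{corr_threshold}, \code{alpha}).
#' @return Data.frame with columns \code{mirna_id}, \code{covariate},
#'   \code{r}, \code{p}, \code{p_adj}, \code{call}.
#' @export
correlation_screen <- function(m, meta, covariate = c("rin", "time_4C", "time_RT"),
                               cfg = analysis_config()) {
  covariate <- match.arg(covariate)
  validate_expression_matrix(m)
  if (m$state != "normalized") fail("correlation_screen expects a normalized matrix")
  meta <- validate_sample_meta(meta)
  meta <- meta[match(colnames(m$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) fail("metadata is missing some matrix samples")
  if (covariate == "rin") {
    sel <- rep(TRUE, nrow(meta)); x <- meta$rin
  } else {
    temp <- sub("time_", "", covariate)
    sel <- meta$temperature == temp
    x <- meta$time_h[sel]
  }
  if (sum(sel) < 3L) fail("fewer than 3 usable samples for covariate %s", covariate)
  if (stats::sd(x) == 0) fail("covariate %s is constant over the selected samples", covariate)
  v <- m$values[, sel, drop = FALSE]
  res <- apply(v, 1, function(row) {
    if (stats::sd(row) == 0) return(c(NA_real_, 1))
    pc <- pearson_cor(row, x)
    c(pc$r, pc$p)
  })
  r <- res[1, ]; p <- res[2, ]
  p_adj <- bh_adjust(p)
  call <- rep("ns", length(r))
  call[!is.na(r) & r > cfg$corr_threshold & p_adj < cfg$alpha] <- "positive"
  call[!is.na(r) & r < -cfg$corr_threshold & p_adj < cfg$alpha] <- "negative"
  data.frame(mirna_id = rownames(m$values), covariate = covariate,
             r = unname(r), p = unname(p), p_adj = unname(p_adj), call = call,
             stringsAsFactors = FALSE)
}

#' Differential expression between integrity groups
#'
#' Splits samples into a low-integrity group (RIN <= \code{rin_cutoff}) and a
#' high-integrity group (RIN > cutoff) and tests every miRNA with the
#' two-sided WMW test. The log2 fold change is the difference of group
#' centers (median by default) on the normalized scale,
#' \code{log2fc = center(low) - center(high)}. A miRNA is significant when
#' \code{|log2fc| >= log2(fold_change)} and the raw WMW \code{p < alpha};
#' BH-adjusted p-values are reported alongside.
#'
#' @param m A normalized \code{ExpressionMatrix}.
#' @param meta Sample metadata covering the matrix columns.
#' @param rin_cutoff RIN threshold (low group is RIN <= cutoff; default 6).
#' @param fold_change Minimum fold change (default 2).
#' @param alpha Raw p-value threshold (default 0.05).
#' @param center \code{"median"} (default) or \code{"mean"} group center.
#' @return Data.frame with columns \code{mirna_id}, \code{median_low},
#'   \code{median_high}, \code{log2fc}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @export
differential_expression <- function(m, meta, rin_cutoff = 6, fold_change = 2,
                                    alpha = 0.05, center = c("median", "mean")) {
  center <- match.arg(center)
  validate_expression_matrix(m)
  if (m$state != "normalized") fail("differential_expression expects a normalized matrix")
  meta <- validate_sample_meta(meta)
  meta <- meta[match(colnames(m$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) fail("metadata is missing some matrix samples")
  low <- meta$rin <= rin_cutoff
  if (sum(low) < 2L) fail("low-integrity group has fewer than 2 samples")
  if (sum(!low) < 2L) fail("high-integrity group has fewer than 2 samples")
  cfun <- if (center == "median") stats::median else mean
  v <- m$values
  res <- apply(v, 1, function(row) {
    w <- wmw_test(row[low], row[!low])
    c(cfun(row[low]), cfun(row[!low]), w$p)
  })
  med_low <- res[1, ]; med_high <- res[2, ]; p <- res[3, ]
  log2fc <- med_low - med_high
  data.frame(mirna_id = rownames(v),
             median_low = unname(med_low), median_high = unname(med_high),
             log2fc = unname(log2fc), p = unname(p), p_adj = bh_adjust(p),
             significant = unname(abs(log2fc) >= log2(fold_change) & p < alpha),
             stringsAsFactors = FALSE)
}

#' Detected-miRNA counts by miRBase annotation era
#'
#' For each selected sample, counts the detected miRNAs per annotation era
#' (bins of first miRBase versions). Era counts per sample sum to the
#' sample's total detected count because the bins partition versions 1..21.
#'
#' @param m An \code{ExpressionMatrix} (flags are used, values are not).
#' @param annotation Annotation table covering every miRNA in \code{m}.
#' @param era_bins Named list of inclusive version ranges (default
#'   \code{\link{default_era_bins}}).
#' @param samples Optional character vector restricting/ordering the sample
#'   columns.
#' @return Integer matrix, eras x samples.
#' @export
detected_counts_by_era <- function(m, annotation, era_bins = default_era_bins(),
                                   samples = NULL) {
  validate_expression_matrix(m)
  annotation <- validate_mirbase_annotation(annotation)
  validate_era_bins(era_bins)
  idx <- match(rownames(m$values), annotation$mirna_id)
  if (anyNA(idx)) {
    fail("unannotated miRNAs: %s",
         paste(utils::head(rownames(m$values)[is.na(idx)], 5), collapse = ", "))
  }
  if (is.null(samples)) samples <- colnames(m$values)
  missing_s <- setdiff(samples, colnames(m$values))
  if (length(missing_s)) fail("unknown samples: %s", paste(missing_s, collapse = ", "))
  era <- era_of_version(annotation$first_version[idx], era_bins)
  d <- m$detected[, samples, drop = FALSE]
  out <- vapply(seq_along(samples), function(j) {
    as.integer(tapply(d[, j], era, sum, default = 0L))
  }, integer(length(era_bins)))
  dimnames(out) <- list(names(era_bins), samples)
  out
}
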